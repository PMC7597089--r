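Package: convodiff
Title: Inference for Diffusion Processes Observed Through a Moving-Average Kernel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and statistical inference for ergodic diffusion processes
    that are observed only through a rectangular moving-average (convolution)
    kernel, a scheme that produces observations smoother than the latent path,
    as seen in some biomedical time series such as EEG. Provides Euler-Maruyama
    simulation with convolution-by-summation, estimation of the smoothing
    parameter from the ratio of full to reduced quadratic variations, an
    asymptotically Gaussian test of the null of direct (unsmoothed) observation,
    and convolution-corrected least-square quasi-likelihood estimation of the
    diffusion and drift parameters, together with the naive local Gaussian
    approximation baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
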