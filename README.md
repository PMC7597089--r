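# convodiff

Statistical inference for diffusion processes that are observed through a
rectangular moving-average (convolution) kernel.

## The problem

Some regularly sampled biomedical time series — EEG channels are the canonical
case — look like diffusion paths but are *smoother* than one: their realised
volatility falls as the sampling frequency rises, the opposite of the
classical microstructure-noise signature. A parsimonious model for this is
that the latent state follows a stochastic differential equation

    dX_t = b(X_t, beta) dt + a(X_t, alpha) dw_t,

while each recorded value is the trailing moving average of X over a window of
`rho` sampling steps (per coordinate). `rho = 0` is direct observation,
`rho = 1` integrated observation. Ignoring the smoothing biases standard
quasi-likelihood fits of `alpha` and `beta` severely; `convodiff` provides,
per coordinate:

* **`estimate_rho()`** — a consistent estimator of the window length from the
  ratio of the full quadratic variation (one-step squared increments) to the
  reduced one (two-step increments at even indices): smoothing deflates the
  two by different known factors, and their ratio is an explicitly invertible,
  strictly decreasing function of `rho`.
* **`smoothness_test()`** — an asymptotically N(0,1) test of H0 "observed
  directly" vs H1 "smoothed", based on the normalised gap between the two
  quadratic variations, rejected on the lower tail.
* **`fit_diffusion()`** — least-square quasi-likelihood estimates of `alpha`
  and `beta` whose increment-covariance target is corrected by the kernel
  factor `fG(rho_i, rho_j)`, with the estimated (or a known) `rho` plugged in.
* **`lga_fit()`** — the standard local-Gaussian-approximation fit that ignores
  convolution, as the biased baseline for comparison.
* **`simulate_convobs()`** — an Euler–Maruyama simulator with
  convolution-by-summation (compiled, seeded, reproducible) plus
  `run_replicates()` / `replicate_experiment()` to rerun the full simulation
  study at configurable scale.

## Worked example

Simulate the 1-D Ornstein–Uhlenbeck study design (`alpha* = 3`,
`beta* = (-2, 1)`, `n = 1e5` observations at step `h_n = 10^(-10/3)`) observed
through a half-step window (`rho* = 0.5`), then recover everything:

```r
library(convodiff)

model  <- ou_preset_1d()
cfg    <- sim_config(n = 1e5, h_n = 10^(-10/3), m = 2, seed = 42)
series <- simulate_convobs(model, alpha = 3, beta = c(-2, 1), rho = 0.5, cfg)

estimate_rho(series)
#> <smoothing_estimate>
#>   axis     ratio   rho_hat
#> 1    1 0.9085438 0.5027568

smoothness_test(series)
#> <smoothness_test> H0: direct observation; reject if T < -1.6449 (alpha = 0.05)
#>   axis         T      p_value reject
#> 1    1 -22.50097 2.03052e-112   TRUE

fit_diffusion(series, model)
#> <param_estimate> method = convobs
#>   rho_used:  0.50276 (estimated)
#>   alpha_hat: 3.0013
#>   beta_hat:  -1.7994, 0.98093
#>   contrasts: H1 = -1.12568e+07, H2 = -749457

lga_fit(series, model)$alpha_hat
#> [1] 2.7383
```

Reading the output: the QV ratio 0.909 inverts to a window estimate of 0.503
sampling steps (truth 0.5); the test statistic −22.5 rejects direct
observation at any conventional level; the corrected diffusion estimate 3.001
recovers the truth while the naive fit is dragged down to 2.74 — the
`sqrt(fG(0.5, 0.5)) ≈ 0.913` deflation the naive method cannot see. Drift
estimates are intrinsically noisy at this time horizon (T ≈ 46), for corrected
and naive fits alike.

A command-line wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/convodiff.R simulate --model ou1d --rho 0.5 --seed 42 --out series.csv
Rscript inst/cli/convodiff.R estimate-rho --input series.csv
Rscript inst/cli/convodiff.R fit --input series.csv --model ou1d
Rscript inst/cli/convodiff.R rv-profile --input series.csv --kmax 100 --out rv.csv
```

## Scope notes

Rectangular kernels only; no asymptotic standard errors for `alpha`/`beta`
(consistency is what the theory provides); per-axis tests without multiplicity
correction. See the methods vignette
(`vignettes/convolutional-observation.Rmd`) for the model, the numerical
choices and the design decisions.
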