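# Memoised Monte-Carlo runs shared across test files: the replication sweeps
# at the study scale (n = 1e5 observations) are computed once per test session.
.mc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .mc_cache, inherits = FALSE))
    assign(key, force(expr), envir = .mc_cache)
  get(key, envir = .mc_cache, inherits = FALSE)
}

# 1-D OU study replicates (alpha = 3, beta = (-2, 1), n = 1e5, h = 10^(-10/3))
reps_1d <- function(rho, n_reps = 200, fit_params = FALSE, base_seed) {
  key <- sprintf("ou1d_rho%s_fit%d_n%d", format(rho), fit_params, n_reps)
  cached(key, run_replicates(rho, n_reps = n_reps, design = "ou1d",
                             base_seed = base_seed, fit_params = fit_params))
}

reps_2d <- function(n_reps = 100, base_seed = 2000) {
  cached("ou2d", run_replicates(c(2, 4), n_reps = n_reps, design = "ou2d",
                                base_seed = base_seed, fit_params = TRUE))
}
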