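# Shared fixtures and small utilities for the test suite. Everything is
# generated in code; the resultant-walk tables are built once per session
# and cached inside the package.

# group-mean generating parameters used throughout
group_params <- function(beta = -0.05) {
  population_params(M = 100L, gamma = 145, kappa = 2.4, alpha = 48.2,
                    sigma_c = 0.096, beta = beta, T = 0.1, eta = 0)
}

# total-variation distance between a sample of errors and a gridded density,
# both binned over (-pi, pi]
tv_binned <- function(errors, grid, density, n_bins = 25L) {
  brk <- seq(-pi, pi, length.out = n_bins + 1L)
  h <- tabulate(findInterval(errors, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(errors)
  0.5 * sum(abs(h - popcode:::bin_density(grid, density, n_bins)))
}

# contrast that produces a given expected total count under params (eta = 0)
contrast_for_xi <- function(xi, params) {
  q <- xi / (params$gamma * params$T)
  stopifnot(q < 1)
  params$sigma_c * (q / (1 - q))^(1 / params$alpha)
}

# build a single-subject trial table from the generating model, balanced
# across contrast levels (n_per_level trials each)
make_recovery_trials <- function(params, n_per_level = 400L,
                                 contrast_rel = c(0.5, 1, 2, 4)) {
  thr <- threshold_closed_form(params)
  cvec <- rep(contrast_rel * thr, each = n_per_level)
  sim <- simulate_popcode_trials(params, cvec)
  data.frame(subject = 1L, theta = sim$theta, report = sim$report,
             error = sim$error,
             contrast_rel = rep(contrast_rel, each = n_per_level),
             contrast_abs = cvec)
}

# replicate-fit fixture shared by the parameter-recovery and
# model-selection checks (expensive; computed once per session)
.fixture_env <- new.env(parent = emptyenv())
recovery_fixture <- function() {
  if (is.null(.fixture_env$rec)) {
    .fixture_env$rec <- parameter_recovery(
      n_rep = 20L, n_per_level = 400L, params = group_params(),
      models = c("popcode", "threshold", "two_stage"),
      seed = 2024L, n_starts = 2L, maxit = 500L)
  }
  .fixture_env$rec
}
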