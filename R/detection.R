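#' Probability of zero spikes in the decode window
#'
#' \eqn{P(m = 0 \mid c) = e^{-\xi(c)}} from the Poisson total count, with
#' baseline activity included in \eqn{\xi = T(\gamma g(c) + M\eta)}.
#'
#' @inheritParams mean_rates
#' @return probability in `[0, 1]`.
#' @export
p_zero_spikes <- function(c, params) {
  exp(-expected_total(c, params))
}

#' Closed-form 2AFC detection threshold (no baseline)
#'
#' Under zero baseline activity the no-stimulus epoch never contains spikes,
#' so the most-spikes observer errs only when the stimulus epoch is also
#' silent, and then guesses at 50%. Proportion correct is
#' \eqn{1 - e^{-\xi(c)}/2}; the 75%-correct threshold solves
#' \eqn{e^{-\xi(c)} = 1/2}, i.e. \eqn{g(c) = \ln 2/(\gamma T)}, inverted
#' through the contrast-response function:
#' \eqn{c = \sigma_c (q/(1-q))^{1/\alpha}} with \eqn{q = \ln 2/(\gamma T)}.
#'
#' @param params a [population_params] with `eta = 0` and
#'   \eqn{\gamma T > \ln 2} (otherwise 75% correct is unreachable).
#' @return threshold contrast (same units as `sigma_c`).
#' @export
threshold_closed_form <- function(params) {
  if (params$eta != 0)
    stop("closed-form threshold requires eta = 0; use threshold_monte_carlo()",
         call. = FALSE)
  q <- log(2) / (params$gamma * params$T)
  if (q >= 1)
    stop("gamma * T <= ln 2: the population cannot reach 75% correct",
         call. = FALSE)
  params$sigma_c * (q / (1 - q))^(1 / params$alpha)
}

#' Simulate 2AFC detection at one contrast
#'
#' Two decoding epochs per trial: the stimulus epoch has Poisson total count
#' with mean \eqn{T(\gamma g(c) + M\eta)}, the null epoch
#' \eqn{T M \eta}. The observer picks the epoch with more spikes; ties are
#' decided by a fair coin. Only summed counts matter for this observer, so
#' epochs are simulated as two Poisson totals (exact by Poisson
#' superposition).
#'
#' @inheritParams mean_rates
#' @param n_trials number of simulated trials.
#' @return proportion correct.
#' @export
simulate_2afc <- function(c, params, n_trials = 1e5) {
  stopifnot(n_trials >= 1)
  mu_s <- expected_total(c, params)
  mu_0 <- params$T * params$M * params$eta
  s <- stats::rpois(n_trials, mu_s)
  z <- stats::rpois(n_trials, mu_0)
  mean(s > z | (s == z & stats::runif(n_trials) < 0.5))
}

# Exact percent correct of the most-spikes observer: stimulus-epoch total
# S ~ Pois(mu_s), null-epoch total Z ~ Pois(mu_0), correct if S > Z, coin
# flip on ties. P = sum_z P(Z=z) [P(S>z) + P(S=z)/2].
p_correct_2afc <- function(c, params) {
  mu_s <- expected_total(c, params)
  mu_0 <- params$T * params$M * params$eta
  z <- 0:max(5L, stats::qpois(1 - 1e-12, mu_0))
  pz <- stats::dpois(z, mu_0)
  sum(pz * (stats::ppois(z, mu_s, lower.tail = FALSE) +
              0.5 * stats::dpois(z, mu_s)))
}

# Exact 75%-correct threshold by root finding on log contrast; NA when the
# asymptotic performance never reaches 75%.
threshold_exact <- function(params, c_lo, c_hi) {
  f <- function(lc) p_correct_2afc(exp(lc), params) - 0.75
  if (f(log(c_hi)) < 0) return(NA_real_)
  if (f(log(c_lo)) > 0) return(NA_real_)
  exp(stats::uniroot(f, c(log(c_lo), log(c_hi)), tol = 1e-10)$root)
}

#' Monte Carlo psychometric function and detection threshold
#'
#' Simulates [simulate_2afc()] over a contrast grid and finds the
#' 75%-correct threshold by monotone (isotonic-regression smoothed, then
#' linear) interpolation. Works for any baseline rate.
#'
#' @param params a [population_params].
#' @param contrast_grid increasing contrasts bracketing the threshold.
#' @param n_trials trials per grid point.
#' @return object of class `detection_prediction`: list with
#'   `threshold_contrast`, `psychometric` (data.frame `contrast`,
#'   `p_correct`), and `method`.
#' @export
threshold_monte_carlo <- function(params, contrast_grid, n_trials = 1e5) {
  pc <- vapply(contrast_grid, simulate_2afc, numeric(1), params = params,
               n_trials = n_trials)
  iso <- stats::isoreg(contrast_grid, pc)$yf
  if (max(iso) < 0.75 || min(iso) > 0.75)
    stop(sprintf("75%% correct not bracketed: attained range [%.3f, %.3f]",
                 min(iso), max(iso)), call. = FALSE)
  thr <- stats::approx(iso, contrast_grid, xout = 0.75, ties = "ordered")$y
  structure(list(threshold_contrast = thr,
                 psychometric = data.frame(contrast = contrast_grid,
                                           p_correct = pc),
                 method = "monte_carlo"),
            class = "detection_prediction")
}

#' @exportS3Method base::print
print.detection_prediction <- function(x, ...) {
  cat(sprintf("detection_prediction (%s): threshold contrast = %.4g\n",
              x$method, x$threshold_contrast))
  invisible(x)
}
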