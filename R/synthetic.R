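#' Configuration for the synthetic behavioral dataset generator
#'
#' Describes a contrast-varying orientation estimation study: each subject
#' completes a random number of trials (uniform on `trials_range`), each
#' trial shows a uniformly random orientation at a contrast drawn uniformly
#' from `contrast_rel` multiples of that subject's own model-derived
#' detection threshold, and the subject's responses are generated by the
#' population-coding model with per-subject parameters jittered around the
#' group means (log-normal with coefficient of variation `subject_cv`;
#' additive normal jitter with SD `beta_sd` for the bias).
#'
#' Confidence ratings are produced by a synthetic-only mechanism (the
#' behavior being emulated reports only confidence *correlates*): the log
#' posterior precision of the trial is mapped through a logistic function to
#' a latent 0-100 score, Gaussian response noise is added, and the result is
#' quantized to \{0, 25, 50, 75, 100\}.
#'
#' @param n_subjects number of subjects.
#' @param trials_range integer range of trials per subject.
#' @param contrast_rel contrast levels, multiples of detection threshold.
#' @param group_params group-mean generating [population_params].
#' @param subject_cv log-normal between-subject coefficient of variation for
#'   `gamma`, `kappa`, `alpha`, `sigma_c`.
#' @param beta_sd between-subject SD of the response bias (radians).
#' @param confidence list with `center` (log-precision at the latent
#'   midpoint), `scale` (logistic width in log-precision units), and
#'   `noise_sd` (latent response noise, 0-100 scale).
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8L, trials_range = c(280L, 480L),
                         contrast_rel = c(0.5, 1, 2, 4),
                         group_params = population_params(beta = -0.05),
                         subject_cv = 0.3, beta_sd = 0.03,
                         confidence = list(center = log(4), scale = 1.5,
                                           noise_sd = 15),
                         seed = 1L) {
  stopifnot(inherits(group_params, "population_params"),
            n_subjects >= 1, trials_range[1] <= trials_range[2],
            all(contrast_rel > 0), subject_cv >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_range = as.integer(trials_range),
                 contrast_rel = contrast_rel, group_params = group_params,
                 subject_cv = subject_cv, beta_sd = beta_sd,
                 confidence = confidence, seed = as.integer(seed)),
            class = "synth_config")
}

#' Assign a subject's detection threshold
#'
#' The absolute detection threshold implied by a subject's generating
#' parameters, via [threshold_closed_form()], so that threshold-relative
#' contrast levels correspond to well-defined absolute contrasts. Used by
#' [generate_dataset()] and recorded in its ground truth.
#'
#' @param params a [population_params] with `eta = 0` and
#'   \eqn{\gamma T > \ln 2}.
#' @return threshold contrast.
#' @export
assign_threshold <- function(params) threshold_closed_form(params)

# log-normal jitter with mean `m` and coefficient of variation `cv`
jitter_lnorm <- function(m, cv) {
  if (cv <= 0) return(m)
  s2 <- log(1 + cv^2)
  m * exp(stats::rnorm(1, -s2 / 2, sqrt(s2)))
}

quantize_confidence <- function(latent) {
  c(0, 25, 50, 75, 100)[findInterval(latent, c(12.5, 37.5, 62.5, 87.5)) + 1L]
}

#' Generate a synthetic behavioral dataset
#'
#' Runs the full generative pipeline of [synth_config()]: per-subject
#' parameters are drawn, each subject's detection threshold is computed in
#' closed form (so relative contrasts correspond to well-defined absolute
#' contrasts), trials are simulated through the Poisson encoder and MAP
#' decoder, the response bias is applied, and confidence ratings are
#' produced from the posterior precision. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [synth_config].
#' @return list with `trials` (data.frame: `subject`, `theta`, `report`,
#'   `error`, `contrast_rel`, `contrast_abs`, `confidence`, `total_count`,
#'   `posterior_precision`, `guessed`) and `truth` (per-subject generating
#'   parameters and thresholds).
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_subjects = 2, seed = 42))
#' head(ds$trials)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  gp <- config$group_params
  subj <- vector("list", config$n_subjects)
  trl <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    ps <- population_params(
      M = gp$M,
      gamma = jitter_lnorm(gp$gamma, config$subject_cv),
      kappa = jitter_lnorm(gp$kappa, config$subject_cv),
      alpha = jitter_lnorm(gp$alpha, config$subject_cv),
      sigma_c = jitter_lnorm(gp$sigma_c, config$subject_cv),
      beta = gp$beta + stats::rnorm(1, 0, config$beta_sd),
      T = gp$T, eta = gp$eta)
    if (ps$gamma * ps$T <= log(2))
      stop("subject ", s, ": gamma * T <= ln 2, no detection threshold ",
           "exists; increase gamma or the decode window", call. = FALSE)
    thr <- threshold_closed_form(ps)
    n <- sample(config$trials_range[1]:config$trials_range[2], 1L)
    lev <- sample(config$contrast_rel, n, replace = TRUE)
    sim <- simulate_popcode_trials(ps, lev * thr)
    latent <- 100 * stats::plogis(
      (log(sim$posterior_precision + 1e-3) - config$confidence$center) /
        config$confidence$scale) +
      stats::rnorm(n, 0, config$confidence$noise_sd)
    trl[[s]] <- data.frame(subject = s, theta = sim$theta,
                           report = sim$report, error = sim$error,
                           contrast_rel = lev, contrast_abs = lev * thr,
                           confidence = quantize_confidence(latent),
                           total_count = sim$total_count,
                           posterior_precision = sim$posterior_precision,
                           guessed = sim$guessed)
    subj[[s]] <- list(subject = s, params = ps, threshold = thr,
                      n_trials = n)
  }
  list(trials = do.call(rbind, trl), truth = subj)
}
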