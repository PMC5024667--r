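# Grid resolution used for likelihood evaluation. Error densities are
# computed once per unique contrast on this grid and interpolated at the
# observed errors; 360 points give 0.5 degree resolution in orientation
# space, far below behavioral precision.
FIT_GRID <- 360L
DENS_FLOOR <- 1e-300

#' Read and write trial tables
#'
#' Trial tables are stored as CSV with angles in degrees of orientation
#' space \eqn{(-90, 90]} and converted to circle radians at the boundary.
#' Columns: `subject`, `theta_deg`, `report_deg`, `contrast_rel`, optional
#' `contrast_abs`, optional `confidence` (one of 0, 25, 50, 75, 100). The
#' returned data.frame additionally carries `theta`, `report`, and `error`
#' in radians on the doubled circle.
#'
#' @param path CSV file path.
#' @param trials a trial data.frame as returned by [read_trials()] or
#'   [generate_dataset()].
#' @return `read_trials`: a data.frame of trials; `write_trials`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path)
  req <- c("subject", "theta_deg", "report_deg", "contrast_rel")
  if (!all(req %in% names(d)))
    stop("trial file must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(d$contrast_rel <= 0))
    stop("contrast_rel must be positive", call. = FALSE)
  if ("confidence" %in% names(d) &&
      !all(is.na(d$confidence) | d$confidence %in% c(0, 25, 50, 75, 100)))
    stop("confidence must be one of 0, 25, 50, 75, 100", call. = FALSE)
  d$theta <- orientation_to_circle(d$theta_deg)
  d$report <- orientation_to_circle(d$report_deg)
  d$error <- circ_diff(d$report, d$theta)
  d
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  out <- data.frame(subject = trials$subject,
                    theta_deg = circle_to_orientation(trials$theta),
                    report_deg = circle_to_orientation(trials$report),
                    contrast_rel = trials$contrast_rel)
  if ("contrast_abs" %in% names(trials)) out$contrast_abs <- trials$contrast_abs
  if ("confidence" %in% names(trials)) out$confidence <- trials$confidence
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# contrast column used for fitting: absolute if available (then sigma_c is
# in absolute units), otherwise threshold-relative.
fit_contrast <- function(trials) {
  if ("contrast_abs" %in% names(trials)) trials$contrast_abs
  else trials$contrast_rel
}

#' Log likelihood of the population-coding model
#'
#' Sum over trials of the log of the analytic error density
#' [error_density()] with \eqn{\xi = \gamma T g(c)} at the trial's contrast,
#' evaluated at the trial's response error. Densities are computed once per
#' unique contrast (sharing the Von Mises kernel across contrasts) and
#' linearly interpolated. Zero-spike guessing enters automatically through
#' the \eqn{e^{-\xi}/(2\pi)} mixture component.
#'
#' @param trials trial data.frame with columns `error` and `contrast_rel`
#'   (and optionally `contrast_abs`, used preferentially).
#' @param par named list or vector with elements `sigma_c`, `alpha`,
#'   `gamma`, `kappa`, `beta`.
#' @param T decode window in seconds.
#' @param n_grid likelihood grid resolution.
#' @return scalar log likelihood.
#' @export
loglik_popcode <- function(trials, par, T = 0.1, n_grid = FIT_GRID) {
  par <- as.list(par)
  cc <- fit_contrast(trials)
  uc <- sort(unique(cc))
  g <- stats::plogis(par$alpha * (log(uc) - log(par$sigma_c)))
  xi <- par$gamma * T * g
  grid <- circle_grid(n_grid)
  dens <- error_density_multi(xi, par$kappa, par$beta, grid)
  ll <- 0
  for (j in seq_along(uc)) {
    err <- trials$error[cc == uc[j]]
    p <- interp_circular(grid, dens[, j], err)
    ll <- ll + sum(log(pmax(p, DENS_FLOOR)))
  }
  ll
}

# information criteria
aicc_of <- function(ll, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
bic_of <- function(ll, k, n) -2 * ll + k * log(n)

new_fit_result <- function(model, parameters, ll, k, n, converged,
                           trace = NULL, notes = character()) {
  structure(list(model = model, parameters = parameters,
                 log_likelihood = ll, n_params = k, n_trials = n,
                 aicc = aicc_of(ll, k, n), bic = bic_of(ll, k, n),
                 converged = converged, trace = trace, notes = notes),
            class = "popcode_fit")
}

#' @exportS3Method base::print
print.popcode_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%d trials)\n", x$model, x$n_trials))
  p <- unlist(x$parameters)
  cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "), "\n")
  cat(sprintf("  logLik = %.2f, k = %d, AICc = %.2f, BIC = %.2f, converged: %s\n",
              x$log_likelihood, x$n_params, x$aicc, x$bic, x$converged))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Moment-based initializer for the five-parameter model: per-level circular
# precision inverted to expected counts through the high-gain limit
# (precision ~ kappa * A(kappa) * xi), then a Naka-Rushton profile pushed
# through the level contrasts.
init_popcode <- function(trials, T) {
  cc <- fit_contrast(trials)
  uc <- sort(unique(cc))
  prec <- vapply(uc, function(u) {
    p <- circ_precision(trials$error[cc == u])
    if (!is.finite(p)) 50 else p
  }, numeric(1))
  kappa0 <- 2
  xi0 <- pmax(prec / (kappa0 * bessel_A1(kappa0)), 0.02)
  gamma0 <- max(xi0) / T / 0.9
  g0 <- pmin(pmax(xi0 / (gamma0 * T), 0.01), 0.99)
  mid <- which.min(abs(g0 - 0.5))
  sigma0 <- uc[mid]
  alpha0 <- 6
  usable <- g0 > 0.05 & g0 < 0.95
  if (sum(usable) >= 2) {
    fitl <- stats::lm(stats::qlogis(g0[usable]) ~ log(uc[usable]))
    a <- unname(stats::coef(fitl)[2])
    if (is.finite(a) && a > 0.5) {
      alpha0 <- min(a, 100)
      sigma0 <- exp(-unname(stats::coef(fitl)[1]) / alpha0)
    }
  }
  top <- cc == max(uc)
  b0 <- circ_resultant(trials$error[top])$mean_angle
  if (is.na(b0)) b0 <- 0
  list(sigma_c = sigma0, alpha = alpha0, gamma = gamma0, kappa = kappa0,
       beta = b0)
}

#' Fit the population-coding model by maximum likelihood
#'
#' Nelder-Mead maximization of [loglik_popcode()] over the five parameters
#' (`sigma_c`, `alpha`, `gamma`, `kappa`, `beta`), with positivity enforced
#' by log transforms and multiple starts jittered around a moment-based
#' initializer. The best start is returned.
#'
#' If the trials contain no contrast variation, only the expected count is
#' identifiable and the contrast-response parameters are flagged in `notes`.
#'
#' @inheritParams loglik_popcode
#' @param init optional named list of starting values (as in `par`).
#' @param n_starts number of Nelder-Mead starts.
#' @param maxit maximum iterations per start.
#' @param jitter_sd log-scale SD of the multi-start jitter.
#' @return a `popcode_fit` object; `parameters` holds the estimates,
#'   `converged` is `TRUE` if the best start converged.
#' @export
fit_popcode <- function(trials, init = NULL, n_starts = 3L, maxit = 600L,
                        jitter_sd = 0.3, T = 0.1, n_grid = FIT_GRID) {
  n <- nrow(trials)
  stopifnot(n > 0)
  notes <- character()
  if (length(unique(fit_contrast(trials))) < 2L)
    notes <- c(notes, "single contrast level: alpha and sigma_c unidentifiable")
  if (is.null(init)) init <- init_popcode(trials, T)
  # bias bounded to (-pi/2, pi/2): response biases are small fractions of
  # the circle; an unbounded bias can drift to the antipode on flat regions
  to_par <- function(v) list(sigma_c = exp(v[1]), alpha = exp(v[2]),
                             gamma = exp(v[3]), kappa = exp(v[4]),
                             beta = pi / 2 * tanh(v[5]))
  nll <- function(v) {
    p <- to_par(v)
    if (p$alpha > 500 || p$kappa > 100 || p$gamma > 1e6) return(1e10)
    -loglik_popcode(trials, p, T = T, n_grid = n_grid)
  }
  v0 <- c(log(init$sigma_c), log(init$alpha), log(init$gamma),
          log(init$kappa), atanh(max(min(init$beta / (pi / 2), 0.95), -0.95)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    vs <- if (s == 1) v0 else
      v0 + c(stats::rnorm(4, 0, jitter_sd), stats::rnorm(1, 0, 0.1))
    o <- stats::optim(vs, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(best) || o$value < best$value) best <- o
  }
  new_fit_result("popcode", to_par(best$par), -best$value, 5L, n,
                 converged = best$convergence == 0,
                 trace = list(value = best$value, counts = best$counts),
                 notes = notes)
}

#' Fit the threshold ("seen / unseen") observer model
#'
#' Mixture model in which each trial is seen with contrast-dependent
#' probability `p_c` (error then Von Mises with SD `sigma_seen` and bias
#' `beta`) or unseen (error uniform):
#' \eqn{p_c \mathrm{VM}(\Delta\theta; \beta, \sigma_{seen}) +
#' (1 - p_c)/(2\pi)}. One mixing weight per contrast level; `sigma_seen` and
#' `beta` shared. Fitted by Nelder-Mead with logit-transformed weights.
#'
#' @inheritParams fit_popcode
#' @return a `popcode_fit` with parameters `sigma_seen`, `beta`, and `p`
#'   (named vector, one per contrast level in increasing order).
#' @export
fit_threshold_model <- function(trials, n_starts = 2L, maxit = 1000L) {
  cc <- trials$contrast_rel
  uc <- sort(unique(cc))
  lev <- match(cc, uc)
  n <- nrow(trials)
  nll <- function(v) {
    sig <- exp(v[1]); b <- v[2]; p <- stats::plogis(v[-(1:2)])
    if (sig < 0.02 || sig > 10) return(1e10)
    kap <- sigma_to_kappa(sig)
    dv <- dvm(trials$error, b, kap)
    lik <- p[lev] * dv + (1 - p[lev]) / (2 * pi)
    -sum(log(pmax(lik, DENS_FLOOR)))
  }
  # moment start: mixing weight from the resultant length per level
  p0 <- vapply(uc, function(u) {
    min(max(circ_resultant(trials$error[cc == u])$mean_length * 1.2, 0.05),
        0.95)
  }, numeric(1))
  v0 <- c(log(0.4), 0, stats::qlogis(p0))
  best <- NULL
  for (s in seq_len(n_starts)) {
    vs <- if (s == 1) v0 else v0 + stats::rnorm(length(v0), 0, 0.3)
    o <- stats::optim(vs, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- stats::plogis(best$par[-(1:2)])
  names(p) <- paste0("p_", format(uc, trim = TRUE))
  notes <- if (max(p) < 0.05)
    "all mixing weights ~0: sigma_seen unidentifiable" else character()
  new_fit_result("threshold", list(sigma_seen = exp(best$par[1]),
                                   beta = best$par[2], p = p),
                 -best$value, 2L + length(uc), n,
                 converged = best$convergence == 0, notes = notes)
}

#' Fit the two-stage (normal perception + population code) model
#'
#' The stimulus is first perceived with circular normal error whose SD
#' `sigma_c` depends on contrast, then encoded and decoded by the population
#' model with shared expected count `xi` and tuning `kappa`. The predicted
#' error density at each contrast is the circular convolution of
#' VM(0, sigma_c) with the population error density, shifted by the bias
#' `beta`. Seven parameters: one `sigma` per contrast level, plus `beta`,
#' `kappa`, `xi`.
#'
#' @inheritParams fit_popcode
#' @return a `popcode_fit` with parameters `sigma` (per level), `beta`,
#'   `kappa`, `xi`.
#' @export
fit_two_stage <- function(trials, n_starts = 2L, maxit = 800L,
                          n_grid = FIT_GRID) {
  cc <- trials$contrast_rel
  uc <- sort(unique(cc))
  nl <- length(uc)
  lev <- match(cc, uc)
  n <- nrow(trials)
  # FFT circular convolution requires a grid whose first point is angle 0,
  # otherwise the result is rotated by the grid origin
  step <- 2 * pi / n_grid
  grid <- (seq_len(n_grid) - 1L) * step
  nll <- function(v) {
    sig <- exp(v[seq_len(nl)]); b <- pi / 2 * tanh(v[nl + 1])
    kap <- exp(v[nl + 2]); xi <- exp(v[nl + 3])
    if (kap > 100 || xi > 500 || any(sig > 20) || any(sig < 0.02)) return(1e10)
    ed <- error_density_multi(xi, kap, 0, grid)[, 1]
    fed <- stats::fft(ed)
    ll <- 0
    for (j in seq_len(nl)) {
      vm <- dvm(grid, 0, sigma_to_kappa(sig[j]))
      dens <- Re(stats::fft(stats::fft(vm) * fed, inverse = TRUE)) /
        n_grid * step
      dens <- pmax(dens, 0)
      dens <- dens / (sum(dens) * step)
      # convolution computed for the unshifted error; evaluate at err - beta
      err <- trials$error[lev == j]
      p <- interp_circular(grid, dens, err - b)
      ll <- ll + sum(log(pmax(p, DENS_FLOOR)))
    }
    -ll
  }
  prec <- vapply(uc, function(u) {
    p <- circ_precision(trials$error[cc == u]); if (is.finite(p)) p else 50
  }, numeric(1))
  sig0 <- pmin(pmax(1 / sqrt(pmax(prec, 0.05)), 0.05), 5)
  v0 <- c(log(sig0), 0, log(8), log(10))
  best <- NULL
  for (s in seq_len(n_starts)) {
    vs <- if (s == 1) v0 else v0 + stats::rnorm(length(v0), 0, 0.3)
    o <- stats::optim(vs, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(best) || o$value < best$value) best <- o
  }
  v <- best$par
  sig <- exp(v[seq_len(nl)])
  names(sig) <- paste0("sigma_", format(uc, trim = TRUE))
  new_fit_result("two_stage",
                 list(sigma = sig, beta = pi / 2 * tanh(v[nl + 1]),
                      kappa = exp(v[nl + 2]), xi = exp(v[nl + 3])),
                 -best$value, nl + 3L, n,
                 converged = best$convergence == 0)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `popcode_fit`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string (invisibly if written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "popcode_fit"))
  s <- jsonlite::toJSON(
    fit[c("model", "parameters", "log_likelihood", "n_params", "n_trials",
          "aicc", "bic", "converged", "notes")],
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Compare fitted models by information criteria
#'
#' AICc (\eqn{-2LL + 2k + 2k(k+1)/(n-k-1)}) and BIC (\eqn{-2LL + k\ln n})
#' for a set of fits on the *same* trials, with deltas relative to the best
#' (smallest) value of each criterion.
#'
#' @param fits list of `popcode_fit` objects fitted to the identical trial
#'   set.
#' @return data.frame with one row per model: `model`, `k`, `logLik`,
#'   `aicc`, `bic`, `delta_aicc`, `delta_bic`.
#' @export
compare_models <- function(fits) {
  n <- vapply(fits, function(f) f$n_trials, numeric(1))
  if (length(unique(n)) != 1L)
    stop("fits must be on the identical trial set", call. = FALSE)
  d <- data.frame(model = vapply(fits, function(f) f$model, character(1)),
                  k = vapply(fits, function(f) f$n_params, numeric(1)),
                  logLik = vapply(fits, function(f) f$log_likelihood, numeric(1)),
                  aicc = vapply(fits, function(f) f$aicc, numeric(1)),
                  bic = vapply(fits, function(f) f$bic, numeric(1)))
  d$delta_aicc <- d$aicc - min(d$aicc, na.rm = TRUE)
  d$delta_bic <- d$bic - min(d$bic, na.rm = TRUE)
  d
}

#' Parameter-recovery and model-comparison experiment
#'
#' Generates replicate synthetic datasets from the population-coding model
#' at the supplied generating parameters (contrast levels at fixed multiples
#' of the model's own detection threshold, equal trials per level), fits the
#' requested models to each replicate, and collects recovered parameters and
#' information criteria. This is the package's standard harness for checking
#' that the fitting machinery recovers known ground truth and that model
#' selection identifies the generating model.
#'
#' @param n_rep number of replicate datasets.
#' @param n_per_level trials per contrast level.
#' @param params generating [population_params].
#' @param contrast_rel contrast levels as multiples of the detection
#'   threshold.
#' @param models character subset of `c("popcode", "threshold",
#'   "two_stage")`.
#' @param seed integer seed for the experiment.
#' @param ... passed to [fit_popcode()].
#' @return data.frame with one row per replicate: recovered `gamma_hat`,
#'   `kappa_hat`, `beta_hat`, plus `aicc_<model>` columns for each fitted
#'   model.
#' @export
parameter_recovery <- function(n_rep = 20L, n_per_level = 400L,
                               params = population_params(beta = -0.05),
                               contrast_rel = c(0.5, 1, 2, 4),
                               models = "popcode", seed = 1L, ...) {
  thr <- threshold_closed_form(params)
  set.seed(seed)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cvec <- rep(contrast_rel * thr, each = n_per_level)
    sim <- simulate_popcode_trials(params, cvec)
    trials <- data.frame(subject = 1L, theta = sim$theta, report = sim$report,
                         error = sim$error,
                         contrast_rel = rep(contrast_rel, each = n_per_level),
                         contrast_abs = cvec)
    row <- list(rep = r)
    if ("popcode" %in% models) {
      f <- fit_popcode(trials, ...)
      row$gamma_hat <- f$parameters$gamma
      row$kappa_hat <- f$parameters$kappa
      row$beta_hat <- f$parameters$beta
      row$aicc_popcode <- f$aicc
    }
    if ("threshold" %in% models)
      row$aicc_threshold <- fit_threshold_model(trials)$aicc
    if ("two_stage" %in% models)
      row$aicc_two_stage <- fit_two_stage(trials)$aicc
    rows[[r]] <- as.data.frame(row)
  }
  do.call(rbind, rows)
}
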