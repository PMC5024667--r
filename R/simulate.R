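#' Simulate encode/decode trials in bulk
#'
#' Full Monte Carlo of the population-coding model (zero baseline): for each
#' trial, Poisson spike counts are drawn for all `M` neurons at the rates
#' set by the stimulus orientation and contrast, the orientation is decoded
#' as the resultant direction of the spikes' preferred orientations, the
#' response bias is applied, and the posterior precision is computed in
#' closed form (the posterior for `eta = 0` is Von Mises with concentration
#' \eqn{\kappa |\sum_i n_i e^{i\phi_i}|}). Zero-count trials are uniform
#' random guesses with precision 0.
#'
#' @param params a [population_params] object with `eta = 0`.
#' @param contrast per-trial contrasts (vector, recycled against `theta`).
#' @param theta per-trial stimulus orientations in radians; drawn uniformly
#'   on the circle if omitted.
#' @param chunk trials processed per block (memory control).
#' @return data.frame with one row per trial: `theta`, `contrast`,
#'   `theta_map`, `report`, `error` (report minus stimulus, wrapped),
#'   `total_count`, `posterior_precision`, `guessed`.
#' @export
simulate_popcode_trials <- function(params, contrast, theta = NULL,
                                    chunk = 20000L) {
  if (params$eta != 0)
    stop("bulk simulator requires eta = 0; use decode_map() for the baseline model",
         call. = FALSE)
  n <- max(length(contrast), length(theta))
  contrast <- rep_len(contrast, n)
  if (is.null(theta)) theta <- stats::runif(n, -pi, pi)
  theta <- rep_len(theta, n)
  phi <- params$preferred
  cphi <- cos(phi); sphi <- sin(phi)
  g <- contrast_response(contrast, params)
  amp <- g * params$gamma * params$T / params$M  # per-neuron scale
  out_map <- numeric(n); out_m <- integer(n); out_prec <- numeric(n)
  out_guess <- logical(n)
  lI0 <- log_I0(params$kappa)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    nc <- length(idx)
    rateT <- exp(params$kappa * cos(outer(phi, theta[idx], "-")) - lI0) *
      rep(amp[idx], each = params$M)
    counts <- matrix(stats::rpois(params$M * nc, rateT), params$M, nc)
    C <- as.numeric(crossprod(counts, cphi))
    S <- as.numeric(crossprod(counts, sphi))
    m <- colSums(counts)
    rn <- sqrt(C^2 + S^2)
    guess <- m == 0L | rn < 1e-12
    map <- atan2(S, C)
    if (any(guess)) map[guess] <- stats::runif(sum(guess), -pi, pi)
    conc <- params$kappa * rn
    prec <- numeric(nc)
    ok <- !guess & conc > 0
    prec[ok] <- 1 / (-2 * log(bessel_A1(conc[ok])))
    out_map[idx] <- map; out_m[idx] <- m; out_prec[idx] <- prec
    out_guess[idx] <- guess
  }
  report <- wrap_angle(out_map + params$beta)
  data.frame(theta = theta, contrast = contrast, theta_map = out_map,
             report = report, error = circ_diff(report, theta),
             total_count = out_m, posterior_precision = out_prec,
             guessed = out_guess)
}
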