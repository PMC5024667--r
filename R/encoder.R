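#' Parameters of the idealized orientation-coding population
#'
#' Container for the neural model: `M` neurons with Von Mises tuning curves
#' of concentration `kappa`, preferred orientations evenly spaced on
#' \eqn{(-\pi, \pi]}, multiplicative contrast gain given by a Naka-Rushton
#' (hyperbolic-ratio) function with slope `alpha` and semi-saturation
#' contrast `sigma_c`, total population gain `gamma` (spikes/s at full
#' contrast), decoder response bias `beta` (radians), decoding window `T`
#' (seconds), and per-neuron baseline rate `eta` (spikes/s).
#'
#' The tuning curves are normalized as
#' \eqn{f_i(\theta) = \gamma\, e^{\kappa\cos(\theta - \phi_i)} /
#' (M I_0(\kappa))}, so that the stimulus-driven rate summed over the
#' population equals \eqn{\gamma\, g(c)} independent of `kappa` and `M`
#' (exactly in the continuum limit, to < 0.5% for `M >= 100`,
#' `kappa <= 10`). This makes `gamma` directly interpretable as the
#' population gain, and the expected total spike count
#' \eqn{\xi = T(\gamma g(c) + M\eta)} exact.
#'
#' @param M number of neurons (>= 1).
#' @param gamma population gain, spikes/s (>= 0).
#' @param kappa tuning concentration (>= 0), on the doubled orientation
#'   circle.
#' @param alpha contrast-response slope (> 0).
#' @param sigma_c contrast-response semi-saturation constant (> 0), in the
#'   same units as the contrasts passed to the encoder.
#' @param beta response bias, radians.
#' @param T decode window, seconds.
#' @param eta baseline rate per neuron, spikes/s (>= 0).
#' @return object of class `population_params`.
#' @export
#' @examples
#' pp <- population_params(gamma = 145, kappa = 2.4,
#'                         alpha = 48.2, sigma_c = 0.096, beta = -0.05)
#' pp
population_params <- function(M = 100L, gamma = 145, kappa = 2.4,
                              alpha = 48.2, sigma_c = 0.096, beta = 0,
                              T = 0.1, eta = 0) {
  stopifnot(M >= 1, gamma >= 0, kappa >= 0, alpha > 0, sigma_c > 0,
            T > 0, eta >= 0)
  M <- as.integer(M)
  p <- list(M = M, gamma = gamma, kappa = kappa, alpha = alpha,
            sigma_c = sigma_c, beta = beta, T = T, eta = eta,
            preferred = wrap_angle(seq_len(M) * 2 * pi / M - pi))
  class(p) <- "population_params"
  p
}

#' @exportS3Method base::print
print.population_params <- function(x, ...) {
  cat("Population coding parameters\n")
  cat(sprintf("  M = %d neurons, gain gamma = %.3g Hz, tuning kappa = %.3g\n",
              x$M, x$gamma, x$kappa))
  cat(sprintf("  contrast response: alpha = %.3g, sigma_c = %.3g\n",
              x$alpha, x$sigma_c))
  cat(sprintf("  bias beta = %.3g rad, window T = %.3g s, baseline eta = %.3g Hz\n",
              x$beta, x$T, x$eta))
  invisible(x)
}

#' Serialize population parameters to and from JSON
#'
#' @param params a [population_params] object.
#' @param path optional file path; if omitted the JSON string is returned
#'   (`params_to_json`) or `json` is parsed as a string (`params_from_json`).
#' @param json JSON string or file path.
#' @return `params_to_json`: JSON string (invisibly if written to file);
#'   `params_from_json`: a [population_params] object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "population_params"))
  x <- params[c("M", "gamma", "kappa", "alpha", "sigma_c", "beta", "T", "eta")]
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' @rdname params_to_json
#' @export
params_from_json <- function(json) {
  x <- if (length(json) == 1L && file.exists(json)) jsonlite::fromJSON(json)
       else jsonlite::fromJSON(json)
  do.call(population_params, x)
}

#' Contrast response function
#'
#' Multiplicative gain \eqn{g(c) = c^\alpha / (c^\alpha + \sigma_c^\alpha)}:
#' a hyperbolic ratio (Naka-Rushton), equivalently a logistic function of log
#' contrast, with semi-saturation at `sigma_c` (`g(sigma_c) = 0.5`) and slope
#' controlled by `alpha`. Monotone increasing from `g(0) = 0` towards 1.
#'
#' @param c nonnegative contrast(s).
#' @param params a [population_params] object.
#' @return gain factor(s) in `[0, 1]`.
#' @export
contrast_response <- function(c, params) {
  if (any(c < 0)) stop("contrast must be nonnegative", call. = FALSE)
  out <- numeric(length(c))
  pos <- c > 0
  # logistic in log contrast; stable for extreme alpha
  out[pos] <- stats::plogis(params$alpha * (log(c[pos]) - log(params$sigma_c)))
  out
}

#' Mean firing rates of the population
#'
#' Rate of neuron i to a stimulus at orientation `theta` and contrast `c`:
#' \eqn{r_i = \eta + g(c)\,\gamma\, e^{\kappa\cos(\theta - \phi_i)} /
#' (M I_0(\kappa))} spikes/s.
#'
#' @param theta stimulus orientation, radians on the doubled circle.
#' @param c stimulus contrast (scalar).
#' @param params a [population_params] object.
#' @return numeric vector of `M` nonnegative rates, spikes/s.
#' @export
mean_rates <- function(theta, c, params) {
  g <- contrast_response(c, params)
  params$eta + g * params$gamma *
    exp(params$kappa * cos(theta - params$preferred) - log_I0(params$kappa)) /
    params$M
}

#' Expected total spike count in the decode window
#'
#' \eqn{\xi = T(\gamma g(c) + M \eta)}: the Poisson mean of the summed
#' population count; for \eqn{\eta = 0}, \eqn{\xi = \gamma T g(c)}.
#'
#' @inheritParams mean_rates
#' @return expected total count (dimensionless).
#' @export
expected_total <- function(c, params) {
  params$T * (params$gamma * contrast_response(c, params) +
                params$M * params$eta)
}

#' Sample a population spike vector
#'
#' Independent homogeneous Poisson spiking: neuron i emits
#' `Poisson(rate_i * T)` spikes in the decode window. The summed count is
#' therefore itself Poisson with mean [expected_total()].
#'
#' @inheritParams mean_rates
#' @return object of class `spike_vector`: list with integer `counts`
#'   (length `M`) and `total`.
#' @export
sample_spikes <- function(theta, c, params) {
  counts <- stats::rpois(params$M, mean_rates(theta, c, params) * params$T)
  structure(list(counts = counts, total = sum(counts)),
            class = "spike_vector")
}

#' @exportS3Method base::print
print.spike_vector <- function(x, ...) {
  cat(sprintf("spike_vector: %d spikes over %d neurons\n",
              x$total, length(x$counts)))
  invisible(x)
}
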