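# Default grid size for numeric posterior evaluation.
POSTERIOR_GRID <- 1024L

# Midpoint grid on (-pi, pi]: n cell centers, cell width 2*pi/n. Symmetric
# under negation, so symmetric densities stay symmetric after discretization.
circle_grid <- function(n) {
  -pi + (seq_len(n) - 0.5) * 2 * pi / n
}

#' MAP decoding of a population spike vector
#'
#' Maximum a posteriori decoding under a uniform prior (= maximum
#' likelihood). For zero baseline activity the log likelihood of orientation
#' \eqn{\theta} given counts \eqn{n_i} is, up to a constant,
#' \eqn{\kappa \sum_i n_i \cos(\theta - \phi_i)}, which is maximized at the
#' resultant direction of the spikes' preferred orientations (each spike
#' contributing one unit vector at its neuron's preferred orientation). With
#' baseline activity (`eta > 0`) no closed form exists and the decoder
#' evaluates the log likelihood on a grid.
#'
#' When no spikes occur, or the resultant cancels exactly (the analogue of a
#' likelihood tie), the decoded orientation is drawn uniformly at random and
#' flagged as a guess. Grid ties are likewise broken at random.
#'
#' @param spikes a `spike_vector` (or bare integer vector of counts).
#' @param c stimulus contrast; only needed when `eta > 0` (the likelihood
#'   then depends on the stimulus-driven rate scale).
#' @param params a [population_params] object.
#' @param n_grid grid size for the `eta > 0` path and the posterior
#'   precision.
#' @return object of class `decode_result`: list with `theta_map` (decoded
#'   orientation), `report` (`theta_map` plus bias `beta`, wrapped),
#'   `total_count`, `posterior_precision` (1/sigma^2 of the posterior; 0 for
#'   a uniform posterior), and `guessed`.
#' @export
decode_map <- function(spikes, params, c = 1, n_grid = POSTERIOR_GRID) {
  counts <- if (inherits(spikes, "spike_vector")) spikes$counts else spikes
  if (length(counts) != params$M)
    stop("spike vector length does not match params$M", call. = FALSE)
  m <- sum(counts)
  guessed <- FALSE
  if (params$eta == 0) {
    C <- sum(counts * cos(params$preferred))
    S <- sum(counts * sin(params$preferred))
    rnorm_ <- sqrt(C^2 + S^2)
    if (m == 0 || rnorm_ < 1e-12) {
      theta_map <- stats::runif(1, -pi, pi)
      guessed <- TRUE
      prec <- 0
    } else {
      theta_map <- atan2(S, C)
      conc <- params$kappa * rnorm_
      s2 <- -2 * log(bessel_A1(conc))
      prec <- if (conc <= 0) 0 else 1 / s2
    }
  } else {
    grid <- circle_grid(n_grid)
    ll <- spike_loglik_grid(counts, params, c, grid)
    mx <- max(ll)
    top <- which(ll >= mx - 1e-12)
    idx <- if (length(top) > 1L) {
      guessed <- TRUE
      top[sample.int(length(top), 1L)]
    } else top
    theta_map <- grid[idx]
    if (m == 0) {
      theta_map <- stats::runif(1, -pi, pi)
      guessed <- TRUE
      prec <- 0
    } else {
      dens <- exp(ll - mx)
      dens <- dens / (sum(dens) * 2 * pi / n_grid)
      prec <- posterior_precision(dens, grid)
    }
  }
  structure(list(theta_map = theta_map,
                 report = wrap_angle(theta_map + params$beta),
                 total_count = m,
                 posterior_precision = prec,
                 guessed = guessed),
            class = "decode_result")
}

#' @exportS3Method base::print
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: theta_map = %.4f rad (report %.4f), m = %d, precision = %.3g%s\n",
              x$theta_map, x$report, x$total_count, x$posterior_precision,
              if (x$guessed) ", guessed" else ""))
  invisible(x)
}

# log p(n | theta) over a grid, up to an additive constant. The sum-of-rates
# term is constant in theta under dense uniform coverage and is dropped.
spike_loglik_grid <- function(counts, params, c, grid) {
  active <- which(counts > 0)
  if (length(active) == 0L) return(rep(0, length(grid)))
  g <- contrast_response(c, params)
  amp <- g * params$gamma / params$M
  # rate_i(theta) = eta + amp * exp(kappa*cos(theta - phi_i) - logI0)
  lograte <- log(params$eta + amp *
    exp(params$kappa * cos(outer(grid, params$preferred[active], "-")) -
          log_I0(params$kappa)))
  as.numeric(lograte %*% counts[active])
}

#' Posterior density of orientation given spikes
#'
#' The decoder's posterior \eqn{p(\theta \mid \mathbf n)} over a uniform
#' grid, proportional to \eqn{\exp(\sum_i n_i \log f_i(\theta))} with the
#' count-independent term dropped. For `eta = 0` this reduces to a Von Mises
#' with concentration \eqn{\kappa\,|\sum_i n_i e^{i\phi_i}|} centered on the
#' resultant direction. For zero total count the posterior is uniform.
#'
#' @inheritParams decode_map
#' @param grid numeric vector of grid points covering \eqn{(-\pi, \pi]}
#'   uniformly (defaults to a 1024-point midpoint grid).
#' @return numeric density values over `grid`, integrating to 1.
#' @export
posterior_density <- function(spikes, params, c = 1,
                              grid = circle_grid(POSTERIOR_GRID)) {
  counts <- if (inherits(spikes, "spike_vector")) spikes$counts else spikes
  n <- length(grid)
  if (sum(counts) == 0) return(rep(1 / (2 * pi), n))
  ll <- if (params$eta == 0) {
    C <- sum(counts * cos(params$preferred))
    S <- sum(counts * sin(params$preferred))
    params$kappa * sqrt(C^2 + S^2) * cos(grid - atan2(S, C))
  } else {
    spike_loglik_grid(counts, params, c, grid)
  }
  dens <- exp(ll - max(ll))
  dens / (sum(dens) * 2 * pi / n)
}

#' Precision of a gridded circular density
#'
#' Treats the density as a distribution on the circle and returns
#' \eqn{1/\sigma^2}, where \eqn{\sigma} is its Fisher circular SD computed
#' from the mean resultant length of the gridded mass. Returns 0 for a
#' (numerically) uniform density.
#'
#' @param density nonnegative density values over `grid` (need not be
#'   normalized; they are treated as weights).
#' @param grid uniform grid on \eqn{(-\pi, \pi]}.
#' @return nonnegative precision (possibly `Inf` for a point mass).
#' @export
posterior_precision <- function(density, grid) {
  rbar <- circ_resultant(grid, w = density)$mean_length
  if (rbar < 1e-10) return(0)
  if (rbar >= 1) return(Inf)
  1 / (-2 * log(rbar))
}
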