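#' Wrap angles into (-pi, pi]
#'
#' All angular quantities in this package live on the circle \eqn{(-\pi, \pi]},
#' the doubled orientation space. The boundary \eqn{-\pi} maps to \eqn{\pi}.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, wrapped into \eqn{(-\pi, \pi]}.
#' @export
#' @examples
#' wrap_angle(c(3 * pi, -pi, 0.1))
wrap_angle <- function(x) {
  y <- x %% (2 * pi)
  ifelse(y > pi, y - 2 * pi, y)
}

#' Map orientations to the circle and back
#'
#' Orientation is a half-circular variable: gratings at \eqn{\theta} and
#' \eqn{\theta + 180^\circ} are identical. The space of possible orientations
#' \eqn{(-90^\circ, 90^\circ]} is therefore mapped linearly onto the full
#' circle \eqn{(-\pi, \pi]} radians (a factor \eqn{\pi/90}), so that circular
#' statistics apply without modification. `circle_to_orientation` is the
#' inverse map.
#'
#' @param deg orientations in degrees, each in \eqn{(-90, 90]}.
#' @param rad angles in radians (wrapped into \eqn{(-\pi, \pi]} first).
#' @return `orientation_to_circle`: radians in \eqn{(-\pi, \pi]};
#'   `circle_to_orientation`: degrees in \eqn{(-90, 90]}.
#' @export
#' @examples
#' orientation_to_circle(45)           # pi/2
#' circle_to_orientation(pi / 2)       # 45
orientation_to_circle <- function(deg) {
  if (any(!is.finite(deg)) || any(deg < -90) || any(deg > 90))
    stop("orientations must lie in (-90, 90] degrees", call. = FALSE)
  # the boundary -90 is the same orientation as +90 and wraps to +pi
  wrap_angle(deg * pi / 90)
}

#' @rdname orientation_to_circle
#' @export
circle_to_orientation <- function(rad) {
  wrap_angle(rad) * 90 / pi
}

#' Angular difference on the circle
#'
#' Computes \eqn{a \ominus b}, the difference \eqn{a - b} wrapped into
#' \eqn{(-\pi, \pi]}. This is the response error when `a` is the reported and
#' `b` the true orientation (both already on the doubled circle).
#'
#' @param a,b numeric vectors of angles in radians (recycled).
#' @return wrapped differences in \eqn{(-\pi, \pi]}.
#' @export
circ_diff <- function(a, b) wrap_angle(a - b)

#' Resultant vector of a set of angles
#'
#' The (weighted) resultant is \eqn{\sum_j w_j e^{i\theta_j}}. Its normalized
#' length \eqn{\bar R \in [0, 1]} measures concentration and its argument is
#' the circular mean direction. When the resultant is numerically zero
#' (antipodal cancellation) the mean direction is undefined and returned as
#' `NA`.
#'
#' @param angles numeric vector of angles in radians; at least one.
#' @param w optional nonnegative weights, same length as `angles`, not all
#'   zero.
#' @return list with elements `mean_length` (in `[0, 1]`), `mean_angle`
#'   (radians, `NA` if undefined), and `norm` (the unnormalized resultant
#'   length \eqn{|\sum w_j e^{i\theta_j}|}).
#' @export
#' @examples
#' circ_resultant(c(0, pi / 2))  # length sqrt(2)/2, direction pi/4
circ_resultant <- function(angles, w = NULL) {
  if (length(angles) == 0L) stop("at least one angle is required", call. = FALSE)
  if (is.null(w)) w <- rep_len(1, length(angles))
  if (length(w) != length(angles) || any(w < 0) || sum(w) <= 0)
    stop("weights must be nonnegative, match angles in length, and not all be zero",
         call. = FALSE)
  C <- sum(w * cos(angles))
  S <- sum(w * sin(angles))
  norm <- sqrt(C^2 + S^2)
  rbar <- min(norm / sum(w), 1)
  ang <- if (norm < 1e-12) NA_real_ else atan2(S, C)
  list(mean_length = rbar, mean_angle = ang, norm = norm)
}

#' Circular standard deviation and precision (Fisher)
#'
#' Fisher's circular standard deviation \eqn{\sigma = \sqrt{-2 \ln \bar R}},
#' where \eqn{\bar R} is the mean resultant length. Precision is defined as
#' \eqn{1/\sigma^2}. A uniform sample (\eqn{\bar R = 0}) gives
#' \eqn{\sigma = \infty} and precision 0; a degenerate sample (all angles
#' equal) gives \eqn{\sigma = 0} and precision \eqn{\infty}.
#'
#' @inheritParams circ_resultant
#' @return `circ_sd`: nonnegative scalar (possibly `Inf`); `circ_precision`:
#'   nonnegative scalar (possibly `Inf`).
#' @export
circ_sd <- function(angles, w = NULL) {
  rbar <- circ_resultant(angles, w)$mean_length
  if (rbar <= 0) return(Inf)
  sqrt(-2 * log(rbar))
}

#' @rdname circ_sd
#' @export
circ_precision <- function(angles, w = NULL) {
  s <- circ_sd(angles, w)
  if (s == 0) Inf else 1 / s^2
}

#' V test for circular nonuniformity with a specified mean direction
#'
#' The modified Rayleigh (V) test statistic \eqn{V = n \bar R
#' \cos(\bar\theta - \mu_0)} against the hypothesized direction \eqn{\mu_0}.
#' The p-value uses the standard large-sample approximation: \eqn{u =
#' V\sqrt{2/n}} referred to the upper tail of the standard normal.
#'
#' @param angles numeric vector of angles in radians.
#' @param mu0 hypothesized mean direction in radians (0 for response errors).
#' @return list with `V`, `u`, `n`, and `p.value`.
#' @export
v_test <- function(angles, mu0 = 0) {
  n <- length(angles)
  r <- circ_resultant(angles)
  V <- if (is.na(r$mean_angle)) 0 else n * r$mean_length * cos(r$mean_angle - mu0)
  u <- V * sqrt(2 / n)
  list(V = V, u = u, n = n, p.value = stats::pnorm(u, lower.tail = FALSE))
}

# Bessel-function ratios A1 = I1/I0 and A2 = I2/I0 (exponentially scaled for
# numerical stability at large kappa), and log I0.
bessel_A1 <- function(kappa) {
  out <- numeric(length(kappa))
  pos <- kappa > 0
  out[pos] <- besselI(kappa[pos], 1, expon.scaled = TRUE) /
    besselI(kappa[pos], 0, expon.scaled = TRUE)
  out
}

bessel_A2 <- function(kappa) {
  out <- numeric(length(kappa))
  pos <- kappa > 0
  out[pos] <- besselI(kappa[pos], 2, expon.scaled = TRUE) /
    besselI(kappa[pos], 0, expon.scaled = TRUE)
  out
}

log_I0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

#' Convert between Von Mises concentration and circular SD
#'
#' The package-wide convention for translating a Von Mises concentration
#' \eqn{\kappa} into a circular standard deviation is
#' \eqn{\sigma = \sqrt{-2\ln A(\kappa)}} with \eqn{A(\kappa) =
#' I_1(\kappa)/I_0(\kappa)}, i.e. the Fisher circular SD of the VM
#' distribution itself. `sigma_to_kappa` inverts the map numerically.
#'
#' @param kappa nonnegative concentration(s).
#' @param sigma positive circular SD(s) in radians.
#' @return the converted parameter(s).
#' @export
kappa_to_sigma <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be nonnegative", call. = FALSE)
  A <- bessel_A1(kappa)
  ifelse(A <= 0, Inf, sqrt(-2 * log(A)))
}

#' @rdname kappa_to_sigma
#' @export
sigma_to_kappa <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  vapply(sigma, function(s) {
    R <- exp(-s^2 / 2)
    if (R >= 1 - 1e-12) return(1e8)
    # bracket: A(k) is increasing; A(k) ~ k/2 near 0, ~ 1 - 1/(2k) near Inf
    lo <- max(2 * R * 0.5, 1e-10)
    hi <- max(4, 2 / (1 - R))
    while (bessel_A1(hi) < R) hi <- hi * 2
    while (bessel_A1(lo) > R) lo <- lo / 2
    stats::uniroot(function(k) bessel_A1(k) - R, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Von Mises density
#'
#' Density of the Von Mises (circular normal) distribution,
#' \eqn{f(x) = e^{\kappa \cos(x - \mu)} / (2\pi I_0(\kappa))}. At
#' \eqn{\kappa = 0} this is the circular uniform density \eqn{1/(2\pi)}.
#' Evaluated in log space so large concentrations do not overflow.
#'
#' @param x angles in radians.
#' @param mu mean direction in radians.
#' @param kappa nonnegative concentration.
#' @param log logical; return log density?
#' @return numeric vector of (log) densities.
#' @export
dvm <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (any(kappa < 0)) stop("kappa must be nonnegative", call. = FALSE)
  ld <- kappa * cos(x - mu) - log(2 * pi) - log_I0(kappa)
  if (log) ld else exp(ld)
}

#' Sample from the Von Mises distribution
#'
#' Random draws using the Best--Fisher (1979) rejection algorithm, falling
#' back to the circular uniform for very small concentration. Uses the R
#' session RNG stream.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa nonnegative concentration.
#' @return `n` angles in \eqn{(-\pi, \pi]}.
#' @export
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-7) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    need <- n - got
    m <- ceiling(need * 1.3) + 8L
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r0 * z) / (r0 + z)
    cc <- kappa * (r0 - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[keep] - 0.5) * acos(f[keep])
    take <- min(length(th), need)
    if (take > 0) out[(got + 1L):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_angle(out + mu)
}

#' Sample circular kurtosis in excess of a matched Von Mises
#'
#' Fisher's sample circular kurtosis
#' \deqn{\hat k = \frac{\bar R_2 \cos(\hat\mu_2 - 2\hat\mu_1) - \bar R^4}
#'   {(1 - \bar R)^2},}
#' where \eqn{(\bar R_2, \hat\mu_2)} is the second trigonometric moment,
#' minus the same quantity evaluated for the Von Mises distribution matched
#' in circular variance (concentration \eqn{A^{-1}(\bar R)}). Positive values
#' indicate tails heavier than circular normal. Accepts optional weights, so
#' it can be applied to a gridded density as well as to a sample.
#'
#' @inheritParams circ_resultant
#' @return scalar excess kurtosis.
#' @export
circ_kurtosis_excess <- function(angles, w = NULL) {
  if (is.null(w) && length(angles) < 4L)
    stop("at least 4 observations are required", call. = FALSE)
  r1 <- circ_resultant(angles, w)
  if (r1$mean_length > 1 - 1e-8)
    stop("degenerate sample: mean resultant length is ~1", call. = FALSE)
  r2 <- circ_resultant(wrap_angle(2 * angles), w)
  mu1 <- if (is.na(r1$mean_angle)) 0 else r1$mean_angle
  mu2 <- if (is.na(r2$mean_angle)) 0 else r2$mean_angle
  khat <- (r2$mean_length * cos(mu2 - 2 * mu1) - r1$mean_length^4) /
    (1 - r1$mean_length)^2
  # Von Mises reference matched in circular variance: A(kappa) = Rbar
  Rbar <- r1$mean_length
  if (Rbar <= 0) return(khat)  # matched VM is uniform; reference is 0
  kap <- sigma_to_kappa(sqrt(-2 * log(Rbar)))
  kref <- (bessel_A2(kap) - bessel_A1(kap)^4) / (1 - bessel_A1(kap))^2
  khat - kref
}
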