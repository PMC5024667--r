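# Constants of the analytic error-distribution machinery. The resultant
# tables use a fixed internal seed so that likelihood evaluations are
# deterministic and reproducible across sessions; the seed is a documented
# constant, not a user-facing source of randomness.
WALK_M_MAX <- 100L      # Monte Carlo tables cover m <= 100 steps
WALK_BINS <- 1000L      # resultant-length bins per table
WALK_NSIM <- 1e6        # walks simulated per table
WALK_SEED <- 20160907L  # fixed seed for table construction
POIS_TAIL <- 1e-8       # Poisson truncation: keep mass up to 1 - POIS_TAIL

# Validity limit of the tilted tables. Exponential tilting concentrates the
# resultant-length distribution around m*A(kappa), but a Monte Carlo
# histogram of the uniform walk only resolves resultant lengths up to about
# sqrt(m * log(n_sim)) (beyond that the bins are empty and the tilted
# density is noise). Tables are therefore used only while
# m * A(kappa)^2 <= log(n_sim)/2, with a floor so the Gaussian
# approximation is never invoked below m = 6; beyond the limit the Gaussian
# approximation to the resultant-length distribution takes over. Accuracy
# of both branches against the brute-force Von Mises walk is asserted in
# the test suite across this boundary.
walk_m_safe <- function(kappa) {
  A <- bessel_A1(kappa)
  if (A <= 0) return(WALK_M_MAX)
  max(6L, min(WALK_M_MAX, as.integer(floor(log(WALK_NSIM) / 2 / A^2))))
}

# Build (and cache) the uniform-walk resultant tables for m = 1..m_max in a
# single incremental pass: maintain the running vector sum of n_sim walks,
# histogram |sum| at every step. Rows of the returned matrix are the binned
# densities (summing to 1) over bin centers (k - 1/2) * m / n_bins.
walk_table_matrix <- function(m_max = WALK_M_MAX, n_bins = WALK_BINS,
                              n_sim = WALK_NSIM, seed = WALK_SEED) {
  key <- paste("walk", m_max, n_bins, n_sim, seed, sep = "_")
  hit <- .popcode_cache[[key]]
  if (!is.null(hit)) return(hit)
  D <- matrix(0, m_max, n_bins)
  with_seed(seed, {
    C <- numeric(n_sim); S <- numeric(n_sim)
    for (m in seq_len(m_max)) {
      u <- stats::runif(n_sim, -pi, pi)
      C <- C + cos(u); S <- S + sin(u)
      r <- sqrt(C^2 + S^2)
      idx <- pmin(n_bins, pmax(1L, ceiling(r / (m / n_bins))))
      D[m, ] <- tabulate(idx, n_bins) / n_sim
    }
  })
  .popcode_cache[[key]] <- D
  D
}

#' Resultant-length density of a uniform circular random walk
#'
#' Monte Carlo estimate of the distribution of the resultant length
#' \eqn{r = |\sum_{j=1}^m e^{iU_j}|} of `m` unit steps with uniform random
#' directions, discretized over `n_bins` bins on `[0, m]`. Tables for all
#' `m` up to 100 are built in one pass under a fixed internal seed and
#' cached for the session, so repeated calls (and likelihood evaluations
#' that depend on them) are deterministic.
#'
#' @param m number of steps (>= 1).
#' @param n_bins number of resultant-length bins.
#' @param n_sim number of simulated walks.
#' @return object of class `resultant_table`: list with `m`, `bin_centers`
#'   (on `[0, m]`), `density` (bin probabilities summing to 1), `n_sim`, and
#'   `seed`.
#' @export
#' @examples
#' tab <- uniform_walk_resultant(2)
#' sum(tab$density)  # 1
uniform_walk_resultant <- function(m, n_bins = WALK_BINS, n_sim = WALK_NSIM) {
  stopifnot(m >= 1, n_sim >= 1e4)
  m <- as.integer(m)
  D <- walk_table_matrix(max(m, WALK_M_MAX), n_bins, n_sim)
  structure(list(m = m,
                 bin_centers = (seq_len(n_bins) - 0.5) * m / n_bins,
                 density = D[m, ],
                 n_sim = n_sim, seed = WALK_SEED),
            class = "resultant_table")
}

#' Write or read a resultant table as a delimited file
#'
#' Plain-text cache format: a header line recording `m`, bin count, `n_sim`
#' and seed, followed by one `bin_center density` pair per line.
#'
#' @param table a `resultant_table`.
#' @param path file path.
#' @return `read_resultant_table` returns a `resultant_table`.
#' @export
write_resultant_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m=%d n_bins=%d n_sim=%g seed=%d",
                     table$m, length(table$density), table$n_sim, table$seed),
             con)
  utils::write.table(data.frame(r = table$bin_centers, density = table$density),
                     con, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_resultant_table
#' @export
read_resultant_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", hdr), " ")[[1]]))
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(m = as.integer(meta[1]), bin_centers = d$r, density = d$density,
                 n_sim = meta[3], seed = as.integer(meta[4])),
            class = "resultant_table")
}

#' Resultant-length density of a Von Mises random walk
#'
#' Exponential tilting of the uniform-walk resultant density by `m` iid
#' VM(0, kappa) steps (Mardia & Jupp): the walk with concentrated steps has
#' \deqn{p(r \mid m, \kappa) \propto p_0(r \mid m)\, I_0(\kappa r) /
#'   I_0(\kappa)^m,} renormalized over the bins. For `kappa = 0` the uniform
#' table is returned unchanged.
#'
#' @param m number of steps.
#' @param kappa step concentration (>= 0).
#' @param table optional `resultant_table` for the same `m` (built on demand
#'   if omitted).
#' @return a `resultant_table` whose `density` is the tilted, renormalized
#'   distribution of `r`.
#' @export
vm_walk_resultant <- function(m, kappa, table = NULL) {
  if (is.null(table)) table <- uniform_walk_resultant(m)
  stopifnot(table$m == m, kappa >= 0)
  if (kappa == 0) return(table)
  lw <- log(table$density) + log_I0(kappa * table$bin_centers) -
    m * log_I0(kappa)
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(w)] <- 0
  table$density <- w / sum(w)
  table
}

# Gaussian approximation to the resultant-length distribution for large m:
# r ~ Normal(m*A1(kappa), m * (0.5*(1 + A2) - A1^2)), discretized over
# Gauss nodes and truncated to [0, m]. Returns r values and weights.
walk_resultant_normal <- function(m, kappa, n_nodes = 25L) {
  A1 <- bessel_A1(kappa); A2 <- bessel_A2(kappa)
  mu <- m * A1
  v <- m * max(0.5 * (1 + A2) - A1^2, 1e-8)
  z <- seq(-4, 4, length.out = n_nodes)
  r <- mu + sqrt(v) * z
  keep <- r > 0 & r <= m
  w <- stats::dnorm(z)[keep]
  list(r = r[keep], w = w / sum(w))
}

#' Decoding-error density conditional on the total spike count
#'
#' Given `m` spikes, the decoding error is the resultant direction of a Von
#' Mises random walk of `m` steps with step concentration `kappa`;
#' conditional on resultant length `r` the error is VM(0, kappa * r). This
#' function marginalizes the conditional VM over the resultant-length
#' density: the tilted Monte Carlo table while the tilt stays within the
#' table's resolved support (small `m * A(kappa)^2`), the Gaussian
#' approximation to the resultant-length distribution beyond.
#'
#' @param m total spike count (>= 1).
#' @param kappa step (tuning) concentration.
#' @param grid angular grid, defaults to a 360-point midpoint grid on
#'   \eqn{(-\pi, \pi]}.
#' @return density values over `grid`, integrating to 1.
#' @export
error_density_given_m <- function(m, kappa, grid = circle_grid(360L)) {
  stopifnot(m >= 1)
  if (kappa == 0) return(rep(1 / (2 * pi), length(grid)))
  if (m <= walk_m_safe(kappa)) {
    tab <- vm_walk_resultant(m, kappa)
    keep <- tab$density > 1e-12
    r <- tab$bin_centers[keep]; w <- tab$density[keep]
  } else {
    gn <- walk_resultant_normal(m, kappa)
    r <- gn$r; w <- gn$w
  }
  conc <- kappa * r
  K <- exp(outer(cos(grid), conc) - rep(log_I0(conc), each = length(grid))) /
    (2 * pi)
  dens <- as.numeric(K %*% w)
  dens / (sum(dens) * 2 * pi / length(grid))
}

# --- pooled evaluation -----------------------------------------------------
#
# The mixture over m of the per-m conditionals can be evaluated much faster
# by pooling resultant-length mass across m onto one common r grid before
# applying the VM kernel. Used by error_density(method = "pooled") and by
# all likelihood evaluations; agreement with the per-m path is asserted in
# the test suite.

# Log of the per-m walk tables aggregated onto a common r grid of n_bins
# cells on (0, m_hi]; kappa-independent, cached per truncation point.
log_agg_tables <- function(m_hi, m_tab, n_bins, step) {
  key <- paste("agg", m_hi, m_tab, n_bins, sep = "_")
  hit <- .popcode_cache[[key]]
  if (!is.null(hit)) return(hit)
  D <- walk_table_matrix()
  u <- (seq_len(WALK_BINS) - 0.5) / WALK_BINS
  W <- matrix(0, m_tab, n_bins)
  for (m in seq_len(m_tab)) {
    idx <- pmin(n_bins, pmax(1L, ceiling(u * m / step)))
    agg <- rowsum(D[m, ], idx, reorder = FALSE)
    W[m, idx[!duplicated(idx)]] <- agg
  }
  out <- log(W)
  .popcode_cache[[key]] <- out
  out
}

# Internal: densities of the decoding error for one kappa/beta and several
# expected counts xi (one column per xi), sharing the expensive VM kernel.
error_density_multi <- function(xi, kappa, beta, grid) {
  n <- length(grid)
  out <- matrix(0, n, length(xi))
  m_hi <- max(1L, suppressWarnings(stats::qpois(1 - POIS_TAIL, max(xi))))
  if (!is.finite(m_hi)) m_hi <- 1L
  if (all(xi <= 0) || kappa == 0) {
    # zero expected count or flat tuning: uniform error for every m
    out[] <- 1 / (2 * pi)
    return(out)
  }
  m_tab <- min(m_hi, walk_m_safe(kappa))
  r_max <- m_hi  # resultant length cannot exceed the step count
  n_bins <- WALK_BINS
  step <- r_max / n_bins
  rc <- (seq_len(n_bins) - 0.5) * step

  # untilted per-m resultant mass aggregated onto the common grid, in log
  # space; cached per truncation point since it is kappa-independent
  lWagg <- log_agg_tables(m_hi, m_tab, n_bins, step)
  lI0r <- log_I0(kappa * rc)
  lI0k <- log_I0(kappa)
  # exponential tilting, all m at once, normalized per row
  LW <- lWagg + matrix(lI0r, m_tab, n_bins, byrow = TRUE) -
    seq_len(m_tab) * lI0k
  mx <- LW[cbind(seq_len(m_tab), max.col(LW, ties.method = "first"))]
  Wn <- exp(LW - mx)
  Wn[!is.finite(Wn)] <- 0
  Wn <- Wn / rowSums(Wn)
  # Gaussian-approximation mass for larger m, also on the common grid
  if (m_hi > m_tab) {
    extra <- matrix(0, m_hi - m_tab, n_bins)
    for (m in (m_tab + 1L):m_hi) {
      gn <- walk_resultant_normal(m, kappa)
      idx <- pmin(n_bins, pmax(1L, ceiling(gn$r / step)))
      agg <- rowsum(gn$w, idx, reorder = FALSE)
      extra[m - m_tab, idx[!duplicated(idx)]] <- agg
    }
    Wn <- rbind(Wn, extra)
  }
  # shared VM kernel over the common r grid, centered on beta
  conc <- kappa * rc
  K <- exp(outer(cos(grid - beta), conc) -
             rep(lI0r, each = n)) / (2 * pi)
  for (j in seq_along(xi)) {
    if (xi[j] <= 0) { out[, j] <- 1 / (2 * pi); next }
    mj <- max(1L, suppressWarnings(stats::qpois(1 - POIS_TAIL, xi[j])))
    mj <- min(mj, nrow(Wn))
    pm <- stats::dpois(0:mj, xi[j])
    pm <- pm / sum(pm)
    pooled <- as.numeric(crossprod(Wn[seq_len(mj), , drop = FALSE], pm[-1]))
    dens <- pm[1] / (2 * pi) + as.numeric(K %*% pooled)
    out[, j] <- dens / (sum(dens) * 2 * pi / n)
  }
  out
}

#' Analytic distribution of the decoding error
#'
#' The marginal density of the response error \eqn{\Delta\theta} under the
#' population-coding model: a Poisson(\eqn{\xi}) mixture over the total
#' spike count `m` of the per-`m` conditional error densities, plus the
#' zero-count guessing component \eqn{e^{-\xi}/(2\pi)}, shifted by the
#' response bias `beta`. The Poisson sum is truncated at its
#' \eqn{1 - 10^{-8}} quantile. As a mixture of circular normals of different
#' widths, the result is in general *not* circular normal: approximately VM
#' at large \eqn{\xi}, long-tailed at intermediate \eqn{\xi}, approaching
#' uniform as \eqn{\xi \to 0}.
#'
#' @param xi expected total spike count (>= 0).
#' @param kappa tuning concentration (>= 0).
#' @param beta response bias, radians.
#' @param n_grid number of grid points on \eqn{(-\pi, \pi]}.
#' @param method `"pooled"` (fast; pools resultant-length mass across `m`
#'   onto a common grid before applying the Von Mises kernel) or `"per_m"`
#'   (direct mixture of [error_density_given_m()] terms).
#' @return object of class `error_density`: list with `grid`, `density`,
#'   `xi`, `kappa`, `beta`, and `mode = "analytic"`.
#' @export
#' @examples
#' ed <- error_density(xi = 14.5, kappa = 2.4)
#' plot(ed)
error_density <- function(xi, kappa, beta = 0, n_grid = 360L,
                          method = c("pooled", "per_m")) {
  stopifnot(xi >= 0, kappa >= 0)
  method <- match.arg(method)
  grid <- circle_grid(n_grid)
  dens <- if (method == "pooled" || xi == 0 || kappa == 0) {
    error_density_multi(xi, kappa, beta, grid)[, 1]
  } else {
    m_hi <- max(1L, stats::qpois(1 - POIS_TAIL, xi))
    pm <- stats::dpois(0:m_hi, xi)
    pm <- pm / sum(pm)
    d <- pm[1] / (2 * pi)
    for (m in seq_len(m_hi))
      d <- d + pm[m + 1] * error_density_given_m(m, kappa, grid - beta)
    d / (sum(d) * 2 * pi / n_grid)
  }
  structure(list(grid = grid, density = dens, xi = xi, kappa = kappa,
                 beta = beta, mode = "analytic"),
            class = "error_density")
}

#' @exportS3Method base::print
print.error_density <- function(x, ...) {
  cat(sprintf("error_density (%s): xi = %.4g, kappa = %.4g, beta = %.4g, %d grid points\n",
              x$mode, x$xi, x$kappa, x$beta, length(x$grid)))
  invisible(x)
}

#' @export
plot.error_density <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l", xlab = "error (rad)",
                 ylab = "density",
                 main = sprintf("xi = %.3g, kappa = %.3g", x$xi, x$kappa), ...)
  graphics::abline(h = 1 / (2 * pi), lty = 3)
  invisible(x)
}

# Interpolate a gridded circular density at arbitrary angles (periodic
# linear interpolation on the midpoint grid).
interp_circular <- function(grid, density, at) {
  n <- length(grid)
  step <- 2 * pi / n
  x <- wrap_angle(at)
  # position relative to first midpoint
  pos <- (x - grid[1]) / step
  pos <- pos %% n
  i0 <- floor(pos)
  frac <- pos - i0
  i1 <- (i0 %% n) + 1L
  i2 <- ((i0 + 1) %% n) + 1L
  density[i1] * (1 - frac) + density[i2] * frac
}
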