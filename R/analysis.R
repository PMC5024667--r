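#' Response precision by contrast level
#'
#' Fisher circular precision (\eqn{1/\sigma^2}) of response errors at each
#' contrast level, with bootstrap standard errors and a chance reference
#' (the median precision of same-sized uniform samples, i.e. the precision a
#' purely guessing observer would show).
#'
#' @param trials trial data.frame with `error` and `contrast_rel`.
#' @param n_boot bootstrap resamples for the SE.
#' @return data.frame with one row per level: `contrast_rel`, `n`,
#'   `precision`, `se`, `chance`.
#' @export
precision_by_contrast <- function(trials, n_boot = 200L) {
  uc <- sort(unique(trials$contrast_rel))
  rows <- lapply(uc, function(u) {
    err <- trials$error[trials$contrast_rel == u]
    if (length(err) < 2L) {
      warning("contrast level ", u, " has fewer than 2 trials; omitted")
      return(NULL)
    }
    p <- circ_precision(err)
    bs <- replicate(n_boot, circ_precision(sample(err, replace = TRUE)))
    ch <- stats::median(replicate(n_boot,
      circ_precision(stats::runif(length(err), -pi, pi))))
    data.frame(contrast_rel = u, n = length(err), precision = p,
               se = stats::sd(bs[is.finite(bs)]), chance = ch)
  })
  do.call(rbind, rows)
}

#' Deviation of an error distribution from the matched circular normal
#'
#' Bins the errors over \eqn{(-\pi, \pi]} and subtracts the binned
#' probability of the Von Mises distribution matched in circular mean and
#' circular variance (concentration \eqn{A^{-1}(\bar R)}). The long-tail
#' signature of low-gain population coding shows up as positive deviations
#' at the center and tails with negative flanks.
#'
#' @param errors numeric vector of errors in radians (length >= 50).
#' @param n_bins number of histogram bins.
#' @return object of class `deviation_curve`: data.frame with
#'   `bin_center`, `observed`, `matched_vm`, `deviation` (all per-bin
#'   probabilities), and attributes `mu` and `kappa` of the matched VM.
#' @export
deviation_from_normal <- function(errors, n_bins = 25L) {
  stopifnot(length(errors) >= 50L)
  brk <- seq(-pi, pi, length.out = n_bins + 1L)
  obs <- tabulate(findInterval(wrap_angle(errors), brk, rightmost.closed = TRUE,
                               all.inside = TRUE), n_bins) / length(errors)
  r <- circ_resultant(errors)
  mu <- if (is.na(r$mean_angle)) 0 else r$mean_angle
  kap <- if (r$mean_length <= 1e-6) 0 else
    sigma_to_kappa(sqrt(-2 * log(r$mean_length)))
  # VM bin mass by fine-grid quadrature
  fine <- circle_grid(20L * n_bins)
  dv <- dvm(fine, mu, kap) * 2 * pi / length(fine)
  vmb <- as.numeric(rowsum(dv, rep(seq_len(n_bins), each = 20L)))
  out <- data.frame(bin_center = (brk[-1] + brk[-(n_bins + 1L)]) / 2,
                    observed = obs, matched_vm = vmb, deviation = obs - vmb)
  attr(out, "mu") <- mu
  attr(out, "kappa") <- kap
  class(out) <- c("deviation_curve", "data.frame")
  out
}

#' Correlation of confidence ratings with error magnitude
#'
#' For each subject and contrast level, the squared Pearson correlation
#' between the confidence rating (treated as numeric 0-100) and the
#' absolute circular error. Group-level significance per contrast level is
#' assessed with a one-sample t test of Fisher-z-transformed (signed)
#' correlations against zero. Subject-level cells with constant confidence
#' are excluded and counted.
#'
#' @param trials trial data.frame with `subject`, `error`, `contrast_rel`,
#'   `confidence`.
#' @return data.frame with one row per contrast level: `contrast_rel`,
#'   `n_subjects`, `n_excluded`, `mean_r2`, `t`, `df`, `p.value`.
#' @export
confidence_error_correlation <- function(trials) {
  stopifnot("confidence" %in% names(trials))
  uc <- sort(unique(trials$contrast_rel))
  rows <- lapply(uc, function(u) {
    sub <- trials[trials$contrast_rel == u, ]
    rs <- vapply(split(sub, sub$subject), function(d) {
      if (length(unique(d$confidence)) < 2L || nrow(d) < 3L) return(NA_real_)
      stats::cor(d$confidence, abs(d$error))
    }, numeric(1))
    excl <- sum(is.na(rs))
    rs <- rs[!is.na(rs)]
    z <- atanh(pmin(pmax(rs, -0.999), 0.999))
    tt <- if (length(z) >= 2L && stats::sd(z) > 1e-10) stats::t.test(z) else
      list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
    data.frame(contrast_rel = u, n_subjects = length(rs), n_excluded = excl,
               mean_r2 = mean(rs^2), t = unname(tt$statistic),
               df = unname(tt$parameter), p.value = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Median split of trials by a reliability criterion
#'
#' Splits trials at the within-contrast-level median of a criterion
#' (confidence, posterior precision, or total spike count) and computes the
#' Fisher circular precision of response errors in each half. Ties at the
#' median are assigned to halves at random (using the session RNG) so the
#' halves are balanced to within one trial.
#'
#' @param trials trial data.frame with `error`, `contrast_rel`, and the
#'   criterion column.
#' @param criterion column name: `"confidence"`, `"posterior_precision"`, or
#'   `"total_count"` (any numeric column is accepted).
#' @return object of class `split_summary`: data.frame with one row per
#'   level: `contrast_rel`, `n_high`, `n_low`, `precision_high`,
#'   `precision_low`.
#' @export
median_split <- function(trials, criterion = "confidence") {
  stopifnot(criterion %in% names(trials))
  v_all <- trials[[criterion]]
  uc <- sort(unique(trials$contrast_rel))
  rows <- lapply(uc, function(u) {
    sel <- trials$contrast_rel == u
    v <- v_all[sel]; err <- trials$error[sel]
    n <- length(v)
    med <- stats::median(v)
    hi <- v > med; lo <- v < med
    tie <- which(!hi & !lo)
    if (length(tie)) {
      need_hi <- floor(n / 2) - sum(hi)
      tie <- sample(tie)  # random tie assignment, balanced halves
      hi[tie[seq_len(max(need_hi, 0))]] <- TRUE
    }
    data.frame(contrast_rel = u, n_high = sum(hi), n_low = sum(!hi),
               precision_high = circ_precision(err[hi]),
               precision_low = circ_precision(err[!hi]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("split_summary", "data.frame")
  out
}

#' Mean squared difference between two split summaries
#'
#' Compares the high/low precision curves of two [median_split()] results
#' (e.g. a simulated split against the behavioral confidence split), in
#' precision units.
#'
#' @param split,reference `split_summary` objects over the same contrast
#'   levels.
#' @return mean squared difference across levels and halves.
#' @export
split_mse <- function(split, reference) {
  stopifnot(all(split$contrast_rel == reference$contrast_rel))
  mean(c((split$precision_high - reference$precision_high)^2,
         (split$precision_low - reference$precision_low)^2))
}

#' Correlation between total spike count and posterior precision
#'
#' Simulates trials of the population-coding model at the given contrast
#' levels (as multiples of the model's own detection threshold) and returns
#' the squared Pearson correlation between the per-trial total spike count
#' and the per-trial posterior precision, pooled over levels. Total spiking
#' is the readily computable proxy for decoding reliability; this measures
#' how tightly it tracks the ideal quantity.
#'
#' @param params a [population_params] with `eta = 0`.
#' @param contrast_rel contrast levels as multiples of the detection
#'   threshold.
#' @param n_sim simulated trials per level (>= 1e4 recommended).
#' @return list with `r2` and the simulated trials (`trials`).
#' @export
spikecount_posterior_corr <- function(params, contrast_rel = c(0.5, 1, 2, 4),
                                      n_sim = 1e4) {
  thr <- threshold_closed_form(params)
  cvec <- rep(contrast_rel * thr, each = n_sim)
  sim <- simulate_popcode_trials(params, cvec)
  sim$contrast_rel <- rep(contrast_rel, each = n_sim)
  if (stats::sd(sim$total_count) == 0 || stats::sd(sim$posterior_precision) == 0)
    return(list(r2 = NA_real_, trials = sim,
                notes = "degenerate counts: correlation undefined"))
  list(r2 = stats::cor(sim$total_count, sim$posterior_precision)^2,
       trials = sim)
}

#' Anisotropy control: non-normality from orientation-dependent biases
#'
#' Orientation judgments show small biases away from cardinal angles;
#' pooling errors across stimulus orientations could then mimic a
#' non-normal error distribution even if errors at each orientation are
#' normal. This control estimates the circular mean bias and dispersion of
#' the reports in evenly spaced stimulus-orientation bins, resamples
#' synthetic reports from Von Mises distributions with those per-bin
#' parameters, and returns the pooled deviation-from-normality curve of the
#' synthetic errors. If the observed non-normality were an artifact of
#' anisotropy, this curve would match it; in population-coding data it is an
#' order of magnitude smaller.
#'
#' @param trials trial data.frame with `theta`, `report` (radians).
#' @param n_bins number of stimulus-orientation bins.
#' @param n_rep resamples per observed trial.
#' @param n_dev_bins bins for the deviation curve.
#' @return a `deviation_curve` for the resampled errors.
#' @export
anisotropy_control <- function(trials, n_bins = 15L, n_rep = 10L,
                               n_dev_bins = 25L) {
  brk <- seq(-pi, pi, length.out = n_bins + 1L)
  bin <- findInterval(wrap_angle(trials$theta), brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
  err <- circ_diff(trials$report, trials$theta)
  bias <- kap <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    e <- err[bin == b]
    if (length(e) < 2L) next
    r <- circ_resultant(e)
    bias[b] <- if (is.na(r$mean_angle)) 0 else r$mean_angle
    kap[b] <- if (r$mean_length <= 1e-6) 0 else
      sigma_to_kappa(sqrt(-2 * log(r$mean_length)))
  }
  if (any(is.na(bias))) {
    warning("empty stimulus bins inherit neighboring parameters")
    for (b in which(is.na(bias))) {
      nb <- which(!is.na(bias))
      j <- nb[which.min(pmin(abs(nb - b), n_bins - abs(nb - b)))]
      bias[b] <- bias[j]; kap[b] <- kap[j]
    }
  }
  # resample: each trial draws an error from its bin's matched VM
  sim_err <- unlist(lapply(seq_len(n_rep), function(i) {
    out <- numeric(length(bin))
    for (b in seq_len(n_bins)) {
      idx <- which(bin == b)
      if (length(idx)) out[idx] <- rvm(length(idx), bias[b], kap[b])
    }
    out
  }))
  deviation_from_normal(sim_err, n_dev_bins)
}

#' Match the baseline-activity model to the no-baseline model
#'
#' Grid search over (`gamma`, `kappa`) for the population model with
#' baseline rate `eta` such that its simulated error densities at the four
#' study contrast levels best match the no-baseline model's analytic
#' densities, by summed total-variation distance.
#'
#' Both models are evaluated at contrasts expressed as multiples of their
#' *own* detection threshold (closed form for the no-baseline reference,
#' exact Poisson 2AFC arithmetic for each baseline candidate), matching how
#' contrast conditions are defined throughout: as percentages of the model
#' observer's threshold. Candidates whose gain is too low ever to reach 75%
#' correct have no threshold and are excluded (infinite distance).
#'
#' By default the baseline model is read out with the same fixed resultant
#' decoder as the no-baseline model, so background spikes contaminate the
#' estimate (the readout circuit is not assumed to change when background
#' activity is introduced); `decoder = "map"` instead decodes with the
#' baseline-aware likelihood on a grid.
#'
#' @param decoder `"resultant"` (default) or `"map"`, see Details.
#'
#' @param params no-baseline [population_params] (the reference).
#' @param eta baseline rate, spikes/s.
#' @param gamma_mult,kappa_mult multiplicative search grids applied to the
#'   reference `gamma` and `kappa` (defaults: 10 values each, bracketing 1).
#' @param contrast_rel contrast levels as multiples of detection threshold.
#' @param n_sim simulated trials per grid point and level.
#' @param n_grid_decode decoding grid resolution.
#' @param n_bins histogram bins for the total-variation distance.
#' @return list with `gamma_matched`, `kappa_matched`, `distance` (summed
#'   TV at the optimum), and the full `grid` data.frame.
#' @export
match_baseline <- function(params, eta = 1,
                           gamma_mult = c(0.8, 1, 1.5, 2, 2.5, 3, 3.5, 4,
                                          4.5, 5),
                           kappa_mult = seq(0.4, 1.3, by = 0.1),
                           contrast_rel = c(0.5, 1, 2, 4),
                           n_sim = 1e5, n_grid_decode = 360L,
                           n_bins = 60L, decoder = c("resultant", "map")) {
  decoder <- match.arg(decoder)
  stopifnot(params$eta == 0)
  thr <- threshold_closed_form(params)
  # reference: analytic no-baseline densities at its own threshold multiples
  brk <- seq(-pi, pi, length.out = n_bins + 1L)
  ref <- vapply(contrast_rel * thr, function(cc) {
    ed <- error_density(expected_total(cc, params), params$kappa, 0)
    bin_density(ed$grid, ed$density, n_bins)
  }, numeric(n_bins))
  # candidate thresholds depend on gamma only (Poisson totals); computed
  # exactly so threshold noise does not leak into the distance surface
  # (the contrast response is steep: tiny threshold errors would translate
  # into large expected-count errors at the threshold-level contrast)
  gammas <- params$gamma * gamma_mult
  thr_cand <- vapply(gammas, function(gg) {
    pb <- population_params(M = params$M, gamma = gg, kappa = params$kappa,
                            alpha = params$alpha, sigma_c = params$sigma_c,
                            T = params$T, eta = eta)
    threshold_exact(pb, thr * 0.05, thr * 50)
  }, numeric(1))
  grid_pts <- expand.grid(gamma = gammas, kappa = params$kappa * kappa_mult)
  grid_pts$threshold <- thr_cand[match(grid_pts$gamma, gammas)]
  dist <- numeric(nrow(grid_pts))
  for (i in seq_len(nrow(grid_pts))) {
    if (is.na(grid_pts$threshold[i])) { dist[i] <- Inf; next }
    pb <- population_params(M = params$M, gamma = grid_pts$gamma[i],
                            kappa = grid_pts$kappa[i], alpha = params$alpha,
                            sigma_c = params$sigma_c, beta = 0,
                            T = params$T, eta = eta)
    d <- 0
    for (j in seq_along(contrast_rel)) {
      errs <- simulate_baseline_errors(pb, contrast_rel[j] * grid_pts$threshold[i],
                                       n_sim, n_grid_decode, decoder)
      h <- tabulate(findInterval(errs, brk, rightmost.closed = TRUE,
                                 all.inside = TRUE), n_bins) / n_sim
      d <- d + 0.5 * sum(abs(h - ref[, j]))
    }
    dist[i] <- d
  }
  best <- which.min(dist)
  gm <- grid_pts$gamma[best]; km <- grid_pts$kappa[best]
  if (gm %in% range(grid_pts$gamma) || km %in% range(grid_pts$kappa))
    warning("optimum on grid boundary; consider widening the search grid")
  grid_pts$distance <- dist
  list(gamma_matched = gm, kappa_matched = km, distance = dist[best],
       grid = grid_pts)
}

# bin a gridded (midpoint) density into n_bins equal bins over (-pi, pi],
# by linear interpolation of the cumulative mass at the bin edges
bin_density <- function(grid, density, n_bins) {
  n <- length(grid)
  step <- 2 * pi / n
  cell_edges <- seq(-pi, pi, length.out = n + 1L)
  F <- c(0, cumsum(density * step))
  F <- F / F[n + 1L]
  brk <- seq(-pi, pi, length.out = n_bins + 1L)
  diff(stats::approx(cell_edges, F, xout = brk)$y)
}

# Simulate decoding errors of the baseline model at one contrast, stimulus
# fixed at 0 (errors are equivariant). Spikes are drawn via Poisson
# superposition (total ~ Poisson, neurons ~ categorical on the rate
# profile). Decoding: "resultant" applies the same readout as the
# no-baseline model (the resultant direction of the spikes' preferred
# orientations), so background spikes contaminate the estimate; "map"
# decodes with the baseline-aware likelihood by sparse-matrix grid argmax.
simulate_baseline_errors <- function(params, c, n_sim, n_grid = 180L,
                                     decoder = c("resultant", "map")) {
  decoder <- match.arg(decoder)
  rateT <- mean_rates(0, c, params) * params$T
  xi <- sum(rateT)
  m <- stats::rpois(n_sim, xi)
  tot <- sum(m)
  err <- stats::runif(n_sim, -pi, pi)  # zero-count trials guess
  if (tot == 0) return(err)
  neuron <- sample.int(params$M, tot, replace = TRUE, prob = rateT)
  trial <- rep.int(seq_len(n_sim), m)
  has <- m > 0L
  if (decoder == "resultant") {
    C <- S <- numeric(n_sim)
    cs <- rowsum(cbind(cos(params$preferred[neuron]),
                       sin(params$preferred[neuron])), trial)
    idx <- as.integer(rownames(cs))
    C[idx] <- cs[, 1]; S[idx] <- cs[, 2]
    ok <- has & sqrt(C^2 + S^2) >= 1e-12
    err[ok] <- atan2(S[ok], C[ok])
  } else {
    grid <- circle_grid(n_grid)
    counts <- Matrix::sparseMatrix(i = trial, j = neuron, x = 1,
                                   dims = c(n_sim, params$M))
    g <- contrast_response(c, params)
    amp <- g * params$gamma / params$M
    logR <- t(log(params$eta + amp *
      exp(params$kappa * cos(outer(grid, params$preferred, "-")) -
            log_I0(params$kappa))))  # M x n_grid
    ll <- as.matrix(counts %*% logR)
    pick <- max.col(ll, ties.method = "random")
    err[has] <- grid[pick[has]]
  }
  err
}
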