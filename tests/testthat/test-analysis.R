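test_that("precision rises with contrast and uniform errors sit at chance", {
  set.seed(23)
  # moderate contrast-response slope so expected counts are graded across
  # all four levels
  pp <- population_params(gamma = 145, kappa = 2.4, alpha = 3, sigma_c = 0.1)
  thr <- threshold_closed_form(pp)
  sim <- simulate_popcode_trials(pp, rep(c(0.5, 1, 2, 4) * thr, each = 600))
  tr <- data.frame(error = sim$error,
                   contrast_rel = rep(c(0.5, 1, 2, 4), each = 600))
  pc <- precision_by_contrast(tr)
  expect_true(all(diff(pc$precision) > 0))
  tu <- data.frame(error = runif(1000, -pi, pi), contrast_rel = 1)
  pu <- precision_by_contrast(tu)
  expect_lt(pu$precision, 10 * pu$chance)
})

test_that("deviation from the matched circular normal isolates the long-tail signature", {
  set.seed(24)
  # self-match: VM data deviates only by sampling noise
  dv <- deviation_from_normal(rvm(5000, 0.1, 3))
  expect_lt(max(abs(dv$deviation)), 3 * sqrt(0.1 * 0.9 / 5000) * 3)
  expect_lt(abs(sum(dv$deviation)), 1e-10)
  # threshold-regime population errors: positive center and tails,
  # negative flanks
  pp <- group_params(beta = 0)
  err <- simulate_popcode_trials(pp, rep(contrast_for_xi(log(2), pp), 2e4))$error
  dvp <- deviation_from_normal(err)
  nb <- nrow(dvp)
  expect_gt(dvp$deviation[(nb + 1) %/% 2], 0)           # center
  expect_gt(dvp$deviation[1] + dvp$deviation[nb], 0)    # tails
  expect_lt(min(dvp$deviation), 0)                      # flanks
  # uniform errors force a near-flat matched VM and a flat deviation
  dvu <- deviation_from_normal(runif(2e4, -pi, pi))
  expect_lt(max(abs(dvu$deviation)), 0.02)
})

test_that("confidence-error correlations are detected per subject and level", {
  set.seed(25)
  ds <- generate_dataset(synth_config(n_subjects = 8, seed = 77))
  tr <- ds$trials
  # deterministically decreasing confidence in |error| gives r2 = 1
  tr1 <- tr
  tr1$confidence <- 100 - 100 * abs(tr1$error) / pi
  cc <- confidence_error_correlation(tr1)
  expect_true(all(cc$mean_r2 > 0.999))
  # generated data: the effect is strongest at detection threshold, where
  # trial reliability varies most; higher levels saturate
  cg <- confidence_error_correlation(tr)
  at_thr <- cg$contrast_rel == 1
  expect_gt(cg$mean_r2[at_thr], 0.05)
  expect_lt(cg$p.value[at_thr], 0.01)
  expect_lt(cg$t[at_thr], 0)  # higher confidence, smaller |error|
  # shuffled confidence: small r2, no significance
  tr2 <- tr
  tr2$confidence <- sample(tr2$confidence)
  cs <- confidence_error_correlation(tr2)
  expect_lt(mean(cs$mean_r2), 0.05)
})

test_that("median splits are balanced and posterior-precision splits order precision", {
  set.seed(26)
  pp <- group_params()
  thr <- threshold_closed_form(pp)
  sim <- simulate_popcode_trials(pp, rep(c(0.5, 1, 2, 4) * thr, each = 1000))
  sim$contrast_rel <- rep(c(0.5, 1, 2, 4), each = 1000)
  sp <- median_split(sim, "posterior_precision")
  expect_true(all(abs(sp$n_high - sp$n_low) <= 1))
  # at the 50% level the steep group-mean contrast response yields almost
  # no spikes, so both halves are guesses; assert ordering where there is
  # signal to split on
  informative <- sp$contrast_rel >= 1
  expect_true(all(sp$precision_high[informative] >
                    sp$precision_low[informative]))
  # distinct criterion values, even n: exactly equal halves
  tr <- data.frame(error = rvm(100, 0, 2), contrast_rel = 1,
                   crit = seq_len(100))
  s2 <- median_split(tr, "crit")
  expect_equal(s2$n_high, s2$n_low)
  # heavily tied criterion still balances to within one
  tr$crit <- rep(c(1, 1, 1, 2), 25)
  s3 <- median_split(tr, "crit")
  expect_lte(abs(s3$n_high - s3$n_low), 1)
  expect_equal(split_mse(sp, sp), 0)
})

test_that("count-precision correlation is near 1 in the deterministic regime and flagged when degenerate", {
  set.seed(27)
  pp_hi <- population_params(gamma = 300, kappa = 25, alpha = 2, sigma_c = 0.05)
  r_hi <- spikecount_posterior_corr(pp_hi, contrast_rel = 4, n_sim = 3000)
  expect_gt(r_hi$r2, 0.9)
  # vanishing contrast: no spikes anywhere, correlation undefined and flagged
  r_lo <- spikecount_posterior_corr(group_params(),
                                    contrast_rel = c(1e-9, 2e-9), n_sim = 500)
  expect_true(is.na(r_lo$r2))
})

test_that("anisotropy resampling reproduces flat data and stays far below coding non-normality", {
  set.seed(28)
  n <- 6000
  theta <- runif(n, -pi, pi)
  # no anisotropy: constant dispersion, zero bias
  tr0 <- data.frame(theta = theta, report = wrap_angle(theta + rvm(n, 0, 3)))
  d0 <- anisotropy_control(tr0, n_rep = 3)
  expect_lt(max(abs(d0$deviation)), 0.02)
  # oblique bias pattern: nonzero but far below the threshold-regime signature
  bias <- 0.15 * sin(2 * theta)
  trb <- data.frame(theta = theta,
                    report = wrap_angle(theta + bias + rvm(n, 0, 3)))
  db <- anisotropy_control(trb, n_rep = 3)
  pp <- group_params(beta = 0)
  err <- simulate_popcode_trials(pp, rep(contrast_for_xi(log(2), pp), 2e4))$error
  dp <- deviation_from_normal(err)
  expect_lt(max(abs(db$deviation)), 0.3 * max(abs(dp$deviation)))
  # single stimulus bin reduces to one matched VM
  d1 <- anisotropy_control(tr0, n_bins = 1L, n_rep = 3)
  expect_lt(max(abs(d1$deviation)), 0.02)
})
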