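test_that("trial tables round-trip through CSV with degree conversion", {
  set.seed(17)
  pp <- group_params()
  thr <- threshold_closed_form(pp)
  sim <- simulate_popcode_trials(pp, rep(c(1, 4) * thr, each = 50))
  trials <- data.frame(subject = 1L, theta = sim$theta, report = sim$report,
                       contrast_rel = rep(c(1, 4), each = 50),
                       confidence = sample(c(0, 25, 50, 75, 100), 100, TRUE))
  tmp <- tempfile(fileext = ".csv")
  write_trials(trials, tmp)
  back <- read_trials(tmp)
  expect_equal(back$theta, trials$theta, tolerance = 1e-12)
  expect_equal(back$report, trials$report, tolerance = 1e-12)
  expect_equal(back$error, circ_diff(trials$report, trials$theta),
               tolerance = 1e-12)
  bad <- trials; bad$confidence[1] <- 33
  tmp2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject = 1, theta_deg = 0, report_deg = 0,
                              contrast_rel = 1, confidence = 33),
                   tmp2, row.names = FALSE)
  expect_error(read_trials(tmp2), "confidence")
  unlink(c(tmp, tmp2))
})

test_that("the population-model likelihood behaves as the density predicts", {
  pp <- group_params(beta = 0)
  thr <- threshold_closed_form(pp)
  # perfectly centered reports at high gain: bias 0 beats bias 0.5
  n <- 200
  trials0 <- data.frame(error = rep(0, n), contrast_rel = 4,
                        contrast_abs = 4 * thr)
  par0 <- list(sigma_c = 0.096, alpha = 48.2, gamma = 145, kappa = 2.4,
               beta = 0)
  par_b <- par0; par_b$beta <- 0.5
  expect_gt(loglik_popcode(trials0, par0), loglik_popcode(trials0, par_b))
  # as xi -> 0 the density is uniform: ll = n log(1/2pi) for any errors
  set.seed(18)
  trials_u <- data.frame(error = runif(n, -pi, pi), contrast_rel = 1,
                         contrast_abs = 1e-6)
  expect_equal(loglik_popcode(trials_u, par0), n * log(1 / (2 * pi)),
               tolerance = 1e-6)
  # determinism given the cached tables
  tr <- make_recovery_trials(group_params(), 50L)
  expect_identical(loglik_popcode(tr, par0), loglik_popcode(tr, par0))
})

test_that("the likelihood surface peaks near the generating parameters", {
  set.seed(19)
  trials <- make_recovery_trials(group_params(), 1250L)
  base <- list(sigma_c = 0.096, alpha = 48.2, gamma = 145, kappa = 2.4,
               beta = -0.05)
  ll0 <- loglik_popcode(trials, base)
  for (nm in c("gamma", "kappa")) {
    for (f in c(0.5, 2)) {
      pert <- base; pert[[nm]] <- base[[nm]] * f
      expect_gt(ll0, loglik_popcode(trials, pert))
    }
  }
})

test_that("threshold-model mixing weights follow the data composition", {
  set.seed(20)
  # pure VM errors: weights pushed to 1 at every level
  n <- 300
  tv <- data.frame(error = rvm(2 * n, 0, 6),
                   contrast_rel = rep(c(1, 2), each = n))
  fv <- fit_threshold_model(tv)
  expect_true(all(fv$parameters$p > 0.95))
  back <- jsonlite::fromJSON(fit_to_json(fv))
  expect_equal(back$model, "threshold")
  expect_equal(back$log_likelihood, fv$log_likelihood, tolerance = 1e-12)
  # pure uniform errors: weights to 0 and sigma flagged unidentifiable
  tu <- data.frame(error = runif(2 * n, -pi, pi),
                   contrast_rel = rep(c(1, 2), each = n))
  fu <- fit_threshold_model(tu)
  expect_true(all(fu$parameters$p < 0.05))
  expect_true(length(fu$notes) > 0)
  # population-model data with graded xi: p rises with contrast
  pp <- population_params(gamma = 80, kappa = 2.4, alpha = 3, sigma_c = 0.1)
  thr <- threshold_closed_form(pp)
  sim <- simulate_popcode_trials(pp, rep(c(0.5, 1, 2, 4) * thr, each = 400))
  tp <- data.frame(error = sim$error,
                   contrast_rel = rep(c(0.5, 1, 2, 4), each = 400))
  fp <- fit_threshold_model(tp)
  expect_true(all(diff(fp$parameters$p) > -0.02))
  expect_gt(fp$parameters$p[4], fp$parameters$p[1])
})

test_that("information criteria penalize parameters and require identical data", {
  f1 <- popcode:::new_fit_result("a", list(), -500, 5L, 400L, TRUE)
  f2 <- popcode:::new_fit_result("b", list(), -500, 6L, 400L, TRUE)
  cmp <- compare_models(list(f1, f2))
  expect_equal(cmp$delta_aicc[1], 0)
  expect_gt(cmp$delta_aicc[2], 0)
  expect_gt(cmp$delta_bic[2], 0)
  expect_true(is.na(popcode:::aicc_of(-10, 5L, 6L)))  # n <= k + 1
  f3 <- popcode:::new_fit_result("c", list(), -400, 5L, 300L, TRUE)
  expect_error(compare_models(list(f1, f3)), "identical")
})

test_that("fitting without contrast variation flags the contrast-response parameters", {
  set.seed(21)
  pp <- group_params()
  thr <- threshold_closed_form(pp)
  sim <- simulate_popcode_trials(pp, rep(2 * thr, 300))
  tr <- data.frame(error = sim$error, contrast_rel = 2,
                   contrast_abs = 2 * thr)
  f <- fit_popcode(tr, n_starts = 1L, maxit = 150L)
  expect_true(any(grepl("unidentifiable", f$notes)))
})

test_that("two-stage fit converges to interpretable parameters on a small set", {
  set.seed(22)
  trials <- make_recovery_trials(group_params(), 100L)
  f <- fit_two_stage(trials, n_starts = 1L, maxit = 300L)
  expect_true(all(unlist(f$parameters$sigma) > 0))
  expect_true(f$parameters$xi > 0)
  expect_equal(f$n_params, 7L)
  expect_lt(f$log_likelihood, 0)
})
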