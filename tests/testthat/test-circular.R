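test_that("orientation <-> circle mapping is the x pi/90 map and round-trips", {
  expect_equal(orientation_to_circle(45), pi / 2)
  expect_equal(orientation_to_circle(-90), pi)  # boundary wraps to +pi
  # report 44, stimulus 46: error -2 deg -> -pi/45 rad
  expect_equal(circ_diff(orientation_to_circle(44), orientation_to_circle(46)),
               -pi / 45)
  deg <- seq(-89.5, 90, by = 0.5)
  expect_equal(circle_to_orientation(orientation_to_circle(deg)), deg,
               tolerance = 1e-12)
  expect_error(orientation_to_circle(90.5), "orientations")
})

test_that("circ_diff wraps differences into (-pi, pi]", {
  expect_equal(circ_diff(pi / 2, pi / 2), 0)
  expect_equal(circ_diff(-3, 3), 2 * pi - 6)
  expect_equal(circ_diff(pi, -pi), 0)
  x <- seq(-10, 10, length.out = 101)
  expect_true(all(circ_diff(x, 0.3) > -pi & circ_diff(x, 0.3) <= pi))
})

test_that("resultant length and direction follow vector geometry", {
  r <- circ_resultant(0.7)
  expect_equal(r$mean_length, 1)
  expect_equal(r$mean_angle, 0.7)
  r2 <- circ_resultant(c(0, pi / 2))
  expect_equal(r2$mean_length, sqrt(2) / 2)
  expect_equal(r2$mean_angle, pi / 4)
  anti <- circ_resultant(c(0, pi))
  expect_lt(anti$mean_length, 1e-12)
  expect_true(is.na(anti$mean_angle))
  expect_error(circ_resultant(numeric(0)))
  set.seed(1)
  for (i in 1:20) {
    rl <- circ_resultant(runif(50, -pi, pi))$mean_length
    expect_true(rl >= 0 && rl <= 1)
  }
})

test_that("Fisher circular SD inverts the resultant and is rotation invariant", {
  expect_equal(circ_sd(rep(1.2, 10)), 0, tolerance = 1e-6)
  # symmetric pair at +/- a has Rbar = cos(a); choose cos(a) = exp(-1/2)
  a <- acos(exp(-0.5))
  expect_equal(circ_sd(c(-a, a)), 1, tolerance = 1e-10)
  expect_equal(circ_precision(c(-a, a)), 1, tolerance = 1e-10)
  set.seed(2)
  x <- rvm(500, 0.3, 2)
  expect_equal(circ_sd(x), circ_sd(wrap_angle(x + 1.1)), tolerance = 1e-12)
  # uniform sample: precision near chance (sd large)
  set.seed(3)
  u <- runif(1e5, -pi, pi)
  expect_gt(circ_sd(u), 2)
  expect_lt(circ_precision(u), 0.25)
})

test_that("V test detects a concentrated mean direction and not a uniform one", {
  vt <- v_test(rep(0.4, 10), mu0 = 0.4)
  expect_equal(vt$V, 10)
  set.seed(4)
  vt2 <- v_test(rvm(100, 0.2, 2), mu0 = 0.2)
  expect_gt(vt2$V, 0)
  expect_lt(vt2$p.value, 0.01)
  vt3 <- v_test(runif(1e4, -pi, pi), mu0 = 0)
  expect_lt(abs(vt3$V), 3 * sqrt(1e4 / 2))  # E[V] ~ 0, sd ~ sqrt(n/2)
  expect_gt(vt3$p.value, 1e-4)
})

test_that("circular kurtosis excess is ~0 for VM, positive for heavy tails, finite for uniform", {
  set.seed(5)
  expect_lt(abs(circ_kurtosis_excess(rvm(2e5, 0, 2))), 0.1)
  mix <- c(rvm(1e5, 0, 8), runif(1e5, -pi, pi))
  expect_gt(circ_kurtosis_excess(mix), 0.2)
  u <- runif(1e5, -pi, pi)
  expect_true(is.finite(circ_kurtosis_excess(u)))
  expect_error(circ_kurtosis_excess(rep(0.2, 10)), "degenerate")
})

test_that("Von Mises density normalizes, matches known values, and sampler matches pdf", {
  expect_equal(dvm(1.3, 2, 0), 1 / (2 * pi))
  expect_equal(dvm(0, 0, 1), exp(1) / (2 * pi * besselI(1, 0)),
               tolerance = 1e-12)
  expect_equal(round(dvm(0, 0, 1), 4), 0.3417)
  g <- popcode:::circle_grid(1e4)
  for (k in c(0, 0.5, 2, 10, 50))
    expect_equal(sum(dvm(g, 0.7, k)) * 2 * pi / 1e4, 1, tolerance = 1e-8)
  expect_error(dvm(0, 0, -1), "kappa")
  # goodness of fit of the sampler against the pdf
  set.seed(6)
  x <- rvm(1e5, 0.5, 3)
  brk <- seq(-pi, pi, length.out = 41)
  obs <- tabulate(findInterval(x, brk, all.inside = TRUE), 40)
  ctr <- (brk[-1] + brk[-41]) / 2
  p <- dvm(ctr, 0.5, 3); p <- p / sum(p)
  keep <- p * 1e5 > 5
  chi <- sum((obs[keep] - 1e5 * p[keep])^2 / (1e5 * p[keep]))
  expect_gt(stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 1e-4)
})

test_that("kappa <-> sigma conversion is a consistent bijection", {
  k <- c(0.1, 0.5, 2.4, 10, 80)
  expect_equal(sigma_to_kappa(kappa_to_sigma(k)), k, tolerance = 1e-6)
  expect_true(all(diff(kappa_to_sigma(k)) < 0))  # sigma decreases in kappa
  expect_equal(kappa_to_sigma(0), Inf)
})
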