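test_that("uniform-walk resultant tables have the right support and moments", {
  t1 <- uniform_walk_resultant(1)
  expect_equal(sum(t1$density), 1, tolerance = 1e-6)
  expect_equal(sum(t1$density[abs(t1$bin_centers - 1) < 2e-3]), 1)  # unit step
  # two steps: r = 2|cos(U/2)|, so P(r <= sqrt(2)) = 1/2 exactly
  t2 <- uniform_walk_resultant(2)
  expect_equal(sum(t2$density[t2$bin_centers <= sqrt(2)]), 0.5,
               tolerance = 0.005)
  # large m: Rayleigh limit, mean sqrt(pi m)/2, var m(1 - pi/4)
  t100 <- uniform_walk_resultant(100)
  mu <- sum(t100$bin_centers * t100$density)
  v <- sum(t100$bin_centers^2 * t100$density) - mu^2
  expect_equal(mu, sqrt(pi * 100) / 2, tolerance = 0.02)
  expect_equal(sqrt(v), sqrt(100 * (1 - pi / 4)), tolerance = 0.02)
})

test_that("resultant tables round-trip through the delimited cache format", {
  tab <- uniform_walk_resultant(3)
  tmp <- tempfile(fileext = ".tsv")
  write_resultant_table(tab, tmp)
  tab2 <- read_resultant_table(tmp)
  expect_equal(tab2$m, 3L)
  expect_equal(tab2$density, tab$density, tolerance = 1e-12)
  expect_equal(tab2$bin_centers, tab$bin_centers, tolerance = 1e-9)
  unlink(tmp)
})

test_that("Von Mises tilting of the walk density shifts mass to larger resultants", {
  t5 <- uniform_walk_resultant(5)
  expect_equal(vm_walk_resultant(5, 0, t5)$density, t5$density)
  means <- vapply(c(0, 1, 4), function(k) {
    d <- vm_walk_resultant(5, k, t5)
    sum(d$bin_centers * d$density)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # brute-force oracle: mean resultant of 5 VM(0, 2) steps
  set.seed(11)
  ang <- matrix(rvm(5 * 4e4, 0, 2), 5)
  r_mc <- mean(sqrt(colSums(cos(ang))^2 + colSums(sin(ang))^2))
  d2 <- vm_walk_resultant(5, 2, t5)
  expect_equal(sum(d2$bin_centers * d2$density), r_mc, tolerance = 0.01)
})

test_that("conditional error density given m matches the VM-walk oracle on both branches", {
  g <- popcode:::circle_grid(360)
  expect_equal(error_density_given_m(1, 2.4, g), dvm(g, 0, 2.4),
               tolerance = 1e-3)
  expect_equal(error_density_given_m(7, 0, g), rep(1 / (2 * pi), 360))
  set.seed(12)
  for (kap in c(1, 2.4, 8)) {
    ms <- popcode:::walk_m_safe(kap)
    for (m in unique(c(3, ms, ms + 1L, 2L * ms))) {
      ang <- matrix(rvm(m * 2e4, 0, kap), m)
      errs <- atan2(colSums(sin(ang)), colSums(cos(ang)))
      expect_lt(tv_binned(errs, g, error_density_given_m(m, kap, g)), 0.02)
    }
  }
})

test_that("the table/Gaussian handover is continuous", {
  g <- popcode:::circle_grid(360)
  for (kap in c(1.5, 2.4, 6)) {
    ms <- popcode:::walk_m_safe(kap)
    d_lo <- error_density_given_m(ms, kap, g)
    d_hi <- error_density_given_m(ms + 1L, kap, g)
    # consecutive m differ intrinsically by O(1/m); the handover must not add
    # a visible jump on top of that
    expect_lt(0.5 * sum(abs(d_hi - d_lo)) * 2 * pi / 360, 0.05)
  }
})

test_that("the error density is a normalized Poisson mixture with a guessing floor", {
  ed0 <- error_density(0, 2.4)
  expect_equal(ed0$density, rep(1 / (2 * pi), length(ed0$grid)))
  for (xi in c(0.2, 2, 14.5, 100)) {
    ed <- error_density(xi, 2.4)
    expect_equal(sum(ed$density) * 2 * pi / length(ed$grid), 1,
                 tolerance = 1e-6)
    # symmetric about zero for beta = 0
    expect_equal(ed$density, rev(ed$density), tolerance = 1e-8)
    # guessing floor: density never below the zero-count uniform component
    expect_true(all(ed$density >= exp(-xi) / (2 * pi) - 1e-10))
  }
})

test_that("pooled evaluation agrees with the per-m mixture", {
  for (xi in c(0.7, 14.5)) {
    p1 <- error_density(xi, 2.4, beta = -0.05)
    p2 <- error_density(xi, 2.4, beta = -0.05, method = "per_m")
    expect_lt(0.5 * sum(abs(p1$density - p2$density)) * 2 * pi / 360, 0.005)
  }
})

test_that("mixture consistency: marginal equals the Poisson-weighted conditionals", {
  xi <- 3.2; kap <- 2.4
  g <- popcode:::circle_grid(360)
  m_hi <- qpois(1 - 1e-8, xi)
  pm <- dpois(0:m_hi, xi); pm <- pm / sum(pm)
  manual <- pm[1] / (2 * pi)
  for (m in seq_len(m_hi))
    manual <- manual + pm[m + 1] * error_density_given_m(m, kap, g)
  manual <- manual / (sum(manual) * 2 * pi / 360)
  expect_equal(error_density(xi, kap, method = "per_m")$density, manual,
               tolerance = 1e-12)
})

test_that("beta shifts the error density rigidly", {
  ed0 <- error_density(14.5, 2.4, beta = 0)
  edb <- error_density(14.5, 2.4, beta = 0.3)
  shifted <- popcode:::interp_circular(ed0$grid, ed0$density, edb$grid - 0.3)
  expect_equal(edb$density, shifted, tolerance = 1e-3)
})

test_that("high gain approaches a matched circular normal; low gain approaches uniform", {
  ed <- error_density(200, 2.4)
  prec <- posterior_precision(ed$density, ed$grid)
  vm <- dvm(ed$grid, 0, sigma_to_kappa(1 / sqrt(prec)))
  expect_lt(max(abs(ed$density - vm)) / max(vm), 0.01)
  expect_lt(abs(circ_kurtosis_excess(ed$grid, w = ed$density)), 0.05)
  edl <- error_density(0.002, 2.4)
  expect_lt(max(abs(edl$density - 1 / (2 * pi))) * 2 * pi, 0.01)
})

test_that("a single Von Mises fits population-coded errors worse than the true density", {
  # the non-normality is statistically meaningful: on data simulated from the
  # threshold-regime density, the matched-VM likelihood is strictly lower
  set.seed(13)
  pp <- group_params(beta = 0)
  cc <- contrast_for_xi(log(2), pp)
  err <- simulate_popcode_trials(pp, rep(cc, 4000))$error
  ed <- error_density(log(2), 2.4)
  ll_model <- sum(log(popcode:::interp_circular(ed$grid, ed$density, err)))
  kap_vm <- sigma_to_kappa(circ_sd(err))
  mu_vm <- circ_resultant(err)$mean_angle
  ll_vm <- sum(dvm(err, mu_vm, kap_vm, log = TRUE))
  expect_gt(ll_model, ll_vm + 10)
})
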