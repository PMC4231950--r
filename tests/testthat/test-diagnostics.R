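test_that("empirical pmf gives relative frequencies over 0..max", {
  p <- empirical_pmf(c(0, 0, 1, 1))
  expect_equal(p$prob, c(0.5, 0.5))
  p5 <- empirical_pmf(5)
  expect_equal(p5$prob, c(0, 0, 0, 0, 0, 1))
  x <- simulate_counts(mix_gamma(1, 0.2), 1000, seed = 3)
  expect_equal(sum(empirical_pmf(x)$prob), 1)
})

test_that("recover_pmf applies the Poisson mixture formula", {
  p <- recover_pmf(discrete_mixture(3, 1), x_max = 20)
  expect_equal(p$prob, dpois(0:20, 3))
  p2 <- recover_pmf(discrete_mixture(c(1, 10), c(0.5, 0.5)), x_max = 0)
  expect_equal(p2$prob, 0.5 * exp(-1) + 0.5 * exp(-10))
  expect_equal(tail_mass(p2), 1 - p2$prob, tolerance = 1e-12)
})

test_that("NPMLE recovery approaches the empirical distribution with n", {
  dtv <- vapply(c(1e3, 1e5), function(n) {
    x <- simulate_counts(mix_gamma(2, 0.5), n, seed = 51)
    tv_distance(recover_pmf(cnm_fit(x), max(x$count)), empirical_pmf(x))
  }, numeric(1))
  expect_lt(dtv[2], dtv[1])
  expect_lt(dtv[2], 0.01)
})

test_that("total variation matches direct summation and its extremes", {
  f <- empirical_pmf(c(0, 1, 2))
  expect_equal(tv_distance(f, f), 0)
  p0 <- new_pmf(0, 1)
  p1 <- new_pmf(0:1, c(0, 1))
  expect_equal(tv_distance(p0, p1), 1)
  f1 <- new_pmf(0:50, dpois(0:50, 1), 1 - sum(dpois(0:50, 1)))
  f2 <- new_pmf(0:50, dpois(0:50, 2), 1 - sum(dpois(0:50, 2)))
  expect_equal(tv_distance(f1, f2), oracle_tv_poisson(1, 2, 50), tolerance = 1e-10)
})

test_that("total variation is a metric on pmf tables", {
  withr::with_seed(61L, {
    for (rep in 1:20) {
      f <- random_pmf(8, tail = runif(1, 0, 0.2))
      g <- random_pmf(sample(4:10, 1), tail = runif(1, 0, 0.2))
      h <- random_pmf(8, tail = runif(1, 0, 0.2))
      expect_equal(tv_distance(f, g), tv_distance(g, f))
      expect_equal(tv_distance(f, f), 0)
      expect_lte(
        tv_distance(f, h),
        tv_distance(f, g) + tv_distance(g, h) + 1e-12
      )
      expect_gte(tv_distance(f, g), 0)
      expect_lte(tv_distance(f, g), 1)
    }
  })
})

test_that("cdf_bounds are the cumulative weights, telescoping to 1", {
  b1 <- cdf_bounds(discrete_mixture(4, 1))
  expect_equal(unlist(b1), c(theta = 4, lower = 0, upper = 1))
  b <- cdf_bounds(discrete_mixture(c(1, 5, 9), c(0.5, 0.3, 0.2)))
  expect_equal(b$lower, c(0, 0.5, 0.8))
  expect_equal(b$upper, c(0.5, 0.8, 1.0))
  withr::with_seed(71L, {
    for (rep in 1:10) {
      L <- sample(2:6, 1)
      pi <- diff(c(0, sort(runif(L - 1)), 1))
      b <- cdf_bounds(discrete_mixture(seq_len(L) * 2, pi), collapse = 0)
      expect_equal(b$lower[-1], b$upper[-L])
      expect_equal(sum(b$upper - b$lower), 1)
      expect_equal(b$lower[1], 0)
      expect_equal(b$upper[L], 1)
    }
  })
})

test_that("the bound check is strictly half-open at the upper end", {
  mix <- discrete_mixture(c(2, 6), c(0.4, 0.6))
  bounds <- cdf_bounds(mix)
  # the discrete mixture's own right-continuous CDF sits exactly on the
  # upper bound at each support point: a documented boundary "fail"
  chk <- check_mixing_fit(mix, bounds)
  expect_equal(chk$cdf, bounds$upper)
  expect_false(any(chk$pass))
  expect_equal(attr(chk, "first_violation"), 1L)
})

test_that("bound checks separate adequate from inadequate mixing models", {
  x <- simulate_counts(mix_gamma(shape = 2, rate = 2 / 10), 2e4, seed = 81)
  bounds <- cdf_bounds(cnm_fit(x))
  good <- check_mixing_fit(mix_gamma(2, 2 / 10), bounds)
  expect_lte(sum(!good$pass), 1)
  bad <- check_mixing_fit(fit_poisson(x), bounds)
  expect_gt(sum(!bad$pass), 0)
})

test_that("zero_scan reproduces the unadjusted fit at rho = 0 and is deterministic", {
  x <- simulate_counts(mix_gamma(1, 0.4), 3000, seed = 91)
  grid <- c(-0.2, 0, 0.3)
  scan <- zero_scan(x, grid, models = c("poisson", "nb"), seed = 4)
  expect_equal(nrow(scan), 6L)
  nb0 <- fit_nb(x)
  row0 <- scan[scan$rho == 0 & scan$model == "nb", ]
  expect_identical(row0$loglik, nb0$loglik)
  expect_identical(
    row0$d_tv,
    tv_distance(chipmix:::fitted_pmf(nb0, max(x$count)), empirical_pmf(x))
  )
  expect_identical(scan, zero_scan(x, grid, models = c("poisson", "nb"), seed = 4))
  expect_error(zero_scan(x, c(0, 1.2)), "at most 1")
  expect_error(zero_scan(c(1, 2, 3), 0.5), "no zeros")
})

test_that("posterior classification follows Bayes' rule", {
  fit <- new_mix_fit_for_test(tau = 0.1, mu1 = 2, r1 = 8, mu2 = 25, r2 = 1)
  x <- 0:50
  cls <- suppressWarnings(classify_bins(fit, x, threshold = 0.5))
  f1 <- dnbinom(x, size = 8, mu = 2)
  f2 <- dnbinom(x, size = 1, mu = 25)
  direct <- 0.1 * f2 / (0.1 * f2 + 0.9 * f1)
  expect_equal(cls$bins$posterior, direct, tolerance = 1e-12)
})

test_that("tau = 0 yields zero posteriors everywhere", {
  fit <- new_mix_fit_for_test(tau = 0, mu1 = 2, r1 = 8, mu2 = 25, r2 = 1)
  cls <- suppressWarnings(classify_bins(fit, 0:20))
  expect_equal(cls$bins$posterior, rep(0, 21))
})

test_that("the posterior is monotone in x under stochastic dominance", {
  fit <- new_mix_fit_for_test(tau = 0.1, mu1 = 3, r1 = 2, mu2 = 30, r2 = 2)
  cls <- suppressWarnings(classify_bins(fit, 0:500))
  expect_true(all(diff(cls$bins$posterior) >= -1e-14))
})

test_that("flagged bins become a merged blacklist; no coordinates, no regions", {
  fit <- new_mix_fit_for_test(tau = 0.1, mu1 = 2, r1 = 8, mu2 = 40, r2 = 2)
  bins <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, 900, by = 100),
    end = seq(100, 1000, by = 100),
    count = c(1, 2, 80, 95, 1, 0, 120, 2, 1, 3)
  )
  cls <- classify_bins(fit, bins)
  expect_equal(cls$blacklist$start, c(200, 600))
  expect_equal(cls$blacklist$end, c(400, 700))  # adjacent flagged bins merged
  expect_warning(classify_bins(fit, c(1, 2, 200)), "coordinates")
})
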