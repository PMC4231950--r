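test_that("the gradient is non-positive at the degenerate NPMLE", {
  x <- rep(3, 8)
  mix <- discrete_mixture(3, 1)
  cand <- c(0, 0.5, 1, 2, 2.9, 3, 3.1, 5, 10)
  d <- gradient_function(cand, mix, x)
  expect_true(all(d <= 1e-10))
  expect_equal(d[cand == 3], 0)
})

test_that("the closed-form gradient matches a finite-difference derivative", {
  x <- withr::with_seed(5L, rpois(40, 3))
  mix <- discrete_mixture(c(1.2, 4.5), c(0.4, 0.6))
  ll <- function(theta, pi) oracle_mixture_loglik(x, theta, pi)
  for (ts in c(0.3, 2, 6, 11)) {
    d <- gradient_function(ts, mix, x)
    eps <- 1e-6
    fd <- (ll(c(mix$theta, ts), c((1 - eps) * mix$pi, eps)) -
      ll(c(mix$theta, ts), c((1 + eps) * mix$pi, -eps))) / (2 * eps)
    expect_equal(d, fd, tolerance = 1e-4)
  }
})

test_that("unmodelled tail mass gives a positive gradient", {
  x <- c(rep(1, 10), 20)
  mix <- discrete_mixture(1, 1)
  expect_gt(gradient_function(20, mix, x), 0)
})

test_that("the gradient errors when an observed count has zero probability", {
  mix <- discrete_mixture(0, 1)  # point mass at rate 0
  expect_error(gradient_function(1, mix, c(0, 2)), "zero probability")
})

test_that("weight update returns the simplex point for L = 1", {
  expect_identical(update_weights(4.2, c(1, 2, 3)), 1)
})

test_that("weight update matches a brute-force two-point grid search", {
  x <- c(0, 0, 6)
  theta <- c(0.5, 6)
  pi_hat <- update_weights(theta, x)
  w_grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(
    w_grid,
    function(w) oracle_mixture_loglik(x, theta, c(w, 1 - w)),
    numeric(1)
  )
  expect_lt(abs(pi_hat[1] - w_grid[which.max(ll)]), 1e-3)
})

test_that("weight updates are feasible for random supports", {
  withr::with_seed(11L, {
    for (rep in 1:10) {
      x <- rpois(30, runif(1, 0.5, 8))
      L <- sample(2:4, 1)
      theta <- sort(runif(L, 0, 10))
      pi <- update_weights(theta, x)
      expect_lt(abs(sum(pi) - 1), 1e-12)
      expect_true(all(pi >= 0))
    }
  })
})

test_that("identical counts give a single point mass at the common value", {
  res <- cnm_fit(c(2, 2, 2, 2))
  expect_equal(res$mixture$L, 1L)
  expect_equal(res$mixture$theta, 2)
  expect_equal(res$mixture$pi, 1)
  expect_true(res$converged)
})

test_that("cnm beats an exhaustive small-instance search", {
  x <- c(0, 0, 0, 10, 10)
  res <- cnm_fit(x)
  # two distinct values, so the NPMLE has at most two support points
  best <- oracle_npmle_loglik(x, seq(0, 12, length.out = 200),
    w_step2 = 0.005, max_L = 2L
  )
  expect_gte(res$loglik, best - 1e-6)
})

test_that("cnm satisfies its invariants on simulated gamma mixing", {
  x <- simulate_counts(mix_gamma(2, 0.5), 2000, seed = 41)
  res <- cnm_fit(x)
  expect_true(res$converged)
  expect_lte(res$max_gradient, res$grad_tol)
  expect_lte(res$mixture$L, length(unique(x$count)))
  expect_true(all(diff(res$trace) >= -1e-9))
  expect_lt(abs(sum(res$mixture$pi) - 1), 1e-12)
  # the NPMLE dominates every parametric mixing distribution
  expect_gte(res$loglik, fit_nb(x)$loglik - 1e-6)
  expect_gte(res$loglik, fit_poisson(x)$loglik - 1e-6)
})

test_that("non-convergence is reported, with the result still usable", {
  x <- simulate_counts(mix_gamma(2, 0.5), 2000, seed = 43)
  res <- cnm_fit(x, max_iter = 1L)
  expect_false(res$converged)
  expect_s3_class(res$mixture, "discrete_mixture")
  expect_true(is.finite(res$loglik))
})

test_that("discrete_mixture validates its invariants", {
  expect_error(discrete_mixture(c(2, 1), c(0.5, 0.5)), "increasing")
  expect_error(discrete_mixture(c(1, 2), c(0.7, 0.2)), "sum to 1")
  expect_error(discrete_mixture(c(1, 2), c(1, 0)), "positive")
  expect_error(discrete_mixture(-1, 1), "non-negative")
})
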