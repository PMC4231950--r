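# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: brute-force enumeration, dense-grid
# integration, and direct summation.

# log-likelihood of a discrete Poisson mixture, by direct summation
oracle_mixture_loglik <- function(x, theta, pi) {
  sum(log(colSums(pi * t(outer(x, theta, dpois)))))
}

# best mixture log-likelihood found by exhaustive search over a support
# grid and a weight grid, for up to 3 support points
oracle_npmle_loglik <- function(x, theta_grid, w_step2 = 0.02, w_step3 = 0.1,
                                max_L = 3L) {
  logP <- outer(theta_grid, x, function(th, xx) dpois(xx, th, log = TRUE))
  best <- max(rowSums(logP))  # L = 1
  G <- length(theta_grid)
  P <- exp(logP)  # G x n
  if (max_L >= 2L) {
    w2 <- seq(0, 1, by = w_step2)
    pairs <- utils::combn(G, 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      mixp <- outer(w2, P[i, ]) + outer(1 - w2, P[j, ])
      ll <- rowSums(log(mixp))
      best <- max(best, ll, na.rm = TRUE)
    }
  }
  if (max_L >= 3L) {
    w3a <- seq(0, 1, by = w_step3)
    triples <- utils::combn(G, 3L)
    for (k in seq_len(ncol(triples))) {
      i <- triples[1L, k]; j <- triples[2L, k]; l <- triples[3L, k]
      for (a in w3a) {
        wb <- seq(0, 1 - a, by = w_step3)
        mixp <- a * matrix(P[i, ], length(wb), length(x), byrow = TRUE) +
          outer(wb, P[j, ]) + outer(1 - a - wb, P[l, ])
        ll <- rowSums(log(mixp))
        best <- max(best, ll, na.rm = TRUE)
      }
    }
  }
  best
}

# NB pmf by numerical integration of the gamma-mixed Poisson.  For
# shape < 1 the gamma density is singular at 0; substituting u = l^r
# removes the singularity (du-density is proportional to exp(-beta u^(1/r)))
oracle_gamma_poisson_pmf <- function(x, mu, r) {
  beta <- r / mu
  vapply(x, function(xx) {
    if (r < 1) {
      stats::integrate(
        function(u) dpois(xx, u^(1 / r)) * beta^r / (r * gamma(r)) *
          exp(-beta * u^(1 / r)),
        lower = 0, upper = Inf, rel.tol = 1e-12, abs.tol = 0
      )$value
    } else {
      # split at the far side of the integrand's support: a single
      # (0, Inf) call undersamples a far-tail peak at large x
      f <- function(l) dpois(xx, l) * dgamma(l, shape = r, rate = beta)
      stats::integrate(f, 0, xx + mu, rel.tol = 1e-12, abs.tol = 0)$value +
        stats::integrate(f, xx + mu, Inf, rel.tol = 1e-12, abs.tol = 0)$value
    }
  }, numeric(1))
}

# log-normal Poisson integral by dense trapezoid integration over lambda
oracle_lnp_term_trapezoid <- function(x, mu, sigma2) {
  hi <- qlnorm(1 - 1e-6, mu, sqrt(sigma2)) + max(x) * 3 + 50
  l <- seq(1e-12, hi, length.out = 400000)
  f <- dlnorm(l, meanlog = mu, sdlog = sqrt(sigma2)) * dpois(x, l)
  sum((f[-1] + f[-length(f)]) / 2 * diff(l))
}

# total variation by direct summation of truncated Poisson pmfs
oracle_tv_poisson <- function(lam1, lam2, x_max) {
  p1 <- dpois(0:x_max, lam1)
  p2 <- dpois(0:x_max, lam2)
  0.5 * (sum(abs(p1 - p2)) + abs((1 - sum(p1)) - (1 - sum(p2))))
}

random_pmf <- function(x_max, tail = 0) {
  p <- runif(x_max + 1)
  p <- p / sum(p) * (1 - tail)
  new_pmf(0:x_max, p, tail)
}

# construct an nbnb_fit object directly from parameters (for tests that
# exercise pmf/mixing_cdf/classification without running the EM)
new_mix_fit_for_test <- function(tau, mu1, r1, mu2, r2) {
  chipmix:::new_mix_fit(
    "nbnb",
    params = list(tau = tau, mu1 = mu1, r1 = r1, mu2 = mu2, r2 = r2),
    loglik = NA_real_
  )
}
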