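.gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(k) {
  key <- as.character(k)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(k)
  .gh_cache[[key]]
}

# log of the log-normal Poisson integral, one value per count:
#   I(x) = int dnorm(eta; mu, sigma) * dpois(x, exp(eta)) deta
# evaluated by Laplace-adapted Gauss-Hermite quadrature: nodes are centred
# at the mode of the integrand's exponent and scaled by its curvature, so
# a modest node count is accurate for any x.  `k` nodes per term.
lnp_gh <- function(x, mu, sigma2, k) {
  sd_ <- sqrt(sigma2)
  # mode of h(eta) = dnorm log-density + poisson log-density (concave in eta)
  eta <- ifelse(x > 0, pmin(log(x), mu + 30 * sd_), mu)
  for (i in 1:60) {
    ex <- exp(eta)
    g <- -(eta - mu) / sigma2 + x - ex
    hss <- -1 / sigma2 - ex
    step <- g / hss
    eta <- eta - step
    if (max(abs(step)) < 1e-13) break
  }
  s_hat <- 1 / sqrt(1 / sigma2 + exp(eta))
  gh <- gh_nodes(k)
  # eta_jk = eta_j + sqrt(2) s_j t_k ; I = sqrt(2) s sum w e^{t^2} g(eta)
  eta_mat <- outer(eta, sqrt(2) * gh$x, function(e, d) e) +
    outer(s_hat, sqrt(2) * gh$x)
  lam <- exp(eta_mat)
  logg <- dnorm(eta_mat, mean = mu, sd = sd_, log = TRUE) +
    dpois(rep(x, ncol(eta_mat)), as.vector(lam), log = TRUE)
  dim(logg) <- dim(eta_mat)
  logg <- sweep(logg, 2, log(gh$w) + gh$x^2, "+")
  apply(logg, 1, logsumexp) + log(sqrt(2) * s_hat)
}

# adaptive wrapper: doubles the node count until successive evaluations
# agree to rel_tol per term, erroring with the achieved accuracy otherwise
lnp_log_terms <- function(x, mu, sigma2, rel_tol = 1e-8, k_start = 40L,
                          k_max = 640L) {
  if (sigma2 <= 0) abort("`sigma2` must be positive")
  k <- k_start
  prev <- lnp_gh(x, mu, sigma2, k)
  repeat {
    k <- 2L * k
    cur <- lnp_gh(x, mu, sigma2, k)
    err <- max(abs(cur - prev))  # |delta log I| ~ relative error of I
    if (err <= rel_tol) return(cur)
    if (k >= k_max) {
      abort(sprintf(
        "log-normal Poisson quadrature did not reach rel_tol = %g (achieved %g at %d nodes)",
        rel_tol, err, k
      ))
    }
    prev <- cur
  }
}

#' Log-likelihood of the log-normal Poisson model
#'
#' Counts are Poisson with rate Lambda where log(Lambda) ~ N(`mu`,
#' `sigma2`).  Each term requires the integral of the Poisson pmf against
#' the log-normal density, which has no closed form; it is evaluated by
#' deterministic mode-adapted Gauss-Hermite quadrature with an accuracy
#' target of `rel_tol` relative per term (node count is doubled until two
#' successive evaluations agree; failure to reach the target is an error
#' reporting the achieved accuracy).
#'
#' @inheritParams fit_poisson
#' @param mu Log-scale mean.
#' @param sigma2 Log-scale variance (> 0).
#' @param rel_tol Per-term relative accuracy target.
#' @return The log-likelihood, a single number.
#' @examples
#' lnp_loglik(c(0, 1, 2), mu = 0.5, sigma2 = 0.3)
#' @export
lnp_loglik <- function(counts, mu, sigma2, rel_tol = 1e-8) {
  ct <- count_table(counts)
  sum(ct$m * lnp_log_terms(ct$x, mu, sigma2, rel_tol = rel_tol))
}

#' Fit the log-normal Poisson model by Metropolis-Hastings
#'
#' Bayesian fit with weak conjugate-style priors `mu ~ N(0, 10)` (variance
#' 10) and precision `1/sigma2 ~ Gamma(shape = 1, rate = 0.1)`.  A
#' Gaussian random-walk Metropolis-Hastings sampler moves jointly on
#' `(mu, log precision)`, with the proposal scale adapted during burn-in
#' towards ~0.3 acceptance and frozen afterwards.  The point estimate is
#' the post-burn-in posterior mean of each sampled parameter (`mu` and the
#' precision), an approximation to the MAP given the weak priors; the
#' reported `sigma2` is the reciprocal of the posterior-mean precision.
#'
#' @param counts A count table, or `NULL` for a prior-only chain.
#' @param n_iter Total chain length.
#' @param burn_in Iterations discarded (and used for adaptation);
#'   `0 <= burn_in < n_iter`.
#' @param seed Integer seed; required.
#' @param rel_tol Quadrature accuracy for the likelihood.
#' @return A [mix_fit] of subclass `lnp_fit`; component `mcmc` holds the
#'   full trace as a tibble (`iter`, `mu`, `precision`, `accepted`).
#' @export
fit_lnp <- function(counts = NULL, n_iter = 20000L, burn_in = 5000L, seed,
                    rel_tol = 1e-8) {
  if (missing(seed)) abort("`seed` is required")
  if (!(n_iter > burn_in && burn_in >= 0)) abort("need n_iter > burn_in >= 0")
  empty <- is.null(counts) ||
    (is.data.frame(counts) && nrow(counts) == 0L) ||
    (!is.data.frame(counts) && length(counts) == 0L)
  ct <- if (empty) NULL else count_table(counts)

  log_post <- function(mu, log_prec) {
    prec <- exp(log_prec)
    lp <- dnorm(mu, 0, sqrt(10), log = TRUE) +
      dgamma(prec, shape = 1, rate = 0.1, log = TRUE) + log_prec
    if (!is.null(ct)) {
      lp <- lp + sum(ct$m * lnp_log_terms(ct$x, mu, 1 / prec, rel_tol = rel_tol))
    }
    lp
  }

  # moment-matched start: E X = exp(mu + s2/2), Var X = m + m^2 (e^{s2} - 1)
  if (!is.null(ct)) {
    xm <- sum(ct$m * ct$x) / ct$n
    xv <- sum(ct$m * (ct$x - xm)^2) / (ct$n - 1)
    s2_0 <- log(1 + max(xv - xm, 0.01 * xm) / max(xm, 1e-3)^2)
    s2_0 <- min(max(s2_0, 0.01), 10)
    phi <- c(log(max(xm, 1e-3)) - s2_0 / 2, log(1 / s2_0))
  } else {
    phi <- c(0, 0)
  }

  res <- withr::with_seed(as.integer(seed), {
    scale <- c(0.15, 0.3)
    cur_lp <- log_post(phi[1], phi[2])
    draws <- matrix(NA_real_, n_iter, 2L)
    accepted <- logical(n_iter)
    batch_acc <- 0L
    for (it in seq_len(n_iter)) {
      prop <- phi + rnorm(2L) * scale
      prop_lp <- log_post(prop[1], prop[2])
      if (is.finite(prop_lp) && log(runif(1)) < prop_lp - cur_lp) {
        phi <- prop
        cur_lp <- prop_lp
        accepted[it] <- TRUE
        batch_acc <- batch_acc + 1L
      }
      draws[it, ] <- phi
      if (it <= burn_in && it %% 100L == 0L) {
        rate <- batch_acc / 100
        scale <- scale * exp(rate - 0.3)
        batch_acc <- 0L
      }
    }
    list(draws = draws, accepted = accepted, scale = scale)
  })

  post <- res$draws[(burn_in + 1L):n_iter, , drop = FALSE]
  acc_rate <- mean(res$accepted[(burn_in + 1L):n_iter])
  mu_hat <- mean(post[, 1])
  prec_hat <- mean(exp(post[, 2]))
  sigma2_hat <- 1 / prec_hat
  warnings <- if (acc_rate < 0.05 || acc_rate > 0.95) {
    sprintf("post-adaptation acceptance rate %.3f outside [0.05, 0.95]", acc_rate)
  } else {
    character()
  }
  ll <- if (is.null(ct)) NA_real_ else {
    sum(ct$m * lnp_log_terms(ct$x, mu_hat, sigma2_hat, rel_tol = rel_tol))
  }
  new_mix_fit("lnp",
    params = list(mu = mu_hat, sigma2 = sigma2_hat),
    loglik = ll, converged = TRUE, n_iter = n_iter,
    warnings = warnings,
    nobs = if (is.null(ct)) 0L else ct$n,
    precision = prec_hat,
    accept_rate = acc_rate,
    burn_in = burn_in,
    seed = as.integer(seed),
    mcmc = tibble(
      iter = seq_len(n_iter),
      mu = res$draws[, 1],
      precision = exp(res$draws[, 2]),
      accepted = res$accepted
    )
  )
}
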