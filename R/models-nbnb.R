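# psi is the unconstrained parameter vector used for EM fixed-point
# iteration and SQUAREM extrapolation:
#   psi = (qlogis(tau), log mu1, log r1, log mu2, log r2)
nbnb_pack <- function(p) {
  c(qlogis(min(max(p$tau, 1e-12), 1 - 1e-12)),
    log(p$mu1), log(p$r1), log(p$mu2), log(p$r2))
}

nbnb_unpack <- function(psi) {
  list(
    tau = plogis(psi[1]),
    mu1 = exp(psi[2]), r1 = exp(psi[3]),
    mu2 = exp(psi[4]), r2 = exp(psi[5])
  )
}

nbnb_loglik_ct <- function(p, ct) {
  f <- (1 - p$tau) * dnbinom(ct$x, size = p$r1, mu = p$mu1) +
    p$tau * dnbinom(ct$x, size = p$r2, mu = p$mu2)
  sum(ct$m * log(f))
}

# one EM step on the packed scale.  E-step: responsibilities of the
# second (high-mean) component; M-step: tau = mean responsibility, each
# NB component refit by weighted profile maximum likelihood.
nbnb_em_step <- function(psi, ct) {
  p <- nbnb_unpack(psi)
  l1 <- log1p(-p$tau) + dnbinom(ct$x, size = p$r1, mu = p$mu1, log = TRUE)
  l2 <- log(p$tau) + dnbinom(ct$x, size = p$r2, mu = p$mu2, log = TRUE)
  mx <- pmax(l1, l2)
  resp <- exp(l2 - mx) / (exp(l1 - mx) + exp(l2 - mx))
  w2 <- ct$m * resp
  w1 <- ct$m - w2
  tau <- sum(w2) / ct$n
  if (tau < 1e-12 || tau > 1 - 1e-12 || sum(w1) <= 0 || sum(w2) <= 0) {
    return(psi)  # collapsed; fixed point, flagged degenerate by the driver
  }
  c1 <- nb_fit_weighted(ct$x, w1, r_start = p$r1)
  c2 <- nb_fit_weighted(ct$x, w2, r_start = p$r2)
  nbnb_pack(list(tau = tau, mu1 = c1$mu, r1 = c1$r, mu2 = c2$mu, r2 = c2$r))
}

nbnb_auto_init <- function(ct) {
  xs <- rep(ct$x, ct$m)
  q <- quantile(xs, 0.90, type = 1)
  lo <- xs[xs <= q]
  hi <- xs[xs > q]
  if (length(hi) < 2L) {
    hi <- xs[xs >= q]
    lo <- xs[xs < q]
    if (length(lo) < 2L) {
      # nearly constant data: perturbed split around the mean
      m <- mean(xs)
      return(list(tau = 0.1, mu1 = max(m * 0.8, 1e-3), r1 = 10,
                  mu2 = m * 1.5 + 1, r2 = 1))
    }
  }
  mom <- function(v) {
    mu <- max(mean(v), 1e-3)
    r <- if (var(v) > mu) mu^2 / (var(v) - mu) else 100
    list(mu = mu, r = min(max(r, 1e-3), 1e4))
  }
  a <- mom(lo); b <- mom(hi)
  if (b$mu <= a$mu) b$mu <- a$mu * 2 + 1
  list(tau = length(hi) / length(xs), mu1 = a$mu, r1 = a$r, mu2 = b$mu, r2 = b$r)
}

#' Fit the two-component negative binomial (NB-NB) mixture
#'
#' Counts are modelled as a latent two-population mixture: with
#' probability `1 - tau` a bin's count is NB(`mu1`, `r1`) (the bulk
#' background) and with probability `tau` it is NB(`mu2`, `r2`) (the
#' heavy tail of high-count artifact bins).  Equivalently, the latent
#' Poisson rate is a mixture of two gamma distributions.  The maximum
#' likelihood estimate is found with the EM algorithm, optionally
#' accelerated by SQUAREM (first-order squared extrapolation with
#' step-length safeguarding); whenever an extrapolated step fails to
#' increase the log-likelihood the plain EM step is used instead, so the
#' recorded log-likelihood trace is always non-decreasing.  Components
#' are reordered so that `mu1 <= mu2` before return.
#'
#' @inheritParams fit_poisson
#' @param init `"auto"` (split at the 0.90 empirical quantile and fit
#'   each part by method of moments) or a named list with entries `tau`,
#'   `mu1`, `r1`, `mu2`, `r2`.
#' @param max_iter Maximum EM cycles.
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (with a parallel max-abs parameter-change test at 1e-6).
#' @param accelerate Use SQUAREM acceleration (default `TRUE`).
#' @param seed Unused (the fit is deterministic given `init`); accepted
#'   so that all model-fitting calls share a signature.
#' @return A [mix_fit] of subclass `nbnb_fit`; `trace` holds the
#'   per-cycle log-likelihoods and `n_em_steps` the number of EM-map
#'   evaluations, the cost unit that SQUAREM economises.
#' @examples
#' x <- simulate_counts(
#'   mix_gamma_gamma(0.05, shape1 = 10, rate1 = 5, shape2 = 0.8, rate2 = 0.8 / 30),
#'   n = 5000, seed = 1
#' )
#' fit_nbnb(x)
#' @export
fit_nbnb <- function(counts, init = "auto", max_iter = 500L, tol = 1e-8,
                     accelerate = TRUE, seed = NULL) {
  ct <- count_table(counts)
  if (length(ct$x) < 2L) abort("counts must contain at least 2 distinct values")
  p0 <- if (identical(init, "auto")) nbnb_auto_init(ct) else init
  if (!all(c("tau", "mu1", "r1", "mu2", "r2") %in% names(p0))) {
    abort("`init` must be \"auto\" or a list with tau, mu1, r1, mu2, r2")
  }
  psi <- nbnb_pack(p0)
  ll <- nbnb_loglik_ct(nbnb_unpack(psi), ct)
  trace <- ll
  n_em <- 0L
  converged <- FALSE
  iter <- 0L

  em <- function(psi) {
    n_em <<- n_em + 1L
    nbnb_em_step(psi, ct)
  }

  for (iter in seq_len(max_iter)) {
    psi_old <- psi
    ll_old <- ll
    if (accelerate) {
      p1 <- em(psi)
      p2 <- em(p1)
      r <- p1 - psi
      v <- (p2 - p1) - r
      vn <- sqrt(sum(v^2))
      if (vn < 1e-14) {
        psi_new <- p2
      } else {
        alpha <- -sqrt(sum(r^2)) / vn
        alpha <- min(alpha, -1)  # safeguard: never shorter than plain EM
        cand <- psi - 2 * alpha * r + alpha^2 * v
        psi_new <- em(cand)  # stabilising EM step
        ll_new <- nbnb_loglik_ct(nbnb_unpack(psi_new), ct)
        ll_p2 <- nbnb_loglik_ct(nbnb_unpack(p2), ct)
        if (!is.finite(ll_new) || ll_new < ll_p2) psi_new <- p2  # monotone fallback
      }
    } else {
      psi_new <- em(psi)
    }
    ll <- nbnb_loglik_ct(nbnb_unpack(psi_new), ct)
    psi <- psi_new
    trace <- c(trace, ll)
    param_delta <- max(abs(psi - psi_old))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10) || param_delta < 1e-6) {
      converged <- TRUE
      break
    }
  }

  p <- nbnb_unpack(psi)
  warnings <- character()
  if (p$tau < 1e-4 || p$tau > 1 - 1e-4) {
    warnings <- "degenerate_to_single_NB"
    converged <- TRUE
  }
  if (p$mu1 > p$mu2) {  # canonical order: component 1 is the low-mean bulk
    p <- list(tau = 1 - p$tau, mu1 = p$mu2, r1 = p$r2, mu2 = p$mu1, r2 = p$r1)
  }
  new_mix_fit("nbnb",
    params = p, loglik = ll, converged = converged, n_iter = iter,
    trace = trace, warnings = warnings, nobs = ct$n, n_em_steps = n_em
  )
}
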