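#' Discrete mixing distributions
#'
#' The nonparametric MLE of the Poisson mixing distribution is discrete:
#' `L` support points `theta` (the latent rates) with weights `pi`.
#' `discrete_mixture()` validates and constructs one.
#'
#' @param theta Strictly increasing non-negative support points.
#' @param pi Positive weights summing to 1 (within 1e-12 after the
#'   internal renormalisation).
#' @return An object of class `discrete_mixture`.
#' @export
discrete_mixture <- function(theta, pi) {
  if (length(theta) != length(pi) || length(theta) == 0L) {
    abort("`theta` and `pi` must be non-empty and of equal length")
  }
  if (any(theta < 0)) abort("`theta` must be non-negative")
  if (is.unsorted(theta, strictly = TRUE)) abort("`theta` must be strictly increasing")
  if (any(pi <= 0)) abort("`pi` must be positive (prune zeros before constructing)")
  s <- sum(pi)
  if (abs(s - 1) > 1e-8) abort("`pi` must sum to 1")
  structure(
    list(theta = as.double(theta), pi = as.double(pi) / s, L = length(theta)),
    class = "discrete_mixture"
  )
}

#' @export
print.discrete_mixture <- function(x, ...) {
  cat(sprintf("<discrete mixing distribution, L = %d>\n", x$L))
  print(tibble(theta = x$theta, pi = x$pi))
  invisible(x)
}

#' @export
pmf.discrete_mixture <- function(object, x, ...) {
  drop(outer(x, object$theta, dpois) %*% object$pi)
}

#' @export
mixing_cdf.discrete_mixture <- function(object, lambda, ...) {
  vapply(lambda, function(l) sum(object$pi[object$theta <= l]), numeric(1))
}

# mixture pmf at the unique observed counts; errors if the mixture puts
# zero probability on an observed count (likelihood would be -Inf)
mixture_density <- function(ct, theta, pi) {
  P <- outer(ct$x, theta, dpois)
  f <- drop(P %*% pi)
  list(P = P, f = f)
}

mixture_loglik_ct <- function(ct, theta, pi) {
  f <- drop(outer(ct$x, theta, dpois) %*% pi)
  if (any(f <= 0)) return(-Inf)
  sum(ct$m * log(f))
}

#' Gradient function of the mixture log-likelihood
#'
#' The directional derivative of the log-likelihood as probability mass
#' is shifted from the current mixing distribution `G` towards a point
#' mass at `theta_star`:
#' `d(theta*; G) = sum_j [ f_P(x_j; theta*) / f_G(x_j) - 1 ]`.
#' At the NPMLE, `d <= 0` for every candidate rate, with equality on the
#' support; a positive value identifies a rate worth adding.
#'
#' @param theta_star Candidate support point(s), non-negative; vectorised.
#' @param mixture A [discrete_mixture()].
#' @param counts A count table or vector.
#' @return `d(theta_star; G)`, one value per candidate.
#' @export
gradient_function <- function(theta_star, mixture, counts) {
  if (any(theta_star < 0)) abort("`theta_star` must be non-negative")
  ct <- count_table(counts)
  f <- drop(outer(ct$x, mixture$theta, dpois) %*% mixture$pi)
  if (any(f <= 0)) {
    abort("mixture assigns zero probability to an observed count (log-likelihood is -Inf)")
  }
  ratio <- outer(ct$x, theta_star, dpois) / f
  drop(crossprod(ratio, ct$m)) - ct$n
}

#' Weight MLE for a fixed support (constrained-Newton inner solve)
#'
#' Given fixed support points `theta`, finds the maximum likelihood
#' weights `pi` on the probability simplex.  Each inner iteration solves
#' the constrained least-squares problem
#' `min || S pi' - 2 * 1 ||^2` over the simplex, where
#' `S_ij = d l_j / d pi_i = f_P(x_j; theta_i) / f_G(x_j)` (the
#' constrained-Newton step), followed by a monotone line search; the
#' iteration is repeated until the weights are stationary, which yields
#' the exact weight MLE for the given support.  The returned weights may
#' contain (numerical) zeros, pruned by the caller.
#'
#' @param theta Non-empty, strictly increasing support points.
#' @param counts A count table or vector.
#' @param pi_init Optional starting weights (defaults to uniform).
#' @param max_inner,tol Inner iteration controls.
#' @return A weight vector on the simplex (sums to 1 within 1e-12).
#' @export
update_weights <- function(theta, counts, pi_init = NULL, max_inner = 100L,
                           tol = 1e-12) {
  if (length(theta) == 0L) abort("`theta` must be non-empty")
  if (is.unsorted(theta, strictly = TRUE)) abort("`theta` must be strictly increasing")
  ct <- count_table(counts)
  L <- length(theta)
  if (L == 1L) return(1)
  pi_cur <- pi_init %||% rep(1 / L, L)
  pi_cur <- pmax(pi_cur, 0)
  pi_cur <- pi_cur / sum(pi_cur)
  P <- outer(ct$x, theta, dpois)
  sw <- sqrt(ct$m)
  ll_cur <- mixture_loglik_ct(ct, theta, pi_cur)
  if (!is.finite(ll_cur)) {
    pi_cur <- rep(1 / L, L)
    ll_cur <- mixture_loglik_ct(ct, theta, pi_cur)
    if (!is.finite(ll_cur)) abort("support assigns zero probability to an observed count")
  }

  # safeguarded move from pi_cur towards pi_prop: step halving until the
  # log-likelihood does not decrease
  take_step <- function(pi_cur, ll_cur, pi_prop) {
    t_step <- 1
    repeat {
      cand <- pi_cur + t_step * (pi_prop - pi_cur)
      ll_cand <- mixture_loglik_ct(ct, theta, cand)
      if (is.finite(ll_cand) && ll_cand >= ll_cur - 1e-12) {
        return(list(pi = cand, ll = ll_cand))
      }
      t_step <- t_step / 2
      if (t_step < 1e-14) return(list(pi = pi_cur, ll = ll_cur))
    }
  }

  for (inner in seq_len(max_inner)) {
    f <- drop(P %*% pi_cur)
    # stationarity: the per-point gradient is 0 on the active support at
    # the weight MLE and <= 0 off it
    g <- drop(crossprod(P / f, ct$m)) - ct$n
    if (max(g) <= 1e-10 * ct$n && max(abs(g[pi_cur > 0])) <= 1e-10 * ct$n) break
    pi_prev <- pi_cur

    # multiplicative (EM) step on the weights: cheap, monotone, and
    # activates support points whose density is currently underweighted
    em <- pi_cur * (g + ct$n) / ct$n
    if (sum(em) > 0) {
      st <- take_step(pi_cur, ll_cur, em / sum(em))
      pi_cur <- st$pi
      ll_cur <- st$ll
      f <- drop(P %*% pi_cur)
    }

    # constrained-Newton step: least squares || S pi' - 2.1 || on the
    # simplex (sum-to-one via a penalty row at the scale of ||b||),
    # solved as column-equilibrated NNLS and then renormalised exactly
    A <- (P / f) * sw
    b <- 2 * sw
    pen <- 10 * sqrt(sum(ct$m))
    cs <- apply(abs(A), 2, max)
    cs[cs <= 0 | !is.finite(cs)] <- 1
    Aa <- rbind(sweep(A, 2, cs, "/"), pen / cs)
    sol <- tryCatch(
      pracma::lsqnonneg(Aa, c(b, pen))$x / cs,
      error = function(e) NULL
    )
    if (!is.null(sol) && all(is.finite(sol)) && sum(sol) > 0) {
      st <- take_step(pi_cur, ll_cur, sol / sum(sol))
      pi_cur <- st$pi
      ll_cur <- st$ll
    }
    if (max(abs(pi_cur - pi_prev)) < 1e-13) break
  }
  pi_cur / sum(pi_cur)
}

cnm_candidate_grid <- function(ct, theta, grid_size) {
  pos <- ct$x[ct$x > 0]
  # when zeros are observed the NPMLE can place an atom anywhere in
  # (0, min positive count), so the geometric grid must reach down to it
  lo <- if (!length(pos) || min(ct$x) == 0) 1e-3 else max(1e-3, min(pos) / 2)
  hi <- max(2 * max(ct$x) + 1, lo * 2)
  geo <- exp(seq(log(lo), log(hi), length.out = grid_size))
  mids <- if (length(theta) > 1L) (theta[-1] + theta[-length(theta)]) / 2 else numeric()
  cand <- sort(unique(c(ct$x, geo, mids, theta)))
  if (min(ct$x) == 0) cand <- c(0, cand[cand > 0])
  cand
}

# gradient function on the unique-count representation with the mixture
# density at the observed counts precomputed (hot path of cnm_fit)
gradient_ct <- function(theta_star, ct, f) {
  drop(crossprod(outer(ct$x, theta_star, dpois) / f, ct$m)) - ct$n
}

# locate all local maxima of d over the candidate grid with d > 0 and
# polish each by bounded scalar maximisation in its bracketing interval
cnm_new_support <- function(ct, f, cand, d) {
  k <- length(cand)
  up <- c(TRUE, diff(d) > 0)
  down <- c(diff(d) < 0, TRUE)
  is_max <- up & down & d > 0
  idx <- which(is_max)
  if (!length(idx)) return(numeric())
  obj <- function(t) gradient_ct(t, ct, f)
  polish <- function(i) {
    lo <- if (i > 1L) cand[i - 1L] else max(0, cand[i] - 1)
    hi <- if (i < k) cand[i + 1L] else cand[i] + 1
    if (hi - lo < 1e-10) return(cand[i])
    opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
    if (opt$objective >= d[i]) opt$maximum else cand[i]
  }
  pts <- vapply(idx, polish, numeric(1))
  pts[obj(pts) > 0]
}

#' Nonparametric MLE of the Poisson mixing distribution (CNM)
#'
#' Computes the NPMLE of the mixing distribution of a Poisson mixture by
#' the constrained Newton method.  Starting from a single support point
#' at the sample mean, each iteration (i) evaluates the gradient function
#' over a candidate grid (the distinct observed counts, a geometric grid,
#' and midpoints of the current support), adds every polished local
#' maximiser with a positive gradient, (ii) recomputes the weight MLE
#' with [update_weights()], and (iii) deletes support points whose weight
#' has fallen to zero.  Iteration stops when the largest gradient over
#' the grid is at most `grad_tol` (first-order optimality) or `max_iter`
#' is reached; a non-converged result is still returned for downstream
#' diagnostics.  The log-likelihood is non-decreasing across iterations
#' and the number of support points never exceeds the number of distinct
#' observed counts.
#'
#' @inheritParams fit_poisson
#' @param grid_size Number of points in the geometric candidate grid.
#' @param grad_tol Gradient tolerance; default `1e-6 * n` (the gradient
#'   scales with sample size, so the default is scale-free).
#' @param max_iter Maximum CNM iterations.
#' @return An object of class `cnm_fit` with components `mixture`
#'   (a [discrete_mixture()]), `loglik`, `max_gradient`, `n_iter`,
#'   `converged` and `trace`.
#' @examples
#' x <- simulate_counts(mix_gamma(2, 0.5), n = 500, seed = 1)
#' cnm_fit(x)
#' @export
cnm_fit <- function(counts, grid_size = 100L, grad_tol = NULL, max_iter = 200L) {
  ct <- count_table(counts)
  grad_tol <- grad_tol %||% (1e-6 * ct$n)
  theta <- sum(ct$m * ct$x) / ct$n
  pi_cur <- 1
  # a single point at the mean can assign zero (underflowed) probability
  # to extreme observed counts; seed those counts into the support so the
  # likelihood is finite from the start
  f0 <- drop(outer(ct$x, theta, dpois) %*% pi_cur)
  if (any(f0 <= 0)) {
    extra <- ct$x[f0 <= 0]
    theta <- sort(unique(c(theta, extra)))
    pi_cur <- rep(1e-4 / length(extra), length(theta))
    pi_cur[match(sum(ct$m * ct$x) / ct$n, theta)] <- 1 - 1e-4
    pi_cur <- pi_cur / sum(pi_cur)
  }
  ll <- mixture_loglik_ct(ct, theta, pi_cur)
  trace <- ll
  converged <- FALSE
  max_grad <- Inf
  xvec <- rep(ct$x, ct$m)

  for (iter in seq_len(max_iter)) {
    f_cur <- drop(outer(ct$x, theta, dpois) %*% pi_cur)
    cand <- cnm_candidate_grid(ct, theta, grid_size)
    d <- gradient_ct(cand, ct, f_cur)
    max_grad <- max(d)
    if (max_grad <= grad_tol) {
      # verify first-order optimality on a 10x finer grid before
      # declaring convergence; a coarse grid can straddle a narrow
      # positive-gradient peak
      cand <- cnm_candidate_grid(ct, theta, 10L * grid_size)
      d <- gradient_ct(cand, ct, f_cur)
      max_grad <- max(d)
      if (max_grad <= grad_tol) {
        converged <- TRUE
        break
      }
    }
    new_pts <- cnm_new_support(ct, f_cur, cand, d)
    all_theta <- sort(unique(c(theta, new_pts)))
    # drop numerically duplicated points
    if (length(all_theta) > 1L) {
      keep <- c(TRUE, diff(all_theta) > 1e-10 * (1 + all_theta[-1]))
      all_theta <- all_theta[keep]
    }
    # warm start: keep the current weights but give every point (in
    # particular the newly inserted ones) a small floor so the
    # multiplicative inner step can activate them
    init <- numeric(length(all_theta))
    init[match(theta, all_theta)] <- pi_cur
    init <- 0.98 * init + 0.02 / length(init)
    pi_new <- update_weights(all_theta, xvec, pi_init = init)

    # prune zero (sub-floating-point) weights
    keep <- pi_new > 1e-10
    if (!any(keep)) keep <- pi_new == max(pi_new)
    theta_new <- all_theta[keep]
    pi_new <- pi_new[keep] / sum(pi_new[keep])

    # merge support points closer than 1e-4 * (1 + theta), unless the
    # merge would reduce the log-likelihood materially
    if (length(theta_new) > 1L) {
      close <- diff(theta_new) < 1e-4 * (1 + theta_new[-1])
      if (any(close)) {
        grp <- cumsum(c(TRUE, !close))
        th_m <- as.numeric(tapply(theta_new * pi_new, grp, sum) /
          tapply(pi_new, grp, sum))
        pi_m <- as.numeric(tapply(pi_new, grp, sum))
        if (mixture_loglik_ct(ct, th_m, pi_m) >= mixture_loglik_ct(ct, theta_new, pi_new) - 1e-10) {
          theta_new <- th_m
          pi_new <- pi_m
        }
      }
    }
    ll_new <- mixture_loglik_ct(ct, theta_new, pi_new)
    if (ll_new < ll - 1e-9) {
      # no admissible improvement; stop with the previous iterate
      break
    }
    theta <- theta_new
    pi_cur <- pi_new
    ll <- ll_new
    trace <- c(trace, ll)
  }

  mix <- discrete_mixture(theta, pi_cur)
  cand <- cnm_candidate_grid(ct, theta, 10L * grid_size)
  max_grad <- max(gradient_ct(cand, ct, drop(outer(ct$x, theta, dpois) %*% pi_cur)))
  if (max_grad <= grad_tol) converged <- TRUE
  structure(
    list(
      mixture = mix, loglik = ll, max_gradient = max_grad,
      n_iter = iter, converged = converged, trace = trace, nobs = ct$n,
      grad_tol = grad_tol
    ),
    class = "cnm_fit"
  )
}

#' @export
print.cnm_fit <- function(x, ...) {
  cat(sprintf(
    "<CNM nonparametric MLE>  L = %d  loglik = %.6g  max gradient = %.3g  converged = %s\n",
    x$mixture$L, x$loglik, x$max_gradient, x$converged
  ))
  print(tibble(theta = x$mixture$theta, pi = x$mixture$pi))
  invisible(x)
}

#' @export
pmf.cnm_fit <- function(object, x, ...) pmf(object$mixture, x, ...)

#' @export
mixing_cdf.cnm_fit <- function(object, lambda, ...) mixing_cdf(object$mixture, lambda, ...)

#' @export
tidy.cnm_fit <- function(x, ...) {
  tibble(theta = x$mixture$theta, pi = x$mixture$pi)
}

#' @export
glance.cnm_fit <- function(x, ...) {
  tibble(
    L = x$mixture$L, logLik = x$loglik, max_gradient = x$max_gradient,
    nobs = x$nobs, converged = x$converged, n_iter = x$n_iter
  )
}
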