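#' Mixing-distribution specifications
#'
#' The package models bin counts as Poisson draws whose rate is itself a
#' random variable with mixing density f(lambda).  These constructors
#' describe the mixing distributions the simulator can draw from:
#' a degenerate point mass (plain Poisson counts), a gamma (negative
#' binomial counts), a log-normal (log-normal Poisson counts), a
#' two-component gamma mixture (NB-NB counts) and an arbitrary discrete
#' distribution.
#'
#' A gamma with `shape = r` and `rate = r / mu` mixes to a negative
#' binomial with mean `mu` and dispersion `r` (variance `mu + mu^2/r`);
#' this fixes the NB parametrisation used package-wide.
#'
#' @param lambda Poisson rate (> 0 allowed to be 0 for a point mass at 0).
#' @param shape,rate Gamma parameters (> 0).
#' @param mu Log-scale mean of the log-normal.
#' @param sigma2 Log-scale variance of the log-normal (> 0).
#' @param tau Mixing probability of the second (high-rate) component,
#'   in `[0, 1]`.
#' @param shape1,rate1,shape2,rate2 Gamma parameters of the two components.
#' @param theta Support points of a discrete mixing distribution
#'   (non-negative, strictly increasing).
#' @param pi Weights of the discrete support points (positive, sum to 1).
#' @return An object of class `mixing_spec`.
#' @examples
#' mix_gamma(shape = 2, rate = 2 / 10)  # mixes to NB(mu = 10, r = 2)
#' @name mixing_spec
NULL

new_mixing_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "mixing_spec")
}

#' @rdname mixing_spec
#' @export
mix_point <- function(lambda) {
  if (lambda < 0) abort("`lambda` must be non-negative")
  new_mixing_spec("point", lambda = lambda)
}

#' @rdname mixing_spec
#' @export
mix_gamma <- function(shape, rate) {
  if (shape <= 0 || rate <= 0) abort("gamma `shape` and `rate` must be positive")
  new_mixing_spec("gamma", shape = shape, rate = rate)
}

#' @rdname mixing_spec
#' @export
mix_lognormal <- function(mu, sigma2) {
  if (sigma2 <= 0) abort("`sigma2` must be positive")
  new_mixing_spec("lognormal", mu = mu, sigma2 = sigma2)
}

#' @rdname mixing_spec
#' @export
mix_gamma_gamma <- function(tau, shape1, rate1, shape2, rate2) {
  if (tau < 0 || tau > 1) abort("`tau` must lie in [0, 1]")
  if (any(c(shape1, rate1, shape2, rate2) <= 0)) {
    abort("gamma shapes and rates must be positive")
  }
  new_mixing_spec("gamma_gamma_mixture",
    tau = tau,
    shape1 = shape1, rate1 = rate1, shape2 = shape2, rate2 = rate2
  )
}

#' @rdname mixing_spec
#' @export
mix_discrete <- function(theta, pi) {
  if (length(theta) != length(pi) || length(theta) == 0L) {
    abort("`theta` and `pi` must be non-empty and of equal length")
  }
  if (any(theta < 0)) abort("`theta` must be non-negative")
  if (is.unsorted(theta, strictly = TRUE)) abort("`theta` must be strictly increasing")
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    abort("`pi` must be positive and sum to 1")
  }
  new_mixing_spec("discrete", theta = theta, pi = pi / sum(pi))
}

draw_lambda <- function(spec, m) {
  switch(spec$kind,
    point = rep(spec$lambda, m),
    gamma = rgamma(m, shape = spec$shape, rate = spec$rate),
    lognormal = rlnorm(m, meanlog = spec$mu, sdlog = sqrt(spec$sigma2)),
    gamma_gamma_mixture = {
      z <- runif(m) < spec$tau
      lam <- rgamma(m, shape = spec$shape1, rate = spec$rate1)
      if (any(z)) lam[z] <- rgamma(sum(z), shape = spec$shape2, rate = spec$rate2)
      lam
    },
    discrete = {
      if (length(spec$theta) == 1L) {
        rep(spec$theta, m)  # reduces exactly to Poisson sampling
      } else {
        sample(spec$theta, m, replace = TRUE, prob = spec$pi)
      }
    },
    abort(sprintf("unknown mixing kind '%s'", spec$kind))
  )
}

#' Simulate binned counts from a Poisson mixture
#'
#' For each of `n` bins: with probability `nu` the count is set to zero
#' (zero-inflation, applied as a Bernoulli mask before any rate draw);
#' otherwise a rate is drawn from `spec` and the count is Poisson with
#' that rate.  Fully reproducible given `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param spec A [mixing_spec] object.
#' @param n Number of bins (>= 1).
#' @param nu Zero-inflation probability in `[0, 1]` (default 0).
#' @param seed Integer seed; required.
#' @return A tibble with a `count` column of length `n`.
#' @examples
#' simulate_counts(mix_gamma(2, 0.2), n = 5, seed = 1)
#' @export
simulate_counts <- function(spec, n, nu = 0, seed) {
  if (!inherits(spec, "mixing_spec")) abort("`spec` must be a mixing_spec")
  if (n < 1) abort("`n` must be at least 1")
  if (nu < 0 || nu > 1) abort("`nu` must lie in [0, 1]")
  if (missing(seed)) abort("`seed` is required")
  counts <- withr::with_seed(as.integer(seed), {
    mask <- if (nu > 0) runif(n) < nu else rep(FALSE, n)
    out <- numeric(n)
    m <- sum(!mask)
    if (m > 0L) {
      lam <- draw_lambda(spec, m)
      out[!mask] <- rpois(m, lam)
    }
    out
  })
  tibble(count = counts)
}

#' Mixing-distribution CDF of a simulation spec
#'
#' @param object A [mixing_spec].
#' @param lambda Rate values at which to evaluate the CDF.
#' @param ... Unused.
#' @export
mixing_cdf.mixing_spec <- function(object, lambda, ...) {
  switch(object$kind,
    point = as.numeric(lambda >= object$lambda),
    gamma = pgamma(lambda, shape = object$shape, rate = object$rate),
    lognormal = plnorm(lambda, meanlog = object$mu, sdlog = sqrt(object$sigma2)),
    gamma_gamma_mixture = (1 - object$tau) *
      pgamma(lambda, shape = object$shape1, rate = object$rate1) +
      object$tau * pgamma(lambda, shape = object$shape2, rate = object$rate2),
    discrete = vapply(
      lambda, function(l) sum(object$pi[object$theta <= l]), numeric(1)
    )
  )
}
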