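#' Fitted count-model objects
#'
#' All model fits return an object of class `mix_fit` (with a
#' model-specific subclass) carrying the fitted parameters, the final
#' log-likelihood, a convergence flag, the iteration count and, for
#' iterative fits, the per-iteration log-likelihood trace.
#'
#' @name mix_fit
NULL

new_mix_fit <- function(model, params, loglik, converged = TRUE, n_iter = 0L,
                        trace = NULL, warnings = character(), ...) {
  structure(
    list(
      model = model, params = params, loglik = loglik,
      converged = converged, n_iter = n_iter, trace = trace,
      warnings = warnings, ...
    ),
    class = c(paste0(model, "_fit"), "mix_fit")
  )
}

#' @export
print.mix_fit <- function(x, ...) {
  cat(sprintf(
    "<%s fit>  loglik = %.6g  converged = %s  iterations = %d\n",
    x$model, x$loglik, x$converged, x$n_iter
  ))
  est <- unlist(x$params)
  cat(paste(sprintf("  %s = %.6g", names(est), est), collapse = "\n"), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Count probability mass function of a fitted model
#'
#' @param object A fitted model ([mix_fit]) or a [cnm_fit()] discrete
#'   mixture.
#' @param x Non-negative integer count values.
#' @param ... Passed to methods.
#' @return `pmf()` returns P(X = x) under the fitted count model;
#'   `mixing_cdf()` returns the CDF of the implied mixing distribution of
#'   the latent Poisson rate.
#' @export
pmf <- function(object, x, ...) UseMethod("pmf")

#' @rdname pmf
#' @param lambda Rate values at which to evaluate the mixing CDF.
#' @export
mixing_cdf <- function(object, lambda, ...) UseMethod("mixing_cdf")

#' @export
pmf.poisson_fit <- function(object, x, ...) dpois(x, object$params$mu)

#' @export
pmf.nb_fit <- function(object, x, ...) {
  dnbinom(x, size = object$params$r, mu = object$params$mu)
}

#' @export
pmf.nbnb_fit <- function(object, x, ...) {
  p <- object$params
  (1 - p$tau) * dnbinom(x, size = p$r1, mu = p$mu1) +
    p$tau * dnbinom(x, size = p$r2, mu = p$mu2)
}

#' @export
pmf.lnp_fit <- function(object, x, ...) {
  p <- object$params
  exp(lnp_log_terms(x, p$mu, p$sigma2))
}

#' @export
mixing_cdf.poisson_fit <- function(object, lambda, ...) {
  as.numeric(lambda >= object$params$mu)
}

#' @export
mixing_cdf.nb_fit <- function(object, lambda, ...) {
  p <- object$params
  pgamma(lambda, shape = p$r, rate = p$r / p$mu)
}

#' @export
mixing_cdf.lnp_fit <- function(object, lambda, ...) {
  p <- object$params
  plnorm(lambda, meanlog = p$mu, sdlog = sqrt(p$sigma2))
}

#' @export
mixing_cdf.nbnb_fit <- function(object, lambda, ...) {
  p <- object$params
  (1 - p$tau) * pgamma(lambda, shape = p$r1, rate = p$r1 / p$mu1) +
    p$tau * pgamma(lambda, shape = p$r2, rate = p$r2 / p$mu2)
}

#' Tidiers for fitted count models
#'
#' @param x A [mix_fit] object.
#' @param ... Unused.
#' @return `tidy()` gives one row per parameter (`term`, `estimate`);
#'   `glance()` gives a one-row model summary.
#' @export
tidy.mix_fit <- function(x, ...) {
  est <- unlist(x$params)
  tibble(term = names(est), estimate = unname(est))
}

#' @rdname tidy.mix_fit
#' @export
glance.mix_fit <- function(x, ...) {
  tibble(
    model = x$model,
    logLik = x$loglik,
    nobs = x$nobs %||% NA_integer_,
    converged = x$converged,
    n_iter = x$n_iter
  )
}
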