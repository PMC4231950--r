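#' Fit the single-Poisson count model
#'
#' The Poisson MLE equates the expected mean to the observed mean, so
#' `mu` is the arithmetic mean of the counts, exactly.
#'
#' @param counts A count table or non-negative integer vector.
#' @return A [mix_fit] of subclass `poisson_fit`.
#' @examples
#' fit_poisson(c(0, 1, 2, 3, 4))
#' @export
fit_poisson <- function(counts) {
  ct <- count_table(counts)
  mu <- sum(ct$m * ct$x) / ct$n
  ll <- sum(ct$m * dpois(ct$x, mu, log = TRUE))
  new_mix_fit("poisson", list(mu = mu), loglik = ll, nobs = ct$n)
}

# dispersion search window, documented cap for degenerate data
.r_bounds <- c(1e-6, 1e6)

# weighted NB maximum likelihood in the mean-dispersion parametrisation
# (variance mu + mu^2/r).  The mean MLE is the weighted mean in closed
# form for any r, so only the dispersion needs a 1-D profile search over
# log r; `r_start` warm-starts the bracket for EM M-steps.
nb_fit_weighted <- function(x, w, r_start = NULL) {
  W <- sum(w)
  mu <- sum(w * x) / W
  if (mu <= 0) {
    return(list(mu = max(mu, 1e-12), r = .r_bounds[2], loglik = 0, capped = TRUE))
  }
  prof <- function(logr) sum(w * dnbinom(x, size = exp(logr), mu = mu, log = TRUE))
  lb <- log(.r_bounds[1]); ub <- log(.r_bounds[2])
  if (!is.null(r_start) && is.finite(r_start)) {
    lo <- max(lb, log(r_start) - 4); hi <- min(ub, log(r_start) + 4)
  } else {
    lo <- lb; hi <- ub
  }
  repeat {
    opt <- optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
    at_lo <- opt$maximum - lo < 1e-6 && lo > lb
    at_hi <- hi - opt$maximum < 1e-6 && hi < ub
    if (at_lo) lo <- max(lb, lo - 4)
    else if (at_hi) hi <- min(ub, hi + 4)
    else break
  }
  r <- exp(opt$maximum)
  capped <- (ub - opt$maximum) < 1e-4 || (opt$maximum - lb) < 1e-4
  if (capped) r <- if (ub - opt$maximum < 1e-4) .r_bounds[2] else .r_bounds[1]
  list(mu = mu, r = r, loglik = prof(log(r)), capped = capped)
}

#' Fit the single negative binomial count model
#'
#' Maximum likelihood in the mean-dispersion parametrisation
#' NB(`mu`, `r`) with variance `mu + mu^2/r`; equivalently a
#' gamma-mixed Poisson with mixing gamma(shape = `r`, rate = `r/mu`).
#' The NB likelihood has no closed-form MLE for `r`; the mean MLE equals
#' the sample mean and the dispersion is found by profile optimisation.
#' For underdispersed data (sample variance <= mean) the dispersion is
#' capped at 1e6 (at which point the NB is numerically Poisson) and a
#' warning flag is set instead of diverging.
#'
#' @inheritParams fit_poisson
#' @return A [mix_fit] of subclass `nb_fit`.
#' @examples
#' x <- simulate_counts(mix_gamma(shape = 2, rate = 0.2), n = 2000, seed = 1)
#' fit_nb(x)
#' @export
fit_nb <- function(counts) {
  ct <- count_table(counts)
  res <- nb_fit_weighted(ct$x, ct$m)
  warnings <- if (res$capped) "dispersion capped: data not overdispersed" else character()
  new_mix_fit("nb", list(mu = res$mu, r = res$r),
    loglik = res$loglik, nobs = ct$n, n_iter = 1L, warnings = warnings
  )
}
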