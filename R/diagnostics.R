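#' Probability mass tables
#'
#' A pmf table is a tibble with columns `x` (integers `0..x_max`) and
#' `prob`, plus a `tail_mass` attribute holding the probability beyond
#' `x_max`; probabilities and tail mass sum to 1.
#'
#' @param x Integer support `0..x_max`.
#' @param prob Probabilities, parallel to `x`.
#' @param tail_mass Probability mass beyond `x_max`.
#' @return A tibble of class `pmf_tbl`.
#' @export
new_pmf <- function(x, prob, tail_mass = 0) {
  if (any(prob < -1e-12)) abort("probabilities must be non-negative")
  prob <- pmax(prob, 0)
  tail_mass <- max(tail_mass, 0)
  tot <- sum(prob) + tail_mass
  if (abs(tot - 1) > 1e-9) abort("probabilities plus tail mass must sum to 1")
  out <- tibble(x = as.integer(x), prob = prob)
  attr(out, "tail_mass") <- tail_mass
  class(out) <- c("pmf_tbl", class(out))
  out
}

tail_mass <- function(p) attr(p, "tail_mass", exact = TRUE) %||% 0

#' Empirical pmf of observed counts
#'
#' Relative frequencies over `0..max(count)`; the tail mass is zero.
#'
#' @inheritParams fit_poisson
#' @return A [new_pmf()] table.
#' @examples
#' empirical_pmf(c(0, 0, 1, 1))
#' @export
empirical_pmf <- function(counts) {
  x <- count_values(counts)
  xmax <- max(x)
  freq <- tabulate(x + 1L, nbins = xmax + 1L) / length(x)
  new_pmf(0:xmax, freq, 0)
}

#' Recover the count distribution from a discrete mixing distribution
#'
#' The fitted count pmf implied by an NPMLE is the weighted sum of
#' Poisson pmfs over the support:
#' `f(x) = sum_i pi_i * f_P(x; theta_i)` for `x = 0..x_max`; mass beyond
#' `x_max` is reported as tail mass.  Comparing this recovery to the
#' empirical pmf shows whether the NPMLE retains the key features of the
#' data distribution.
#'
#' @param mixture A [discrete_mixture()] or [cnm_fit()] result.
#' @param x_max Largest count evaluated (>= 0).
#' @return A [new_pmf()] table.
#' @export
recover_pmf <- function(mixture, x_max) {
  if (x_max < 0) abort("`x_max` must be non-negative")
  if (inherits(mixture, "cnm_fit")) mixture <- mixture$mixture
  p <- pmf(mixture, 0:x_max)
  new_pmf(0:x_max, p, tail_mass = max(1 - sum(p), 0))
}

# pmf table of any fitted count model, truncated at x_max
fitted_pmf <- function(fit, x_max) {
  p <- pmf(fit, 0:x_max)
  new_pmf(0:x_max, p, tail_mass = max(1 - sum(p), 0))
}

#' Total variation distance between two pmf tables
#'
#' `d_TV = 0.5 * sum_x | f(x) - g(x) |`, computed over the union of the
#' two truncated supports (the shorter table is extended with zeros) with
#' the two tail masses compared as one extra cell.  Always in `[0, 1]`.
#'
#' @param f,g [new_pmf()] tables.
#' @return A single number in `[0, 1]`.
#' @examples
#' tv_distance(empirical_pmf(c(0, 1)), empirical_pmf(c(0, 0, 1, 1)))
#' @export
tv_distance <- function(f, g) {
  xmax <- max(max(f$x), max(g$x))
  pf <- numeric(xmax + 1L)
  pg <- numeric(xmax + 1L)
  pf[f$x + 1L] <- f$prob
  pg[g$x + 1L] <- g$prob
  0.5 * (sum(abs(pf - pg)) + abs(tail_mass(f) - tail_mass(g)))
}

#' Bounds on a continuous mixing CDF from the NPMLE
#'
#' If the discrete NPMLE arose from a continuous mixing distribution by
#' collapsing the mass of each cell of a partition of `[0, Inf)` onto one
#' support point, then the continuous CDF evaluated at support point
#' `theta_i` must lie in the half-open interval
#' `[sum_{j<i} pi_j, sum_{j<=i} pi_j)`.  These bounds assume the latent
#' rate is not zero-inflated.
#'
#' The bounds derivation assigns each support point its own partition
#' cell.  A numerically computed NPMLE can carry pairs of atoms a small
#' fraction of a Poisson standard deviation apart that share the mass of
#' one effective atom (the likelihood is almost flat between splitting
#' and coalescing); such pairs belong to a single partition cell, so by
#' default atoms closer than `collapse * sqrt(1 + theta)` (default: one Poisson standard deviation, the resolution scale of the Poisson kernel) are collapsed
#' (weights summed, locations weight-averaged) before the bounds are
#' formed.  Set `collapse = 0` to use the support verbatim.
#'
#' @param mixture A [discrete_mixture()] or [cnm_fit()] result.
#' @param collapse Collapse scale as a fraction of the local Poisson
#'   standard deviation (default 1; 0 disables).
#' @return A tibble with columns `theta`, `lower`, `upper`; consecutive
#'   rows telescope (`lower_i = upper_{i-1}`), `lower_1 = 0`,
#'   `upper_L = 1`.
#' @export
cdf_bounds <- function(mixture, collapse = 1) {
  if (inherits(mixture, "cnm_fit")) mixture <- mixture$mixture
  theta <- mixture$theta
  pi <- mixture$pi
  if (collapse > 0 && length(theta) > 1L) {
    grp <- cumsum(c(TRUE, diff(theta) >= collapse * sqrt(1 + theta[-length(theta)])))
    theta <- as.numeric(tapply(theta * pi, grp, sum) / tapply(pi, grp, sum))
    pi <- as.numeric(tapply(pi, grp, sum))
  }
  cum <- cumsum(pi)
  tibble(
    theta = theta,
    lower = c(0, cum[-length(cum)]),
    upper = cum
  )
}

#' Check a parametric mixing distribution against the NPMLE bounds
#'
#' Evaluates the model's mixing CDF at each NPMLE support point and
#' reports whether it falls inside the half-open bound
#' `[lower_i, upper_i)` from [cdf_bounds()]; equality at the upper bound
#' counts as a violation under the strict half-open convention.  The
#' returned table also carries `log(1 - CDF)` for survival-scale plots.
#'
#' @param fit A fitted model exposing [mixing_cdf()] (any [mix_fit] or a
#'   [mixing_spec]).
#' @param bounds A bounds table from [cdf_bounds()].
#' @return A tibble (`theta`, `lower`, `upper`, `cdf`, `pass`,
#'   `log_surv`) of class `mixing_fit_check`, with attribute
#'   `first_violation` (index of the first failing support point, or
#'   `NA`).
#' @export
check_mixing_fit <- function(fit, bounds) {
  cdf <- mixing_cdf(fit, bounds$theta)
  pass <- bounds$lower <= cdf & cdf < bounds$upper
  out <- tibble(
    theta = bounds$theta, lower = bounds$lower, upper = bounds$upper,
    cdf = cdf, pass = pass, log_surv = log(1 - cdf)
  )
  attr(out, "first_violation") <- if (any(!pass)) which(!pass)[1L] else NA_integer_
  class(out) <- c("mixing_fit_check", class(out))
  out
}

zero_adjust <- function(x, rho) {
  if (rho > 1) abort("`rho` must be at most 1")
  if (rho == 0) return(x)
  nz <- sum(x == 0)
  if (nz == 0L) abort("counts contain no zeros to adjust")
  if (rho > 0) {
    k <- round(rho * nz)
    if (k > 0) x <- x[-head(which(x == 0), k)]  # zeros are exchangeable
  } else {
    x <- c(x, numeric(round(-rho * nz)))
  }
  x
}

fit_model_by_name <- function(name, x, seed) {
  switch(name,
    poisson = fit_poisson(x),
    nb = fit_nb(x),
    nbnb = fit_nbnb(x, seed = seed),
    lnp = fit_lnp(x, seed = seed),
    abort(sprintf("unknown model '%s'", name))
  )
}

#' Zero-inflation scan
#'
#' Probes for zero-inflation by perturbing the zero count: for each
#' `rho > 0` a fraction `rho` of the zero-valued bins is deleted, and for
#' `rho < 0` a fraction `|rho|` of extra zeros is appended; each model is
#' refit to the adjusted counts and scored by total variation distance
#' against the adjusted empirical pmf (or against the CNM-recovered pmf
#' when `reference = "cnm"`).  Genuinely zero-inflated data shows a
#' d_TV minimum at positive `rho`; a model that simply cannot accommodate
#' the heavy tail of large counts shows a spurious minimum at large
#' `rho` even without zero-inflation.
#'
#' @inheritParams fit_poisson
#' @param rho_grid Zero-adjustment fractions, each at most 1 (negative
#'   values add zeros).  The row at `rho = 0` reproduces the unadjusted
#'   fit exactly.
#' @param models Character vector among `"poisson"`, `"nb"`, `"nbnb"`,
#'   `"lnp"`.
#' @param seed Integer seed governing model-fit initialisation (zero
#'   removal is deterministic because zeros are exchangeable).
#' @param reference `"empirical"` (default) or `"cnm"`.
#' @return A tibble (`rho`, `model`, `d_tv`, `loglik`, `converged`) of
#'   class `zero_scan`.
#' @export
zero_scan <- function(counts, rho_grid, models = c("poisson", "nb", "nbnb"),
                      seed = 1L, reference = c("empirical", "cnm")) {
  reference <- match.arg(reference)
  x0 <- count_values(counts)
  if (any(rho_grid > 1)) abort("`rho_grid` values must be at most 1")
  if (any(rho_grid != 0) && sum(x0 == 0) == 0L) {
    abort("counts contain no zeros to adjust")
  }
  rows <- purrr::map(rho_grid, function(rho) {
    x <- zero_adjust(x0, rho)
    ref <- if (reference == "empirical") {
      empirical_pmf(x)
    } else {
      recover_pmf(cnm_fit(x), x_max = max(x))
    }
    purrr::map(models, function(mod) {
      fit <- fit_model_by_name(mod, x, seed = seed)
      tibble(
        rho = rho, model = mod,
        d_tv = tv_distance(fitted_pmf(fit, max(x)), ref),
        loglik = fit$loglik, converged = fit$converged
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(rows) <- c("zero_scan", class(rows))
  rows
}

#' Posterior bin classification and de novo blacklist
#'
#' Under a fitted NB-NB mixture, the posterior probability that bin `i`
#' belongs to the high-count (artifact) component is
#' `P(Z_i = 1 | x_i) = tau f2(x_i) / (tau f2(x_i) + (1 - tau) f1(x_i))`.
#' Bins at or above `threshold` are flagged; when the counts carry
#' genomic coordinates, adjacent flagged bins are merged into a blacklist
#' region set (BED-style), built de novo from the data rather than taken
#' from an external resource.
#'
#' @param fit An `nbnb_fit` from [fit_nbnb()] (components ordered so
#'   `mu1 <= mu2`).
#' @inheritParams fit_poisson
#' @param threshold Posterior probability cut-off in (0, 1), default 0.5.
#' @return A list of class `bin_classification` with `bins` (per-bin
#'   tibble including `posterior` and `flagged`) and `blacklist` (merged
#'   region tibble; empty with a warning if the counts lack coordinates).
#' @export
classify_bins <- function(fit, counts, threshold = 0.5) {
  if (!inherits(fit, "nbnb_fit")) abort("`fit` must be an nbnb_fit")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1)")
  p <- fit$params
  if (p$mu1 > p$mu2) abort("`fit` must have mu1 <= mu2")
  bins <- as_counts(counts)
  x <- bins$count
  l1 <- log1p(-p$tau) + dnbinom(x, size = p$r1, mu = p$mu1, log = TRUE)
  l2 <- log(p$tau) + dnbinom(x, size = p$r2, mu = p$mu2, log = TRUE)
  posterior <- if (p$tau == 0) {
    numeric(length(x))
  } else if (p$tau == 1) {
    rep(1, length(x))
  } else {
    mx <- pmax(l1, l2)
    exp(l2 - mx) / (exp(l1 - mx) + exp(l2 - mx))
  }
  bins$posterior <- posterior
  bins$flagged <- posterior >= threshold
  has_coords <- all(c("chrom", "start", "end") %in% names(bins))
  if (has_coords) {
    flagged <- bins[bins$flagged, c("chrom", "start", "end")]
    blacklist <- if (nrow(flagged)) as_regions(flagged) else
      tibble(chrom = character(), start = double(), end = double())
  } else {
    if (any(bins$flagged)) {
      warn("counts lack genomic coordinates; returning posteriors with an empty blacklist")
    }
    blacklist <- tibble(chrom = character(), start = double(), end = double())
  }
  structure(
    list(bins = bins, blacklist = blacklist, threshold = threshold),
    class = "bin_classification"
  )
}

#' @export
print.bin_classification <- function(x, ...) {
  cat(sprintf(
    "<bin classification>  %d bins, %d flagged (threshold %.2f), %d blacklist region(s)\n",
    nrow(x$bins), sum(x$bins$flagged), x$threshold, nrow(x$blacklist)
  ))
  invisible(x)
}

#' @export
tidy.bin_classification <- function(x, ...) x$bins
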