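#' Plot an NPMLE distribution recovery against the empirical pmf
#'
#' @param object A [cnm_fit()] result.
#' @param counts The counts the NPMLE was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cnm_fit <- function(object, counts, ...) {
  emp <- empirical_pmf(counts)
  rec <- recover_pmf(object, x_max = max(emp$x))
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(emp), which = "empirical"),
    dplyr::mutate(as_tibble(rec), which = "NPMLE recovery")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$prob, colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "count per bin", y = "probability (log scale)", colour = NULL,
      title = "Distribution recovery from the NPMLE mixing distribution"
    )
}

#' Plot a mixing-CDF bound check on the survival scale
#'
#' Draws `log(1 - CDF)` of the candidate mixing distribution at the
#' NPMLE support points together with the band implied by the bounds; a
#' consistent mixing distribution stays inside the band.
#'
#' @param object A `mixing_fit_check` from [check_mixing_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixing_fit_check <- function(object, ...) {
  df <- as_tibble(object)
  df$log_surv_lower <- log(pmax(1 - df$upper, .Machine$double.xmin))
  df$log_surv_upper <- log(pmax(1 - df$lower, .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(.data$theta)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$log_surv_lower, ymax = .data$log_surv_upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$log_surv)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$log_surv, shape = .data$pass)) +
    ggplot2::labs(
      x = expression(lambda ~ "(NPMLE support points)"),
      y = "log(1 - CDF)",
      title = "Candidate mixing distribution vs NPMLE-derived bounds"
    )
}

#' Plot a zero-inflation scan
#'
#' Model fit (`-log d_TV`, larger is better) against the fraction of
#' zero-valued bins removed (negative: added).  A peak at positive `rho`
#' suggests zero-inflation under that model.
#'
#' @param object A `zero_scan` table from [zero_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zero_scan <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$rho, -log(.data$d_tv), colour = .data$model)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "proportion of zeros removed", y = expression(-log(d[TV])),
      colour = NULL, title = "Zero-inflation scan"
    )
}
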