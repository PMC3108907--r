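#' Plot per-partition segregating-site densities
#'
#' @param density output of [partition_density()].
#' @return A ggplot.
#' @export
plot_partition_density <- function(density) {
  df <- dplyr::filter(density, .data$class != "genome")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$density),
    y = 1000 * .data$density)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "segregating sites per kb",
                  title = "Variant density by genome partition") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_lognormal Density curve with mode and 95% interval.
#' @param object a `lognormal_fit`.
#' @export
autoplot.lognormal_fit <- function(object, ...) {
  mc <- mode_and_ci(object)
  lo <- exp(object$meanlog - 3.5 * max(object$sdlog, 1e-6))
  hi <- exp(object$meanlog + 3.5 * max(object$sdlog, 1e-6))
  grid <- tibble::tibble(
    t = exp(seq(log(lo), log(hi), length.out = 400)),
    density = dlnorm(exp(seq(log(lo), log(hi), length.out = 400)),
                     object$meanlog, max(object$sdlog, 1e-12)))
  ggplot2::ggplot(grid, ggplot2::aes(.data$t, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = mc$mode, linetype = 1) +
    ggplot2::geom_vline(xintercept = c(mc$q025, mc$q975), linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "years until one expected substitution",
                  y = "density",
                  title = "Lognormal waiting-time fit (mode and 95% interval)") +
    ggplot2::theme_minimal()
}

#' @describeIn amova Variance apportionment bar chart.
#' @param object a `mito_amova`.
#' @export
autoplot.mito_amova <- function(object, ...) {
  df <- dplyr::filter(object$table, .data$source != "Total")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of molecular variance",
                  title = "AMOVA variance apportionment") +
    ggplot2::theme_minimal()
}
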