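#' Manhattan plot of association results
#'
#' @param results Association tibble with columns `pos` and `wald_p`.
#' @param threshold Optional significance threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = NULL) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$pos / 1e6,
                                    y = -log10(.data$wald_p))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8, colour = "steelblue4") +
    ggplot2::labs(x = "Position (Mb)",
                  y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Quantile-quantile plot of association p-values
#'
#' Observed against expected `-log10` p-values under the uniform null,
#' annotated with the genomic inflation factor from [genomic_lambda()].
#'
#' @param results Association tibble with a `wald_p` column.
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  p <- sort(results$wald_p)
  n <- length(p)
  df <- tibble::tibble(expected = -log10(stats::ppoints(n)),
                       observed = -log10(p))
  lam <- genomic_lambda(p = results$wald_p)
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8, colour = "steelblue4") +
    ggplot2::annotate("text", x = 0.5, y = max(df$observed),
                      hjust = 0, vjust = 1,
                      label = sprintf("lambda == %.3f", lam), parse = TRUE) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(P))),
                  y = expression(Observed ~ -log[10](italic(P)))) +
    ggplot2::theme_minimal()
}

#' Segment-length diagnostics
#'
#' Histogram of candidate segment lengths split by whether the
#' BH-adjusted lineage-sorting p-value falls below `alpha`.
#'
#' @param segments Scored segments from [score_segments()].
#' @param alpha Calling threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_segments <- function(segments, alpha = 0.05) {
  seg <- dplyr::mutate(segments,
                       call = ifelse(.data$p_adj < alpha,
                                     "introgressed", "consistent with ILS"))
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$length / 1e3,
                                    fill = .data$call)) +
    ggplot2::geom_histogram(bins = 50, position = "identity", alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Segment length (kb)", y = "Segments", fill = NULL) +
    ggplot2::theme_minimal()
}
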