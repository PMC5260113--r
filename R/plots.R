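# ggplot2 helpers for the standard figures of the analysis.

#' Plot a k-dist curve
#'
#' The sorted-descending k-dist values with the selected epsilon marked.
#'
#' @param profile A `kdist_profile`.
#' @param epsilon Optional epsilon (e.g. from [select_epsilon()]) drawn as a
#'   dashed line.
#' @return A ggplot.
#' @export
plot_kdist <- function(profile, epsilon = NULL) {
  d <- tibble(rank = seq_along(profile), kdist = as.numeric(profile))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$kdist)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reads (sorted by descending k-dist)",
                  y = sprintf("distance to %s-th nearest read (bp)",
                              attr(profile, "k") %||% "k")) +
    ggplot2::theme_minimal()
  if (!is.null(epsilon)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(epsilon),
                                 linetype = "dashed")
  }
  p
}

#' Plot per-length siRNA abundance
#'
#' RPM by read length, one panel per plant, one line per time point.
#'
#' @param histogram Output of [length_histogram()].
#' @return A ggplot.
#' @export
plot_length_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$length, y = .data$rpm,
                               colour = factor(.data$time_hat))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$plant)) +
    ggplot2::labs(x = "read length (nt)", y = "abundance (RPM)",
                  colour = "hours after\ntreatment") +
    ggplot2::theme_minimal()
}

#' @describeIn correlation_report Scatter of gene vs cluster log2 fold
#'   changes, faceted by plant and interval.
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$log2fc_gene, y = .data$log2fc_cluster)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_grid(ggplot2::vars(.data$interval), ggplot2::vars(.data$plant)) +
    ggplot2::labs(x = "gene log2 fold change",
                  y = "siRNA cluster log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot feature enrichment odds ratios
#'
#' @param enrichment Output of [feature_odds_ratio()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  d <- enrichment |>
    mutate(feature = factor(.data$feature, levels = FEATURE_LEVELS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$odds_ratio)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "length-normalised enrichment odds ratio") +
    ggplot2::theme_minimal()
}

#' @describeIn chrom_position_profile Histogram of relative arm positions
#'   (0 = centromere, 1 = telomere).
#' @param object A `chrom_position_profile`.
#' @param ... Unused.
#' @method autoplot chrom_position_profile
#' @export
autoplot.chrom_position_profile <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = 1 / nrow(object$density)) +
    ggplot2::labs(x = "relative arm position (0 = centromere, 1 = telomere)",
                  y = "fraction of clusters") +
    ggplot2::theme_minimal()
}

#' Plot cumulative conservation score distributions
#'
#' @param cumulative Output of [cumulative_score_distribution()].
#' @return A ggplot.
#' @export
plot_cumulative_conservation <- function(cumulative) {
  ggplot2::ggplot(cumulative,
                  ggplot2::aes(x = .data$threshold, y = .data$cumulative_fraction,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "conservation score threshold",
                  y = "cumulative fraction of bins", colour = "bins") +
    ggplot2::theme_minimal()
}
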