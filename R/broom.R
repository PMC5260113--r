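# broom-style accessors for fitted/result objects.

#' Tidy a conservation test
#' @param x A `conservation_test`.
#' @param ... Unused.
#' @return One row per feature: counts, median p, fraction of significant
#'   resamples, verdict.
#' @method tidy conservation_test
#' @export
tidy.conservation_test <- function(x, ...) {
  x$results |> select(-"p_values")
}

#' Glance at a conservation test
#' @param x A `conservation_test`.
#' @param ... Unused.
#' @return One-row tibble with the settings and the number of significant
#'   features.
#' @method glance conservation_test
#' @export
glance.conservation_test <- function(x, ...) {
  tibble(n_features = nrow(x$results),
         n_significant = sum(x$results$significant),
         n_resamples = x$n_resamples, alpha = x$alpha,
         significant_fraction = x$significant_fraction)
}

#' Tidy a correlation report
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return Per plant x interval Pearson estimates.
#' @method tidy correlation_report
#' @export
tidy.correlation_report <- function(x, ...) x$by_group

#' Glance at a correlation report
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return One-row tibble: pooled estimate, p-value, pair count, and the
#'   share of pairs in the two anti-correlation quadrants.
#' @method glance correlation_report
#' @export
glance.correlation_report <- function(x, ...) {
  anti <- x$quadrants |>
    filter(.data$quadrant %in% c("gene_down_cluster_up", "gene_up_cluster_down"))
  tibble(estimate = x$pooled$estimate, p_value = x$pooled$p_value,
         n_pairs = nrow(x$table),
         anticorrelated_fraction = if (nrow(x$table) == 0) NA_real_ else
           sum(anti$n) / nrow(x$table))
}
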