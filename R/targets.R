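# Cluster-gene association and expression correlation. Target genes are
# genes whose body embodies one or more merged siRNA clusters; clusters in
# intergenic space are set aside. Per target gene, constituent cluster RPM
# is summed into a unique gene-cluster pair, and log2 fold changes between
# consecutive time points are compared between gene and cluster expression.

#' Remove genes below the expression floor
#'
#' A gene is kept for a plant iff its FPKM strictly exceeds `floor` at some
#' time point of that plant ("not exceeding 1 FPKM at any time point" reads
#' as strict).
#'
#' @param expression Long tibble `gene_id`, `plant`, `time_hat`, `fpkm`.
#' @param floor Expression floor (FPKM). Default 1.
#' @return The retained rows.
#' @export
filter_expressed_genes <- function(expression, floor = 1.0) {
  as_tibble(expression) |>
    group_by(.data$gene_id, .data$plant) |>
    filter(max(.data$fpkm) > floor) |>
    ungroup()
}

#' Assign merged clusters to target genes
#'
#' A cluster targets a gene when its interval is contained in the gene body,
#' or — since merging across samples can push hulls past gene edges — when at
#' least `min_fraction` of the cluster's length lies inside the body
#' (default 0.5; set `strict_containment = TRUE` to require full
#' containment). Clusters assigned to no gene are reported as intergenic.
#'
#' @param merged A `merged_clusters` from [merge_clusters()], or its
#'   `clusters` tibble.
#' @param annotation A `gene_annotation`.
#' @param min_fraction Minimum fraction of cluster length inside the gene
#'   body.
#' @param strict_containment Require the whole cluster inside the body.
#' @return A list of class `cluster_assignment`: `pairs` (tibble
#'   `cluster_id`, `gene_id`) and `intergenic` (tibble of unassigned
#'   clusters).
#' @export
assign_targets <- function(merged, annotation, min_fraction = 0.5,
                           strict_containment = FALSE) {
  clusters <- if (inherits(merged, "merged_clusters")) merged$clusters else as_tibble(merged)
  genes <- annotation$genes
  if (nrow(clusters) == 0) {
    return(structure(list(pairs = tibble(cluster_id = character(),
                                         gene_id = character()),
                          intergenic = clusters), class = "cluster_assignment"))
  }
  hits <- overlap_hits(clusters, genes)
  if (nrow(hits) > 0) {
    cs <- clusters$start[hits$x]; ce <- clusters$end[hits$x]
    gs <- genes$start[hits$y]; ge <- genes$end[hits$y]
    frac <- bp_overlap(cs, ce, gs, ge) / (ce - cs)
    keep <- if (strict_containment) frac >= 1 else frac >= min_fraction
    hits <- hits[keep, ]
  }
  # a cluster straddling two gene bodies is assigned to the gene holding the
  # larger share (ties: smaller gene_id) so each cluster has one host
  pairs <- tibble(cluster_id = clusters$cluster_id[hits$x],
                  gene_id = genes$gene_id[hits$y],
                  frac = bp_overlap(clusters$start[hits$x], clusters$end[hits$x],
                                    genes$start[hits$y], genes$end[hits$y]) /
                    (clusters$end[hits$x] - clusters$start[hits$x])) |>
    group_by(.data$cluster_id) |>
    arrange(dplyr::desc(.data$frac), .data$gene_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("cluster_id", "gene_id")
  intergenic <- clusters |> filter(!(.data$cluster_id %in% pairs$cluster_id))
  structure(list(pairs = pairs, intergenic = intergenic),
            class = "cluster_assignment")
}

#' Log2 fold change with a pseudocount
#'
#' `log2((b + pseudocount) / (a + pseudocount))`; the shared pseudocount
#' guards zero expression and makes the function antisymmetric in its
#' arguments.
#'
#' @param a,b Non-negative expression values (earlier, later).
#' @param pseudocount Added to both values. Default 1.
#' @return The log2 fold change.
#' @export
log2_fold_change <- function(a, b, pseudocount = 1.0) {
  if (any(a < 0 | b < 0)) abort("expression values must be >= 0")
  log2((b + pseudocount) / (a + pseudocount))
}

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return One-row tibble `estimate`, `p_value`, `n`. Zero variance yields
#'   `NA` estimates with a warning.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors with at least 3 observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble(estimate = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Build unique gene-siRNA cluster expression pairs
#'
#' Sums the RPM of all clusters targeting a common gene into one pair per
#' gene, joins the host gene's FPKM, and computes log2 fold changes between
#' consecutive time points for both series.
#'
#' @param assignment A `cluster_assignment` from [assign_targets()].
#' @param cluster_expression Per-sample cluster expression (the `expression`
#'   element of [merge_clusters()]).
#' @param expression Gene FPKM long tibble (after
#'   [filter_expressed_genes()]).
#' @param pseudocount Pseudocount for fold changes.
#' @return Tibble with one row per gene x plant x interval: `gene_id`,
#'   `cluster_ids`, `plant`, `interval`, `log2fc_gene`, `log2fc_cluster`.
#' @export
gene_cluster_pairs <- function(assignment, cluster_expression, expression,
                               pseudocount = 1.0) {
  pairs <- assignment$pairs
  empty <- tibble(gene_id = character(), cluster_ids = character(),
                  plant = character(), interval = character(),
                  log2fc_gene = numeric(), log2fc_cluster = numeric())
  if (nrow(pairs) == 0) return(empty)
  cl_expr <- cluster_expression |>
    inner_join(pairs, by = "cluster_id") |>
    group_by(.data$gene_id, .data$plant, .data$time_hat) |>
    summarise(rpm = sum(.data$rpm), .groups = "drop")
  # a cluster undetected in some sample has zero RPM there; complete the
  # sample grid so fold-change intervals line up with the gene series
  grid <- expression |> distinct(.data$plant, .data$time_hat)
  cl_expr <- tidyr::expand_grid(gene_id = unique(cl_expr$gene_id), grid) |>
    left_join(cl_expr, by = c("gene_id", "plant", "time_hat")) |>
    mutate(rpm = tidyr::replace_na(.data$rpm, 0))
  ids <- pairs |>
    group_by(.data$gene_id) |>
    summarise(cluster_ids = paste(sort(.data$cluster_id), collapse = ","),
              .groups = "drop")
  # consecutive-time-point fold changes; assumes v ordered by time
  fc <- function(v) log2_fold_change(head(v, -1), tail(v, -1), pseudocount)
  gene_fc <- expression |>
    semi_join(pairs, by = "gene_id") |>
    arrange(.data$gene_id, .data$plant, .data$time_hat) |>
    group_by(.data$gene_id, .data$plant) |>
    dplyr::reframe(interval = paste0(head(.data$time_hat, -1), "to",
                                     tail(.data$time_hat, -1)),
                   log2fc_gene = fc(.data$fpkm))
  cl_fc <- cl_expr |>
    arrange(.data$gene_id, .data$plant, .data$time_hat) |>
    group_by(.data$gene_id, .data$plant) |>
    dplyr::reframe(interval = paste0(head(.data$time_hat, -1), "to",
                                     tail(.data$time_hat, -1)),
                   log2fc_cluster = fc(.data$rpm))
  out <- inner_join(gene_fc, cl_fc, by = c("gene_id", "plant", "interval")) |>
    left_join(ids, by = "gene_id") |>
    select("gene_id", "cluster_ids", "plant", "interval",
           "log2fc_gene", "log2fc_cluster")
  if (nrow(out) == 0) empty else out
}

#' Correlate gene and cluster expression changes
#'
#' The scatter of (gene log2 FC, cluster log2 FC) over all pairs, the Pearson
#' correlation per plant x interval and pooled, and counts of pairs per sign
#' quadrant (`gene_down_cluster_up` etc. — the anti-correlation quadrants are
#' `gene_down_cluster_up` and `gene_up_cluster_down`).
#'
#' @param pairs Output of [gene_cluster_pairs()].
#' @return A list of class `correlation_report`: `table` (the input scatter),
#'   `by_group` (per plant x interval correlation), `pooled` (one-row
#'   correlation over all pairs), `quadrants` (sign-quadrant counts).
#' @export
correlation_report <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(structure(list(table = pairs,
                          by_group = tibble(plant = character(), interval = character(),
                                            estimate = numeric(), p_value = numeric(),
                                            n = integer()),
                          pooled = tibble(estimate = NA_real_, p_value = NA_real_, n = 0L),
                          quadrants = tibble(quadrant = character(), n = integer())),
                     class = "correlation_report"))
  }
  by_group <- pairs |>
    group_by(.data$plant, .data$interval) |>
    summarise(pearson_correlation(.data$log2fc_gene, .data$log2fc_cluster),
              .groups = "drop")
  pooled <- pearson_correlation(pairs$log2fc_gene, pairs$log2fc_cluster)
  quadrants <- pairs |>
    mutate(quadrant = dplyr::case_when(
      .data$log2fc_gene < 0 & .data$log2fc_cluster > 0 ~ "gene_down_cluster_up",
      .data$log2fc_gene > 0 & .data$log2fc_cluster < 0 ~ "gene_up_cluster_down",
      .data$log2fc_gene > 0 & .data$log2fc_cluster > 0 ~ "gene_up_cluster_up",
      .data$log2fc_gene < 0 & .data$log2fc_cluster < 0 ~ "gene_down_cluster_down",
      .default = "zero_change")) |>
    count(.data$quadrant, name = "n")
  structure(list(table = pairs, by_group = by_group, pooled = pooled,
                 quadrants = quadrants), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d pairs; pooled r = %.3f (p = %.3g)\n",
              nrow(x$table), x$pooled$estimate, x$pooled$p_value))
  print(x$quadrants)
  invisible(x)
}
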