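# Feature-wise enrichment of clusters within gene bodies, normalised for
# feature length, and chromosomal positioning relative to centromeres and
# telomeres.

#' Classify clusters by host-gene feature
#'
#' Each genic cluster is labelled with the feature class (intron, CDS, 5'UTR,
#' 3'UTR) holding the largest bp overlap with its interval; ties are broken
#' by the fixed priority intron > cds > five_prime_utr > three_prime_utr, and
#' clusters overlapping none of the host's annotated features are labelled
#' `other_genic`.
#'
#' @param merged A `merged_clusters` or its `clusters` tibble.
#' @param assignment A `cluster_assignment` from [assign_targets()].
#' @param annotation A `gene_annotation`.
#' @return Tibble `cluster_id`, `gene_id`, `feature`.
#' @export
classify_cluster_feature <- function(merged, assignment, annotation) {
  clusters <- if (inherits(merged, "merged_clusters")) merged$clusters else as_tibble(merged)
  pairs <- assignment$pairs
  if (nrow(pairs) == 0) {
    return(tibble(cluster_id = character(), gene_id = character(),
                  feature = character()))
  }
  cl <- clusters |> inner_join(pairs, by = "cluster_id")
  feats <- annotation$features |> filter(.data$feature %in% FEATURE_LEVELS)
  joined <- cl |>
    inner_join(feats, by = "gene_id", suffix = c("", ".f"),
               relationship = "many-to-many") |>
    mutate(ov = bp_overlap(.data$start, .data$end, .data$start.f, .data$end.f)) |>
    filter(.data$ov > 0) |>
    mutate(priority = match(.data$feature, FEATURE_LEVELS[c(3, 2, 1, 4)])) |>
    group_by(.data$cluster_id) |>
    arrange(dplyr::desc(.data$ov), .data$priority, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("cluster_id", "gene_id", "feature")
  cl |>
    select("cluster_id", "gene_id") |>
    left_join(joined |> select("cluster_id", "feature"), by = "cluster_id") |>
    mutate(feature = tidyr::replace_na(.data$feature, "other_genic"))
}

#' Total annotated length per feature class
#'
#' Summed over the representative transcripts of all genes.
#'
#' @param annotation A `gene_annotation`.
#' @return Tibble `feature`, `total_length`.
#' @export
feature_lengths <- function(annotation) {
  annotation$features |>
    filter(.data$feature %in% FEATURE_LEVELS) |>
    group_by(.data$feature) |>
    summarise(total_length = sum(.data$end - .data$start), .groups = "drop")
}

#' Length-normalised feature enrichment odds ratios
#'
#' For feature f with n_f clusters over L_f total bp,
#' `OR_f = (n_f / L_f) / ((N - n_f) / (L - L_f))`: the cluster density in f
#' relative to the density in all other features. `or_mode = "counts"`
#' instead computes the 2x2 odds ratio on (clusters, bp):
#' `(n_f / (L_f - n_f)) / ((N - n_f) / ((L - L_f) - (N - n_f)))`.
#'
#' @param classified Output of [classify_cluster_feature()] (rows labelled
#'   `other_genic` are ignored).
#' @param annotation A `gene_annotation`.
#' @param or_mode `"density"` (default) or `"counts"`.
#' @return Tibble `feature`, `n_clusters`, `total_length`, `odds_ratio`; an
#'   infinite ratio (all clusters in one feature) is reported as `Inf`.
#' @export
feature_odds_ratio <- function(classified, annotation,
                               or_mode = c("density", "counts")) {
  or_mode <- match.arg(or_mode)
  lens <- feature_lengths(annotation)
  counts <- classified |>
    filter(.data$feature %in% FEATURE_LEVELS) |>
    count(.data$feature, name = "n_clusters")
  tab <- lens |>
    left_join(counts, by = "feature") |>
    mutate(n_clusters = as.integer(tidyr::replace_na(.data$n_clusters, 0L)))
  if (any(tab$total_length <= 0)) abort("every reported feature needs total length > 0")
  N <- sum(tab$n_clusters); L <- sum(tab$total_length)
  tab |>
    mutate(odds_ratio = if (or_mode == "density") {
      (.data$n_clusters / .data$total_length) /
        ((N - .data$n_clusters) / (L - .data$total_length))
    } else {
      (.data$n_clusters / (.data$total_length - .data$n_clusters)) /
        ((N - .data$n_clusters) / ((L - .data$total_length) - (N - .data$n_clusters)))
    }) |>
    mutate(feature = factor(.data$feature, levels = FEATURE_LEVELS)) |>
    arrange(.data$feature) |>
    mutate(feature = as.character(.data$feature))
}

#' Chromosomal positioning of clusters relative to centromeres
#'
#' Each cluster midpoint is mapped to a relative arm position in [0, 1]
#' (0 = centromere edge, 1 = chromosome end, arm chosen by which side of the
#' centromere the midpoint lies; midpoints inside the centromere get 0 and a
#' flag), then binned into a density over [0, 1].
#'
#' @param merged A `merged_clusters` or its `clusters` tibble.
#' @param layout Genome layout with `chrom_sizes` and `centromeres`.
#' @param n_bins Number of histogram bins. Default 20.
#' @return A list of class `chrom_position_profile`: `positions` (per
#'   cluster: `cluster_id`, `chrom`, `arm`, `position`, `in_centromere`) and
#'   `density` (`bin_mid`, `density`; densities sum to 1).
#' @export
chrom_position_profile <- function(merged, layout, n_bins = 20L) {
  clusters <- if (inherits(merged, "merged_clusters")) merged$clusters else as_tibble(merged)
  cents <- layout$centromeres
  sizes <- layout$chrom_sizes
  missing_chrom <- setdiff(unique(clusters$chrom),
                           intersect(cents$chrom, sizes$chrom))
  if (length(missing_chrom) > 0) {
    abort(sprintf("no centromere/size entry for chromosome %s", missing_chrom[1]))
  }
  pos <- clusters |>
    mutate(mid = (.data$start + .data$end) / 2) |>
    left_join(cents |> rename(cen_start = "start", cen_end = "end"), by = "chrom") |>
    left_join(sizes, by = "chrom") |>
    mutate(in_centromere = .data$mid >= .data$cen_start & .data$mid < .data$cen_end,
           arm = if_else(.data$mid < .data$cen_start, "left", "right"),
           position = dplyr::case_when(
             .data$in_centromere ~ 0,
             .data$mid < .data$cen_start ~ (.data$cen_start - .data$mid) / .data$cen_start,
             .default = (.data$mid - .data$cen_end) / (.data$length - .data$cen_end))) |>
    select("cluster_id", "chrom", "arm", "position", "in_centromere")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(pos$position, breaks, rightmost.closed = TRUE), n_bins)
  dens <- tibble(bin = factor(bin, levels = seq_len(n_bins))) |>
    count(.data$bin, .drop = FALSE) |>
    mutate(bin_mid = (as.integer(.data$bin) - 0.5) / n_bins,
           density = .data$n / sum(.data$n)) |>
    select("bin_mid", "density")
  structure(list(positions = pos, density = dens),
            class = "chrom_position_profile")
}
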