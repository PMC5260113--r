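# Evolutionary conservation of cluster regions. UTR and intron features are
# tiled with 25-nt bins, each bin carries the average per-base conservation
# score, bins are labelled by siRNA-cluster overlap, and cluster vs
# non-cluster bins are compared per feature with a t-test repeated over 1000
# size-matched random selections of non-cluster bins. CDS regions are never
# binned: their uniformly high coding conservation would dominate the
# comparison.

CONSERVATION_FEATURES <- c("five_prime_utr", "three_prime_utr", "intron")

#' Tile feature regions with fixed-width bins
#'
#' Each feature interval is tiled left to right with consecutive `bin`-bp
#' bins anchored at its left edge; a remainder shorter than `bin` is
#' dropped. Only 5'UTR, 3'UTR and intron features are accepted.
#'
#' @param annotation A `gene_annotation` (or a feature tibble with
#'   `gene_id`, `feature`, `chrom`, `start`, `end`).
#' @param bin Bin width (bp). Default 25.
#' @param features Feature classes to tile.
#' @return Tibble of bin skeletons: `gene_id`, `feature`, `chrom`, `start`,
#'   `end`.
#' @export
bin_feature_regions <- function(annotation, bin = 25L,
                                features = CONSERVATION_FEATURES) {
  feats <- if (is.data.frame(annotation)) as_tibble(annotation) else annotation$features
  bad <- setdiff(features, CONSERVATION_FEATURES)
  if (length(bad) > 0) {
    abort(sprintf("feature class '%s' cannot be binned (CDS is excluded from conservation testing)",
                  bad[1]))
  }
  feats <- feats |> filter(.data$feature %in% features)
  if (nrow(feats) == 0) {
    return(tibble(gene_id = character(), feature = character(),
                  chrom = character(), start = integer(), end = integer()))
  }
  n_bins <- (feats$end - feats$start) %/% bin
  idx <- rep.int(seq_len(nrow(feats)), n_bins)
  offset <- unlist(lapply(n_bins, seq_len), use.names = FALSE) - 1L
  tibble(gene_id = feats$gene_id[idx], feature = feats$feature[idx],
         chrom = feats$chrom[idx],
         start = feats$start[idx] + offset * as.integer(bin)) |>
    mutate(end = .data$start + as.integer(bin))
}

#' Average a conservation track over bins
#'
#' Each bin's `mean_score` is the average score over track-covered bases;
#' bins with fewer than `min_coverage` of their bases covered are flagged
#' (`low_coverage`) and excluded from testing downstream.
#'
#' @param bins Bin skeletons from [bin_feature_regions()].
#' @param track Conservation track tibble `chrom`, `start`, `end`, `score`
#'   (e.g. from [read_bedgraph()]); scores in [0, 1].
#' @param min_coverage Minimum covered fraction. Default 0.5.
#' @return `bins` with `mean_score`, `coverage`, `low_coverage`.
#' @export
score_bins <- function(bins, track, min_coverage = 0.5) {
  bins <- as_tibble(bins)
  missing_chrom <- setdiff(unique(bins$chrom), unique(track$chrom))
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome %s absent from conservation track", missing_chrom[1]))
  }
  if (nrow(bins) == 0) {
    return(bins |> mutate(mean_score = numeric(0), coverage = numeric(0),
                          low_coverage = logical(0)))
  }
  hits <- overlap_hits(bins, track)
  ov <- bp_overlap(bins$start[hits$x], bins$end[hits$x],
                   track$start[hits$y], track$end[hits$y])
  agg <- tibble(bin = hits$x, bases = ov,
                weighted = ov * track$score[hits$y]) |>
    group_by(.data$bin) |>
    summarise(bases = sum(.data$bases), weighted = sum(.data$weighted),
              .groups = "drop")
  bins |>
    mutate(.row = row_number()) |>
    left_join(agg, by = c(".row" = "bin")) |>
    mutate(bases = tidyr::replace_na(.data$bases, 0),
           mean_score = if_else(.data$bases > 0, .data$weighted / .data$bases, NA_real_),
           coverage = .data$bases / (.data$end - .data$start),
           low_coverage = .data$coverage < min_coverage) |>
    select(-".row", -"bases", -"weighted")
}

#' Label bins by siRNA-cluster overlap
#'
#' `is_cluster_bin` is `TRUE` iff a bin overlaps any cluster interval by at
#' least one base pair (half-open: touching does not overlap).
#'
#' @param bins Scored bins.
#' @param merged A `merged_clusters` or a cluster interval tibble.
#' @return `bins` with `is_cluster_bin`.
#' @export
label_cluster_bins <- function(bins, merged) {
  clusters <- if (inherits(merged, "merged_clusters")) merged$clusters else as_tibble(merged)
  bins <- as_tibble(bins)
  flag <- logical(nrow(bins))
  if (nrow(bins) > 0 && nrow(clusters) > 0) {
    hits <- overlap_hits(bins, clusters)
    flag[unique(hits$x)] <- TRUE
  }
  bins |> mutate(is_cluster_bin = flag)
}

#' Size-matched resampled t-test of cluster vs non-cluster bin scores
#'
#' Because cluster bins are far fewer than non-cluster bins, the two-sided
#' Welch t-test is repeated over `n_resamples` random selections (without
#' replacement) of as many non-cluster bins as there are cluster bins. All
#' resample p-values are returned with their median and the fraction at or
#' below `alpha`. Degenerate resamples (zero variance in both groups) are
#' counted as non-significant and flagged.
#'
#' @param cluster_scores Scores of cluster bins (length >= 3).
#' @param noncluster_scores Scores of non-cluster bins (length >=
#'   `length(cluster_scores)`).
#' @param n_resamples Number of random selections. Default 1000.
#' @param alpha Significance level. Default 0.05.
#' @param seed Integer seed making the resampling deterministic.
#' @param equal_var Use the pooled-variance (Student) t-test instead of
#'   Welch's.
#' @param feature Optional label carried into the result.
#' @return A one-row tibble: `feature`, `n_cluster_bins`,
#'   `n_noncluster_bins`, `median_p`, `fraction_significant`,
#'   `n_degenerate`, plus the full `p_values` as a list column.
#' @export
resampled_ttest <- function(cluster_scores, noncluster_scores,
                            n_resamples = 1000L, alpha = 0.05, seed = 1L,
                            equal_var = FALSE, feature = NA_character_) {
  m <- length(cluster_scores)
  if (m < 3) abort(sprintf("feature %s: need at least 3 cluster bins (got %d)", feature, m))
  if (length(noncluster_scores) < m) {
    abort(sprintf("feature %s: need at least as many non-cluster bins (%d) as cluster bins (%d)",
                  feature, length(noncluster_scores), m))
  }
  set.seed(seed)
  p <- vapply(seq_len(n_resamples), function(i) {
    sel <- sample(noncluster_scores, m)
    if (stats::sd(cluster_scores) == 0 && stats::sd(sel) == 0) return(NA_real_)
    stats::t.test(cluster_scores, sel, var.equal = equal_var)$p.value
  }, numeric(1))
  degenerate <- is.na(p)
  tibble(feature = feature, n_cluster_bins = m,
         n_noncluster_bins = length(noncluster_scores),
         median_p = median(p, na.rm = TRUE),
         fraction_significant = mean(!degenerate & p <= alpha),
         n_degenerate = sum(degenerate),
         p_values = list(p))
}

#' Per-feature conservation test of cluster regions
#'
#' Runs [resampled_ttest()] for each feature class present in the labelled
#' bins (low-coverage and unscored bins excluded). A feature is called
#' significant when at least `significant_fraction` of its resamples reach
#' `alpha`.
#'
#' @param bins Scored, labelled bins (from [label_cluster_bins()]).
#' @param n_resamples,alpha,seed,equal_var Passed to [resampled_ttest()].
#' @param significant_fraction Verdict threshold on the fraction of
#'   significant resamples. Default 0.95.
#' @return A list of class `conservation_test` with `results` (one row per
#'   feature, plus `significant`) and the test settings.
#' @export
conservation_test <- function(bins, n_resamples = 1000L, alpha = 0.05,
                              seed = 1L, equal_var = FALSE,
                              significant_fraction = 0.95) {
  usable <- bins |> filter(!.data$low_coverage, !is.na(.data$mean_score))
  feats <- intersect(CONSERVATION_FEATURES, unique(usable$feature))
  results <- purrr::imap(setNames(feats, feats), function(f, i) {
    d <- usable |> filter(.data$feature == f)
    resampled_ttest(d$mean_score[d$is_cluster_bin],
                    d$mean_score[!d$is_cluster_bin],
                    n_resamples = n_resamples, alpha = alpha,
                    seed = seed + match(f, CONSERVATION_FEATURES),
                    equal_var = equal_var, feature = f)
  }) |> bind_rows()
  results <- results |>
    mutate(significant = .data$fraction_significant >= significant_fraction)
  structure(list(results = results, n_resamples = n_resamples, alpha = alpha,
                 significant_fraction = significant_fraction, seed = seed),
            class = "conservation_test")
}

#' @export
print.conservation_test <- function(x, ...) {
  cat(sprintf("<conservation_test> %d resamples, alpha = %g\n",
              x$n_resamples, x$alpha))
  print(x$results |> select(-"p_values"))
  invisible(x)
}

#' Cumulative score distribution of bins
#'
#' For thresholds 0, 0.1, ..., 1 the fraction of bins with mean score at or
#' below the threshold, separately for cluster and non-cluster bins; an empty
#' group yields `NA` fractions.
#'
#' @param bins Scored, labelled bins.
#' @param step Threshold step. Default 0.1.
#' @return Tibble `group`, `threshold`, `cumulative_fraction`.
#' @export
cumulative_score_distribution <- function(bins, step = 0.1) {
  thresholds <- seq(0, 1, by = step)
  usable <- bins |> filter(!is.na(.data$mean_score))
  purrr::map(c(cluster = TRUE, noncluster = FALSE), function(flag) {
    s <- usable$mean_score[usable$is_cluster_bin == flag]
    tibble(threshold = thresholds,
           cumulative_fraction = if (length(s) == 0) NA_real_ else
             vapply(thresholds, function(t) mean(s <= t), numeric(1)))
  }) |>
    bind_rows(.id = "group")
}

#' Select conserved-candidate gene-cluster pairs
#'
#' Keeps pairs whose gene and cluster log2 fold changes have opposite signs
#' in at least one time interval and whose gene has orthologs in at least
#' `min_plants` plant species including the reference.
#'
#' @param pairs Output of [gene_cluster_pairs()].
#' @param orthologs Tibble `gene_id`, `plant` (one row per gene x species
#'   with an ortholog; additional columns ignored), e.g. read from a TSV.
#' @param min_plants Minimum number of species. Default 4.
#' @param reference Reference species name that must be among them.
#' @return The retained `gene_id`s with their cluster ids, as a tibble.
#' @export
select_conserved_candidates <- function(pairs, orthologs, min_plants = 4L,
                                        reference = "Oryza sativa") {
  anti <- pairs |>
    filter(.data$log2fc_gene * .data$log2fc_cluster < 0) |>
    distinct(.data$gene_id, .data$cluster_ids)
  orth_ok <- as_tibble(orthologs) |>
    distinct(.data$gene_id, .data$plant) |>
    group_by(.data$gene_id) |>
    summarise(n_plants = n(), has_ref = any(.data$plant == reference),
              .groups = "drop") |>
    filter(.data$n_plants >= min_plants, .data$has_ref)
  anti |> semi_join(orth_ok, by = "gene_id")
}

#' Export cluster sequences as FASTA
#'
#' One record per cluster (id = cluster id), the plus-strand genomic
#' subsequence of the cluster interval.
#'
#' @param merged A `merged_clusters` or a cluster tibble.
#' @param genome Named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param path Optional output FASTA path; omit to just return sequences.
#' @return Named character vector of cluster sequences, invisibly when
#'   writing.
#' @export
export_cluster_fasta <- function(merged, genome, path = NULL) {
  clusters <- if (inherits(merged, "merged_clusters")) merged$clusters else as_tibble(merged)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- read_fasta(genome)
  } else if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (nrow(clusters) > 0) {
    missing_chrom <- setdiff(unique(clusters$chrom), names(genome))
    if (length(missing_chrom) > 0) {
      abort(sprintf("chromosome %s absent from genome", missing_chrom[1]))
    }
    if (any(clusters$end > nchar(genome[clusters$chrom]))) {
      abort("cluster interval exceeds chromosome length")
    }
  }
  seqs <- substr(genome[clusters$chrom], clusters$start + 1L, clusters$end)
  seqs <- setNames(as.character(seqs), clusters$cluster_id)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    return(invisible(seqs))
  }
  seqs
}
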