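# One-dimensional DBSCAN over read start coordinates. A point is core iff at
# least minpts points (itself included) lie within epsilon of it; clusters
# are the connected components of core points under epsilon-reachability,
# with border points (non-core points within epsilon of a core point)
# attached to the cluster of the first core point that reaches them in
# left-to-right genomic scan order. Remaining points are noise.

#' 1-D DBSCAN cluster assignment
#'
#' @param positions Numeric vector of 1-D coordinates (read starts, bp).
#' @param epsilon Neighbourhood radius (bp, > 0).
#' @param minpts Minimum neighbourhood size for a core point (>= 2),
#'   including the point itself.
#' @return Integer vector, same length/order as `positions`: cluster id
#'   (1, 2, ... numbered left to right) or 0 for noise.
#' @export
dbscan_1d <- function(positions, epsilon = 100, minpts = 10L) {
  if (epsilon <= 0) abort("epsilon must be > 0")
  if (minpts < 2) abort("minpts must be >= 2")
  n <- length(positions)
  if (n == 0) return(integer(0))
  ord <- order(positions)
  p <- as.numeric(positions)[ord]
  # neighbourhood size by two-sided binary search on the sorted vector
  left <- findInterval(p - epsilon, p, left.open = TRUE) + 1L
  right <- findInterval(p + epsilon, p)
  core <- (right - left + 1L) >= minpts
  cl <- integer(n)
  cid <- 0L
  last_core_pos <- -Inf
  for (i in seq_len(n)) {
    if (!core[i]) next
    if (p[i] - last_core_pos > epsilon) cid <- cid + 1L
    cl[i] <- cid
    last_core_pos <- p[i]
  }
  # border points: nearest reaching core in left-to-right scan order = the
  # leftmost core point within epsilon
  if (cid > 0L) {
    core_idx <- which(core)
    border <- which(!core)
    if (length(border) > 0) {
      # leftmost core j with p[j] >= p[i] - epsilon; reaches iff also <= p[i] + epsilon
      j <- findInterval(p[border] - epsilon, p[core_idx], left.open = TRUE) + 1L
      ok <- j <= length(core_idx)
      ok[ok] <- p[core_idx[j[ok]]] <= p[border[ok]] + epsilon
      cl[border[ok]] <- cl[core_idx[j[ok]]]
    }
  }
  out <- integer(n)
  out[ord] <- cl
  out
}

#' Detect siRNA clusters in one library
#'
#' Runs [dbscan_1d()] per chromosome on read start coordinates (strand-
#' agnostic by default) and reports one interval per cluster spanning the
#' leftmost member start to the rightmost member end, with weighted read
#' counts and RPM for the library.
#'
#' @param libraries An `srna_libraries` from [preprocess_reads()], or a read
#'   tibble plus `totals`.
#' @param epsilon Neighbourhood radius (bp). Default 100.
#' @param minpts Core threshold. Default 10.
#' @param stranded If `TRUE`, cluster each strand separately.
#' @param min_span Optional minimum cluster span filter (bp); `NULL` (default)
#'   imposes none.
#' @param weight_mode `"fractional"` (each alignment of an n-site read counts
#'   1/n) or `"full"`.
#' @return Tibble of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `strand`, `plant`, `time_hat`, `n_reads` (weighted), `rpm`.
#' @export
detect_clusters <- function(libraries, epsilon = 100, minpts = 10L,
                            stranded = FALSE, min_span = NULL,
                            weight_mode = c("fractional", "full")) {
  weight_mode <- match.arg(weight_mode)
  reads <- libraries$reads
  totals <- libraries$totals
  if (nrow(reads) == 0) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  plant = character(), time_hat = integer(),
                  n_reads = numeric(), rpm = numeric()))
  }
  reads <- reads |> mutate(.w = alignment_weights(reads, weight_mode))
  groups <- if (stranded) {
    reads |> split(~plant + time_hat + chrom + strand, drop = TRUE)
  } else {
    reads |> split(~plant + time_hat + chrom, drop = TRUE)
  }
  out <- purrr::map(groups, function(d) {
    cl <- dbscan_1d(d$start, epsilon, minpts)
    if (all(cl == 0L)) return(NULL)
    d |>
      mutate(.cl = cl) |>
      filter(.data$.cl > 0L) |>
      group_by(.data$plant, .data$time_hat, .data$chrom, .data$.cl) |>
      summarise(start = min(.data$start), end = max(.data$end),
                strand = if (stranded) first(.data$strand) else ".",
                n_reads = sum(.data$.w), .groups = "drop")
  }) |> bind_rows()
  if (nrow(out) == 0) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  plant = character(), time_hat = integer(),
                  n_reads = numeric(), rpm = numeric()))
  }
  if (!is.null(min_span)) out <- out |> filter(.data$end - .data$start >= min_span)
  out |>
    left_join(totals, by = c("plant", "time_hat")) |>
    arrange(.data$plant, .data$time_hat, .data$chrom, .data$start) |>
    group_by(.data$plant, .data$time_hat) |>
    mutate(cluster_id = sprintf("%s_%s_c%04d", .data$plant, .data$time_hat,
                                row_number())) |>
    ungroup() |>
    mutate(rpm = normalize_rpm(.data$n_reads, .data$total_processed)) |>
    select("cluster_id", "chrom", "start", "end", "strand", "plant",
           "time_hat", "n_reads", "rpm")
}

#' Merge overlapping clusters across samples
#'
#' Transitive union: clusters overlapping by at least one base pair are
#' merged, the merged interval is the hull, and per-sample weighted counts
#' and RPM are carried over from the constituents. Resulting intervals are
#' pairwise disjoint.
#'
#' @param clusters Per-sample cluster tibble from [detect_clusters()]
#'   (typically all samples of one plant, or all samples).
#' @return A list of class `merged_clusters`: `clusters` (tibble
#'   `cluster_id`, `chrom`, `start`, `end`, `n_samples`, `n_reads` — total
#'   weighted reads) and `expression` (tibble `cluster_id`, `plant`,
#'   `time_hat`, `n_reads`, `rpm`).
#' @export
merge_clusters <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(structure(list(
      clusters = tibble(cluster_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        n_samples = integer(), n_reads = numeric()),
      expression = tibble(cluster_id = character(), plant = character(),
                          time_hat = integer(), n_reads = numeric(),
                          rpm = numeric())), class = "merged_clusters"))
  }
  red <- reduce_intervals(clusters)
  merged <- red$merged |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("cluster%05d", row_number()))
  # map original order of reduced intervals to the sorted/renamed ones
  key <- paste(red$merged$chrom, red$merged$start, red$merged$end)
  id_of <- merged$cluster_id[match(key, paste(merged$chrom, merged$start, merged$end))]
  members <- clusters |> mutate(cluster_id = id_of[red$member_of])
  expression <- members |>
    group_by(.data$cluster_id, .data$plant, .data$time_hat) |>
    summarise(n_reads = sum(.data$n_reads), rpm = sum(.data$rpm), .groups = "drop")
  summary <- members |>
    group_by(.data$cluster_id) |>
    summarise(n_samples = n_distinct(paste(.data$plant, .data$time_hat)),
              n_reads = sum(.data$n_reads), .groups = "drop")
  merged <- merged |>
    left_join(summary, by = "cluster_id") |>
    select("cluster_id", "chrom", "start", "end", "n_samples", "n_reads")
  structure(list(clusters = merged, expression = expression),
            class = "merged_clusters")
}

#' Re-quantify merged clusters from read alignments
#'
#' Replaces the member-derived per-sample expression of merged clusters with
#' region-based counts: for every library, the weighted number of reads whose
#' start coordinate falls inside each merged interval, and its RPM. Unlike
#' summing detection members, this assigns a cluster its true (possibly
#' sub-threshold) expression in samples where it was not independently
#' detected, so fold changes between samples are not distorted by detection
#' dropouts.
#'
#' @param merged A `merged_clusters`.
#' @param libraries An `srna_libraries` from [preprocess_reads()].
#' @param weight_mode Multi-mapping weight rule.
#' @return `merged` with its `expression` tibble replaced (complete over the
#'   library grid; zero where no reads fall in the interval).
#' @export
quantify_clusters <- function(merged, libraries,
                              weight_mode = c("fractional", "full")) {
  weight_mode <- match.arg(weight_mode)
  clusters <- merged$clusters
  reads <- libraries$reads
  grid <- tidyr::expand_grid(cluster_id = clusters$cluster_id,
                             libraries$totals[c("plant", "time_hat")])
  if (nrow(clusters) == 0 || nrow(reads) == 0) {
    merged$expression <- grid |> mutate(n_reads = 0, rpm = 0)
    return(merged)
  }
  pts <- reads |>
    transmute(.data$chrom, start = .data$start, end = .data$start + 1L,
              .data$plant, .data$time_hat,
              w = alignment_weights(reads, weight_mode))
  hits <- overlap_hits(pts, clusters)
  counts <- pts[hits$x, ] |>
    mutate(cluster_id = clusters$cluster_id[hits$y]) |>
    group_by(.data$cluster_id, .data$plant, .data$time_hat) |>
    summarise(n_reads = sum(.data$w), .groups = "drop")
  merged$expression <- grid |>
    left_join(counts, by = c("cluster_id", "plant", "time_hat")) |>
    mutate(n_reads = tidyr::replace_na(.data$n_reads, 0)) |>
    left_join(libraries$totals, by = c("plant", "time_hat")) |>
    mutate(rpm = normalize_rpm(.data$n_reads, .data$total_processed)) |>
    select("cluster_id", "plant", "time_hat", "n_reads", "rpm")
  merged
}

#' @export
print.merged_clusters <- function(x, ...) {
  cat(sprintf("<merged_clusters> %d merged clusters\n", nrow(x$clusters)))
  print(head(x$clusters, 5))
  invisible(x)
}

#' Score detected clusters against planted ground truth
#'
#' A planted cluster is recovered when a detected interval matches it; a
#' detected interval is a true positive when it matches some planted cluster.
#' By default matching requires >= 1 bp overlap (cluster calling is judged on
#' finding the planted locus, not on reproducing its exact boundaries, which
#' border reads can extend); `min_jaccard` imposes a stricter reciprocal
#' Jaccard threshold.
#'
#' @param detected Tibble of detected intervals (`chrom`, `start`, `end`).
#' @param truth_clusters Tibble of planted intervals.
#' @param min_jaccard Minimum Jaccard index (intersection / union of spans)
#'   for a match; 0 means any overlap.
#' @return One-row tibble: `n_detected`, `n_truth`, `tp`, `recovered`,
#'   `precision`, `recall`, `f1`.
#' @export
score_detection <- function(detected, truth_clusters, min_jaccard = 0) {
  detected <- as_tibble(detected)
  truth_clusters <- as_tibble(truth_clusters)
  if (nrow(detected) == 0 || nrow(truth_clusters) == 0) {
    return(tibble(n_detected = nrow(detected), n_truth = nrow(truth_clusters),
                  tp = 0L, recovered = 0L, precision = 0, recall = 0, f1 = 0))
  }
  hits <- overlap_hits(detected, truth_clusters)
  if (nrow(hits) > 0) {
    ds <- detected$start[hits$x]; de <- detected$end[hits$x]
    ts <- truth_clusters$start[hits$y]; te <- truth_clusters$end[hits$y]
    inter <- bp_overlap(ds, de, ts, te)
    jac <- inter / (pmax(de, te) - pmin(ds, ts))
    hits <- hits[jac >= min_jaccard, ]
  }
  tp <- length(unique(hits$x))
  recovered <- length(unique(hits$y))
  precision <- tp / nrow(detected)
  recall <- recovered / nrow(truth_clusters)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(n_detected = nrow(detected), n_truth = nrow(truth_clusters),
         tp = tp, recovered = recovered, precision = precision,
         recall = recall, f1 = f1)
}
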