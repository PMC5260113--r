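test_that("dense toy configurations cluster as the definition forces", {
  # 10 reads every 10 bp: all pairwise distances <= 90 <= epsilon, all core
  lib <- toy_library(starts = seq(0, 90, 10), lengths = 24L)
  det <- detect_clusters(lib, epsilon = 100, minpts = 10)
  expect_equal(nrow(det), 1)
  expect_equal(det$start, 0)
  expect_equal(det$end, 114)
  expect_equal(det$n_reads, 10)

  # 9 identical starts cannot reach minpts = 10
  lib9 <- toy_library(starts = rep(500, 9))
  expect_equal(nrow(detect_clusters(lib9, epsilon = 100, minpts = 10)), 0)
  expect_equal(nrow(detect_clusters(structure(list(
    reads = lib9$reads[0, ], totals = lib9$totals), class = "srna_libraries"))), 0)
})

test_that("two planted dense regions with sparse noise give exactly two clusters", {
  starts <- c(seq(1000, 1180, 20), seq(3000, 3180, 20), 1500, 2200, 2600)
  cl <- dbscan_1d(starts, epsilon = 100, minpts = 10)
  expect_equal(clustering_sets(starts, cl),
               clustering_sets(starts, dbscan_bruteforce(starts, 100, 10)))
  expect_equal(length(setdiff(unique(cl), 0L)), 2)
})

test_that("dbscan_1d matches the brute-force reference on random instances", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(20:500, 1)
    pos <- sample.int(20000, n, replace = TRUE)
    epsilon <- sample(c(25, 50, 100, 200), 1)
    minpts <- sample(c(3, 5, 10), 1)
    got <- dbscan_1d(pos, epsilon, minpts)
    want <- dbscan_bruteforce(pos, epsilon, minpts)
    expect_equal(clustering_sets(pos, got), clustering_sets(pos, want))
    # noise + clustered partition all points
    expect_equal(length(got), n)
  }
})

test_that("cluster assignment is invariant under input permutation", {
  set.seed(7)
  pos <- sample.int(5000, 300, replace = TRUE)
  ref <- dbscan_1d(pos, 100, 5)
  for (i in 1:5) {
    perm <- sample.int(300)
    got <- dbscan_1d(pos[perm], 100, 5)
    expect_equal(clustering_sets(pos[perm], got), clustering_sets(pos, ref))
  }
})

test_that("every cluster member lies within the reported interval and counts reach minpts", {
  ds <- simulate_dataset(sim_config(seed = 21, n_chroms = 1L, chrom_length = 5e5,
                                    n_genes = 15L, n_planted = 6L,
                                    contaminants_per_library = 0L))
  pre <- preprocess_reads(ds$reads)
  det <- detect_clusters(pre, epsilon = 100, minpts = 10)
  expect_true(all(det$end - det$start >= 1))
  expect_true(all(det$n_reads >= 10))
})

test_that("planted clusters are recovered at low background and epsilon halving only shrinks them", {
  # Jaccard >= 0.8 tests boundary accuracy, so background must be low enough
  # that border-read hull extensions (up to epsilon + read length on a
  # 100-500 bp cluster) stay rare: at 0.02 reads/kbp the expected number of
  # reads landing within epsilon of any of the 2 x 20 cluster edges across
  # the three merged samples is ~0.2.
  cfg <- sim_config(seed = 31, background_rate = 0.02)
  ds <- simulate_dataset(cfg)
  pre <- preprocess_reads(ds$reads, ds$filter_seqs)
  lib1 <- structure(list(
    reads = dplyr::filter(pre$reads, plant == "WT"),
    totals = dplyr::filter(pre$totals, plant == "WT")),
    class = "srna_libraries")
  det <- detect_clusters(lib1, epsilon = 100, minpts = 10)
  merged <- merge_clusters(det)
  score <- score_detection(merged$clusters, ds$truth$clusters, min_jaccard = 0.8)
  expect_gte(score$recovered, 19)

  det50 <- detect_clusters(lib1, epsilon = 50, minpts = 10)
  # each epsilon-50 cluster must lie inside some epsilon-100 cluster
  for (i in seq_len(nrow(det50))) {
    expect_true(any(det$chrom == det50$chrom[i] & det$start <= det50$start[i] &
                      det$end >= det50$end[i]))
  }
})

test_that("cluster merging is the transitive interval union with conserved counts", {
  a <- tibble::tibble(cluster_id = c("x", "y"), chrom = "chr1",
                      start = c(0L, 50L), end = c(100L, 150L), strand = ".",
                      plant = "WT", time_hat = c(0L, 6L), n_reads = c(10, 20),
                      rpm = c(1, 2))
  m <- merge_clusters(a)
  expect_equal(nrow(m$clusters), 1)
  expect_equal(m$clusters$start, 0)
  expect_equal(m$clusters$end, 150)
  expect_equal(sum(m$expression$n_reads), 30)

  b <- dplyr::mutate(a, start = c(0L, 200L), end = c(100L, 300L))
  expect_equal(nrow(merge_clusters(b)$clusters), 2)

  set.seed(55)
  r <- tibble::tibble(cluster_id = sprintf("c%d", 1:200),
                      chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                      start = sample.int(5000, 200, replace = TRUE))
  r <- dplyr::mutate(r, end = start + sample.int(300, 200, replace = TRUE),
                     strand = ".", plant = "WT", time_hat = 0L,
                     n_reads = 1, rpm = 1)
  m <- merge_clusters(r)
  want <- dplyr::bind_rows(lapply(split(r, r$chrom), function(d) {
    dplyr::mutate(merge_sweepline(d$start, d$end), chrom = d$chrom[1])
  }))
  got <- dplyr::arrange(m$clusters, chrom, start)
  want <- dplyr::arrange(want, chrom, start)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # disjointness and count conservation
  by_chrom <- split(got, got$chrom)
  for (d in by_chrom) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  expect_equal(sum(m$expression$n_reads), 200)
})

test_that("region re-quantification fills detection dropouts with true read counts", {
  lib <- toy_library(starts = c(seq(0, 90, 10), 5000), lengths = 24L)
  det <- detect_clusters(lib, epsilon = 100, minpts = 10)
  m <- merge_clusters(det) |> quantify_clusters(lib)
  expect_equal(nrow(m$expression), 1)
  expect_equal(m$expression$n_reads, 10)
  # a second sample with sub-threshold reads in the same region
  lib2 <- toy_library(starts = c(0, 40, 80), time_hat = 6L)
  both <- structure(list(reads = dplyr::bind_rows(lib$reads, lib2$reads),
                         totals = dplyr::bind_rows(lib$totals, lib2$totals)),
                    class = "srna_libraries")
  m2 <- quantify_clusters(merge_clusters(det), both)
  expect_equal(sort(m2$expression$n_reads), c(3, 10))
})
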