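flat_track <- function(chrom = "chr1", from = 0L, to = 200L, score = 0.7) {
  pos <- seq.int(from, to - 1L)
  tibble::tibble(chrom = chrom, start = pos, end = pos + 1L, score = score)
}

test_that("feature tiling drops sub-bin remainders and refuses CDS", {
  feats <- tibble::tibble(gene_id = "g1", feature = "intron", chrom = "chr1",
                          start = 0L, end = 100L)
  bins <- bin_feature_regions(feats)
  expect_equal(bins$start, c(0, 25, 50, 75))
  expect_equal(bins$end - bins$start, rep(25, 4))

  short <- dplyr::mutate(feats, end = 60L)
  expect_equal(nrow(bin_feature_regions(short)), 2)

  expect_error(bin_feature_regions(feats, features = c("intron", "cds")),
               "cds")
})

test_that("bin scores are per-base track averages with coverage flags", {
  feats <- tibble::tibble(gene_id = "g1", feature = "intron", chrom = "chr1",
                          start = 0L, end = 50L)
  bins <- bin_feature_regions(feats)
  scored <- score_bins(bins, flat_track(score = 0.7))
  expect_equal(scored$mean_score, c(0.7, 0.7))

  half <- dplyr::bind_rows(flat_track(from = 0L, to = 13L, score = 1),
                           flat_track(from = 13L, to = 50L, score = 0))
  got <- score_bins(bins, half)
  expect_equal(got$mean_score[1], 13 / 25 * 1)

  # random track equals a direct per-base averaging oracle
  set.seed(12)
  tr <- flat_track(to = 50L)
  tr$score <- runif(50)
  got2 <- score_bins(bins, tr)
  expect_equal(got2$mean_score, c(mean(tr$score[1:25]), mean(tr$score[26:50])))

  # low-coverage bins are flagged; absent chromosomes are an error
  gap <- flat_track(from = 20L, to = 50L)
  got3 <- score_bins(bins, gap)
  expect_true(got3$low_coverage[1])
  expect_false(got3$low_coverage[2])
  expect_error(score_bins(dplyr::mutate(bins, chrom = "chr9"), tr), "chr9")
})

test_that("cluster labels need at least one overlapping base", {
  bins <- tibble::tibble(gene_id = "g1", feature = "intron", chrom = "chr1",
                         start = c(0L, 25L, 50L), end = c(25L, 50L, 75L),
                         mean_score = 0.5, coverage = 1, low_coverage = FALSE)
  clusters <- tibble::tibble(cluster_id = "c1", chrom = "chr1",
                             start = 10L, end = 25L)
  lab <- label_cluster_bins(bins, clusters)
  expect_equal(lab$is_cluster_bin, c(TRUE, FALSE, FALSE))

  ds <- simulate_dataset(sim_config(seed = 41, n_chroms = 1L,
                                    chrom_length = 5e5, n_genes = 15L,
                                    n_planted = 6L,
                                    contaminants_per_library = 0L))
  bins2 <- bin_feature_regions(ds$annotation) |>
    score_bins(ds$conservation) |>
    label_cluster_bins(ds$truth$clusters)
  # oracle: linear scan against planted intervals
  want <- vapply(seq_len(nrow(bins2)), function(i) {
    any(ds$truth$clusters$chrom == bins2$chrom[i] &
          ds$truth$clusters$start < bins2$end[i] &
          ds$truth$clusters$end > bins2$start[i])
  }, logical(1))
  expect_equal(bins2$is_cluster_bin, want)
})

test_that("the resampled t-test is seeded, detects planted shifts and flags degeneracy", {
  set.seed(5)
  cl <- rnorm(100, 0.5, 0.1)
  bg <- rnorm(2000, 0.2, 0.1)
  r1 <- resampled_ttest(cl, bg, n_resamples = 200, seed = 9, feature = "intron")
  r2 <- resampled_ttest(cl, bg, n_resamples = 200, seed = 9, feature = "intron")
  expect_identical(r1$p_values, r2$p_values)
  expect_gte(r1$fraction_significant, 0.99)

  const <- resampled_ttest(rep(0.4, 10), rep(0.4, 50), n_resamples = 20, seed = 1)
  expect_equal(const$fraction_significant, 0)
  expect_equal(const$n_degenerate, 20)

  expect_error(resampled_ttest(c(0.1, 0.2), bg, feature = "intron"), "intron")
  expect_error(resampled_ttest(cl, bg[1:10], feature = "intron"),
               "at least as many")
})

test_that("cumulative distributions step from 0 to 1 across score thresholds", {
  bins <- tibble::tibble(mean_score = rep(0.55, 8),
                         is_cluster_bin = rep(c(TRUE, FALSE), 4))
  cum <- cumulative_score_distribution(bins)
  cl <- dplyr::filter(cum, group == "cluster")
  expect_equal(cl$cumulative_fraction[cl$threshold < 0.55], rep(0, 6))
  expect_equal(cl$cumulative_fraction[cl$threshold >= 0.6], rep(1, 5))
  expect_equal(dplyr::last(cum$cumulative_fraction), 1)

  none <- cumulative_score_distribution(dplyr::filter(bins, is_cluster_bin))
  expect_true(all(is.na(none$cumulative_fraction[none$group == "noncluster"])))

  set.seed(31)
  u <- tibble::tibble(mean_score = runif(5000), is_cluster_bin = FALSE)
  cum_u <- cumulative_score_distribution(u)
  nc <- dplyr::filter(cum_u, group == "noncluster")
  expect_true(all(abs(nc$cumulative_fraction - nc$threshold) < 0.03))
})

test_that("conserved candidates need opposite-sign fold changes and enough orthologs", {
  pairs <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), cluster_ids = c("c1", "c2", "c3"),
    plant = "WT", interval = "0to1",
    log2fc_gene = c(-2, 1.2, -1), log2fc_cluster = c(1.5, 0.8, 2))
  orth <- tidyr::expand_grid(
    gene_id = c("g1", "g2", "g3"),
    plant = c("Oryza sativa", "Zea mays", "Sorghum bicolor",
              "Brachypodium distachyon", "Setaria italica")) |>
    dplyr::filter(!(gene_id == "g3" &
                      plant %in% c("Zea mays", "Sorghum bicolor")))
  got <- select_conserved_candidates(pairs, orth)
  expect_equal(got$gene_id, "g1")   # g2: same sign; g3: only 3 species
})

test_that("cluster FASTA export extracts plus-strand subsequences", {
  genome <- c(chr1 = "ACGTACGTACGTACGTACGT", chr2 = "TTTTAAAACCCCGGGG")
  cl <- tibble::tibble(cluster_id = c("c1", "c2"), chrom = c("chr1", "chr2"),
                       start = c(0L, 4L), end = c(10L, 12L))
  seqs <- export_cluster_fasta(cl, genome)
  expect_equal(unname(seqs), c("ACGTACGTAC", "AAAACCCC"))
  expect_equal(names(seqs), c("c1", "c2"))

  path <- tempfile(fileext = ".fasta")
  export_cluster_fasta(cl, genome, path)
  expect_equal(unname(read_fasta(path)), unname(seqs))
  expect_equal(length(export_cluster_fasta(cl[0, ], genome)), 0)
  expect_error(export_cluster_fasta(dplyr::mutate(cl, end = 999L), genome),
               "exceeds")

  # random fixture vs direct substring oracle
  set.seed(2)
  chrom_seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                     collapse = "")
  cl2 <- tibble::tibble(cluster_id = sprintf("k%d", 1:5),
                        start = c(0L, 17L, 100L, 250L, 480L))
  cl2$end <- cl2$start + c(20L, 33L, 50L, 100L, 20L)
  cl2$chrom <- "chrZ"
  got <- export_cluster_fasta(cl2, c(chrZ = chrom_seq))
  expect_equal(unname(got), substring(chrom_seq, cl2$start + 1, cl2$end))
})
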