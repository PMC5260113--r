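small_cfg <- function(seed = 3, contaminants_per_library = 10L, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 5e5, n_genes = 15L,
             n_planted = 6L,
             contaminants_per_library = contaminants_per_library, ...)
}

test_that("simulation is deterministic: same seed gives byte-identical files", {
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(small_cfg()), d1)
  write_dataset(simulate_dataset(small_cfg()), d2)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("an empty gene set still yields a valid layout", {
  sim <- simulate_annotation(sim_config(seed = 1, n_genes = 0L))
  expect_equal(nrow(sim$annotation$genes), 0)
  expect_equal(nrow(sim$layout$chrom_sizes), 2)
  expect_true(all(sim$layout$centromeres$end <= sim$layout$chrom_sizes$length))
})

test_that("simulated gene bodies are pairwise disjoint", {
  sim <- simulate_annotation(sim_config(seed = 11, n_genes = 50L))
  g <- sim$annotation$genes
  expect_equal(nrow(g), 50)
  by_chrom <- split(g, g$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("with zero background every read lies inside a planted cluster", {
  cfg <- small_cfg(background_rate = 0, contaminants_per_library = 0L)
  ds <- simulate_dataset(cfg)
  hits <- overlap_query  # exercise exported surface per read is slow; use joins
  reads <- ds$reads
  tr <- ds$truth$clusters
  inside <- vapply(seq_len(nrow(reads)), function(i) {
    any(tr$chrom == reads$chrom[i] & tr$start <= reads$start[i] & tr$end >= reads$end[i])
  }, logical(1))
  expect_true(all(inside))
})

test_that("planted per-sample read counts are matched exactly", {
  ds <- simulate_dataset(small_cfg())
  tr <- ds$truth
  for (i in sample.int(nrow(tr$counts), 10)) {
    row <- tr$counts[i, ]
    cl <- tr$clusters[tr$clusters$cluster_id == row$cluster_id, ]
    n <- sum(ds$reads$plant == row$plant & ds$reads$time_hat == row$time_hat &
               ds$reads$origin == "planted" & ds$reads$chrom == cl$chrom &
               ds$reads$start >= cl$start & ds$reads$end <= cl$end)
    expect_equal(n, row$reads)
  }
  # every planted cluster meets the detectability precondition in all samples
  expect_true(all(tr$counts$reads >= 10))
  expect_true(all(tr$clusters$end - tr$clusters$start >= 100))
  # planted intervals are contained in their declared host feature
  feats <- simulate_annotation(small_cfg())$annotation$features
  j <- dplyr::inner_join(tr$clusters, feats, by = c("gene_id", "feature"),
                         suffix = c("", ".f"), relationship = "many-to-many") |>
    dplyr::group_by(cluster_id) |>
    dplyr::summarise(ok = any(start >= start.f & end <= end.f))
  expect_true(all(j$ok))
})

test_that("read lengths follow the configured 21/24-nt biased distribution", {
  cfg <- sim_config(seed = 5)
  set.seed(99)
  n <- 1e5
  lens <- table(factor(sirtron:::sample_lengths(n, cfg$read_length_dist),
                       levels = 18:30))
  p <- cfg$read_length_dist
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(as.numeric(lens) / n - p) <= 3 * se + 1e-9))
  expect_equal(sort(names(sort(p, decreasing = TRUE)[1:2])), c("21", "24"))
})

test_that("expression recovers the configured gene-cluster correlation", {
  for (rho in c(0, -0.8)) {
    cfg <- sim_config(seed = 13, n_chroms = 5L, chrom_length = 2e6,
                      n_genes = 180L, n_planted = 170L,
                      anticorrelation_rho = rho)
    ann <- simulate_annotation(cfg)
    tr <- simulate_truth(cfg, ann)
    ex <- simulate_expression(cfg, ann, tr)
    zc <- tr$counts |>
      dplyr::arrange(cluster_id, plant, time_hat) |>
      dplyr::group_by(cluster_id, plant) |>
      dplyr::reframe(interval = paste(head(time_hat, -1), tail(time_hat, -1)),
                     zc = diff(log2(reads))) |>
      dplyr::left_join(dplyr::select(tr$clusters, cluster_id, gene_id),
                       by = "cluster_id")
    zg <- ex |>
      dplyr::arrange(gene_id, plant, time_hat) |>
      dplyr::group_by(gene_id, plant) |>
      dplyr::reframe(interval = paste(head(time_hat, -1), tail(time_hat, -1)),
                     zg = diff(log2(fpkm)))
    j <- dplyr::inner_join(zc, zg, by = c("gene_id", "plant", "interval"))
    expect_gt(nrow(j), 500)
    expect_lt(abs(cor(j$zc, j$zg) - rho), 0.1)
  }
})

test_that("genes pinned below the floor are removed by the expression filter", {
  ds <- simulate_dataset(small_cfg())
  kept <- filter_expressed_genes(ds$expression)
  low <- ds$expression |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(mx = max(fpkm)) |>
    dplyr::filter(mx <= 1)
  expect_equal(nrow(low), 2)  # config plants two decoys
  expect_true(!any(kept$gene_id %in% low$gene_id))
  expect_setequal(unique(kept$gene_id), setdiff(unique(ds$expression$gene_id),
                                                low$gene_id))
})

test_that("conservation scores live in [0,1] and carry the planted uplift", {
  cfg <- small_cfg(conservation_effect = 0.3, conservation_noise_sd = 0.1)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$conservation$score >= 0 & ds$conservation$score <= 1))
  regions <- ds$truth$conservation_regions
  track <- ds$conservation
  inside <- rep(FALSE, nrow(track))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | (track$chrom == regions$chrom[i] &
                          track$start >= regions$start[i] &
                          track$end <= regions$end[i])
  }
  # baselines differ per feature, so compare within introns only
  cfg0 <- small_cfg(conservation_effect = 0)
  base <- simulate_conservation(cfg0, simulate_annotation(cfg0),
                                simulate_truth(cfg0, simulate_annotation(cfg0)))
  expect_lt(abs(mean(track$score[inside]) -
                  cfg$conservation_baseline[["intron"]] - 0.3), 0.05)
  expect_lt(abs(mean(base$score[inside]) -
                  cfg0$conservation_baseline[["intron"]]), 0.05)
})
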