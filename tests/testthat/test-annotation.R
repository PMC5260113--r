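test_that("GFF3 coordinates convert to 0-based half-open and introns are exon gaps", {
  path <- write_gff3_fixture(c(
    gff3_line("chr1", "gene", 1001, 2000, "+", "ID=g1"),
    gff3_line("chr1", "mRNA", 1001, 2000, "+", "ID=g1.1;Parent=g1"),
    gff3_line("chr1", "exon", 1001, 1200, "+", "Parent=g1.1"),
    gff3_line("chr1", "exon", 1501, 2000, "+", "Parent=g1.1")))
  ann <- read_gff3(path)
  expect_equal(ann$genes$start, 1000)
  expect_equal(ann$genes$end, 2000)
  introns <- dplyr::filter(ann$features, feature == "intron")
  expect_equal(introns$start, 1200)
  expect_equal(introns$end, 1500)
})

test_that("a single-exon gene has no introns", {
  path <- write_gff3_fixture(c(
    gff3_line("chr1", "gene", 101, 600, "+", "ID=g1"),
    gff3_line("chr1", "mRNA", 101, 600, "+", "ID=g1.1;Parent=g1"),
    gff3_line("chr1", "exon", 101, 600, "+", "Parent=g1.1")))
  ann <- read_gff3(path)
  expect_equal(sum(ann$features$feature == "intron"), 0)
})

test_that("multi-isoform genes use the longest transcript and features match the hand-enumerated table", {
  ann <- read_gff3(three_gene_gff3())
  expect_equal(ann$genes$transcript_id[ann$genes$gene_id == "geneA"], "geneA.2")
  expect_equal(ann$genes$transcript_id[ann$genes$gene_id == "geneB"], "geneB.1")

  fa <- dplyr::filter(ann$features, gene_id == "geneA") |>
    dplyr::arrange(feature, start)
  expected_a <- tibble::tribble(
    ~feature,          ~start, ~end,
    "cds",              1100L, 1400L,
    "cds",              1900L, 2100L,
    "exon",             1000L, 1400L,
    "exon",             1900L, 2200L,
    "exon",             2600L, 3000L,
    "five_prime_utr",   1000L, 1100L,
    "intron",           1400L, 1900L,
    "intron",           2200L, 2600L,
    "three_prime_utr",  2100L, 2200L,
    "three_prime_utr",  2600L, 3000L)
  expect_equal(fa[c("feature", "start", "end")], expected_a, ignore_attr = TRUE)

  fb <- dplyr::filter(ann$features, gene_id == "geneB") |>
    dplyr::arrange(feature, start)
  expected_b <- tibble::tribble(
    ~feature,          ~start, ~end,
    "cds",              5100L, 5400L,
    "cds",              5700L, 5900L,
    "exon",             5000L, 5400L,
    "exon",             5700L, 6000L,
    "five_prime_utr",   5900L, 6000L,
    "intron",           5400L, 5700L,
    "three_prime_utr",  5000L, 5100L)
  expect_equal(fb[c("feature", "start", "end")], expected_b, ignore_attr = TRUE)

  fc <- dplyr::filter(ann$features, gene_id == "geneC")
  expect_equal(sort(unique(fc$feature)), "exon")
})

test_that("UTR derivation is strand-aware and confined to exons", {
  ex <- tibble::tibble(start = 0L, end = 300L)
  cds <- tibble::tibble(start = 100L, end = 250L)
  plus <- derive_utrs(ex, cds, "+")
  expect_equal(plus$start[plus$feature == "five_prime_utr"], 0)
  expect_equal(plus$end[plus$feature == "five_prime_utr"], 100)
  expect_equal(plus$start[plus$feature == "three_prime_utr"], 250)
  expect_equal(plus$end[plus$feature == "three_prime_utr"], 300)
  minus <- derive_utrs(ex, cds, "-")
  expect_equal(minus$start[minus$feature == "five_prime_utr"], 250)
  expect_equal(minus$start[minus$feature == "three_prime_utr"], 0)

  # spliced gene, CDS crossing the intron: UTR pieces confined to exons
  ex2 <- tibble::tibble(start = c(0L, 500L), end = c(200L, 800L))
  cds2 <- tibble::tibble(start = c(150L, 500L), end = c(200L, 700L))
  utr <- derive_utrs(ex2, cds2, "+") |> dplyr::arrange(feature, start)
  expect_equal(utr$feature, c("five_prime_utr", "three_prime_utr"))
  expect_equal(utr$start, c(0, 700))
  expect_equal(utr$end, c(150, 800))
  expect_error(derive_utrs(ex, tibble::tibble(start = 250L, end = 350L), "+"),
               "not contained in exons")
})

test_that("malformed GFF3 lines and out-of-span exons raise named errors", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               gff3_line("chr1", "gene", 101, 600, "+", "ID=g1"),
               "chr1\tbroken line"), path)
  expect_error(read_gff3(path), "line 3")
  bad <- write_gff3_fixture(c(
    gff3_line("chr1", "gene", 101, 600, "+", "ID=g1"),
    gff3_line("chr1", "mRNA", 101, 600, "+", "ID=g1.1;Parent=g1"),
    gff3_line("chr1", "exon", 101, 700, "+", "Parent=g1.1")))
  expect_error(read_gff3(bad), "outside its gene span")
})

test_that("overlap_query uses half-open semantics and matches a linear scan", {
  ivs <- tibble::tibble(chrom = "chr1", start = c(0L, 55L), end = c(50L, 70L))
  hit <- overlap_query(ivs, list(chrom = "chr1", start = 50L, end = 60L))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 55)
  # query covering a whole chromosome returns everything on it
  all_hits <- overlap_query(ivs, list(chrom = "chr1", start = 0L, end = 10000L))
  expect_equal(nrow(all_hits), 2)

  set.seed(42)
  ivs <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
                        start = sample.int(10000, 1000, replace = TRUE))
  ivs$end <- ivs$start + sample.int(200, 1000, replace = TRUE)
  for (i in 1:100) {
    q <- list(chrom = sample(c("chr1", "chr2"), 1), start = sample.int(10000, 1),
              end = 0L)
    q$end <- q$start + sample.int(500, 1)
    got <- overlap_query(ivs, q)
    want <- ivs[ivs$chrom == q$chrom & ivs$start < q$end & ivs$end > q$start, ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("annotations survive a GFF3 round trip and respect containment invariants", {
  sim <- simulate_annotation(sim_config(seed = 7, n_genes = 20))
  ann <- sim$annotation
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gff3(path)
  ord <- function(x) dplyr::arrange(x, gene_id, feature, start)
  expect_equal(ord(back$features), ord(ann$features), ignore_attr = TRUE)
  expect_equal(dplyr::arrange(back$genes, gene_id),
               dplyr::arrange(ann$genes, gene_id), ignore_attr = TRUE)

  # every feature within its gene body; intron/exon partition the gene span
  joined <- dplyr::left_join(ann$features, ann$genes, by = "gene_id",
                             suffix = c("", ".g"))
  expect_true(all(joined$start >= joined$start.g & joined$end <= joined$end.g))
  widths <- joined |>
    dplyr::filter(feature %in% c("exon", "intron")) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(covered = sum(end - start),
                     span = dplyr::first(end.g) - dplyr::first(start.g))
  expect_equal(widths$covered, widths$span)
})
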