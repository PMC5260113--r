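# Synthetic data generator
#
# Emulates the structure of a drought time-course small-RNA experiment:
# three plants sampled at 0, 1 and 6 hours after treatment, with siRNA
# clusters planted inside gene features, 21/24-nt-biased read lengths,
# uniform background alignments, host-gene expression anti-correlated with
# cluster expression, and a per-base conservation track elevated over planted
# intronic clusters. Reads are emitted as already-aligned records: the
# pipeline's scope begins after mapping.

#' Simulation configuration
#'
#' Builds the configuration shared by all `simulate_*()` functions. Defaults
#' describe the study conditions: a 2-Mbp two-chromosome genome with 50
#' non-overlapping multi-exon genes, 20 planted clusters (60% intronic, 20%
#' in each UTR class), at least 10 reads per planted cluster per sample with
#' spans of at least 100 bp, background of 5 reads per kbp per library,
#' read lengths peaked at 21 and 24 nt, gene/cluster log2 fold changes
#' anti-correlated at rho = -0.8, and a conservation uplift of 0.3 (per-base
#' noise sd 0.1) confined to planted intronic clusters.
#'
#' @param seed Integer RNG seed; every stage derives its stream from it.
#' @param n_chroms,chrom_length Genome shape (bp per chromosome).
#' @param n_genes Number of genes to place.
#' @param plants,time_points Sample grid (plant labels, hours after treatment).
#' @param n_planted Number of planted siRNA clusters.
#' @param planted_feature_mix Named fractions over
#'   `c("intron", "five_prime_utr", "three_prime_utr")`.
#' @param planted_span_intron,planted_span_utr Length-2 ranges (bp) for
#'   planted cluster spans; all spans must be >= 100 bp.
#' @param planted_reads_range Range of baseline reads per cluster per sample
#'   at 0 hat; minimum must be >= 10.
#' @param fc_sd Standard deviation of log2 fold changes between consecutive
#'   time points (clusters and non-host genes).
#' @param background_rate Expected background reads per kbp per library.
#' @param read_length_dist Named numeric vector of length weights over
#'   18..30 nt; must sum to 1.
#' @param anticorrelation_rho Target Pearson correlation between planted
#'   cluster and host gene log2 fold changes; in `[-1, 0]`.
#' @param contaminants_per_library Reads per library whose sequences are
#'   drawn verbatim from the generated filter FASTA (removed by the ncRNA
#'   filter).
#' @param n_low_expression_genes Non-host genes pinned below the 1-FPKM
#'   expression floor (removed by the floor filter downstream).
#' @param conservation_effect Mean score uplift inside planted intronic
#'   clusters (>= 0).
#' @param conservation_noise_sd Per-base score noise sd.
#' @param conservation_baseline Named baselines per feature class.
#' @param exon_length,intron_length,utr5_length,utr3_length,n_exons_range,
#'   intergenic_gap Gene-architecture ranges (bp / counts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e6,
                       n_genes = 50L,
                       plants = c("WT", "ap2", "Vandana"),
                       time_points = c(0L, 1L, 6L),
                       n_planted = 20L,
                       planted_feature_mix = c(intron = 0.6,
                                               five_prime_utr = 0.2,
                                               three_prime_utr = 0.2),
                       planted_span_intron = c(200L, 500L),
                       planted_span_utr = c(100L, 140L),
                       planted_reads_range = c(50L, 200L),
                       fc_sd = 1.5,
                       background_rate = 5,
                       read_length_dist = c(`18` = 0.02, `19` = 0.03, `20` = 0.06,
                                            `21` = 0.30, `22` = 0.06, `23` = 0.05,
                                            `24` = 0.35, `25` = 0.05, `26` = 0.03,
                                            `27` = 0.02, `28` = 0.01, `29` = 0.01,
                                            `30` = 0.01),
                       anticorrelation_rho = -0.8,
                       contaminants_per_library = 25L,
                       n_low_expression_genes = 2L,
                       conservation_effect = 0.3,
                       conservation_noise_sd = 0.1,
                       conservation_baseline = c(five_prime_utr = 0.45, cds = 0.8,
                                                 intron = 0.25, three_prime_utr = 0.4),
                       exon_length = c(150L, 400L),
                       intron_length = c(500L, 2000L),
                       utr5_length = c(150L, 300L),
                       utr3_length = c(150L, 300L),
                       n_exons_range = c(3L, 5L),
                       intergenic_gap = c(4000L, 16000L)) {
  cfg <- as.list(environment())
  if (cfg$anticorrelation_rho < -1 || cfg$anticorrelation_rho > 0) {
    abort("anticorrelation_rho must lie in [-1, 0]")
  }
  lens <- as.integer(names(cfg$read_length_dist))
  if (any(lens < 18 | lens > 30) || abs(sum(cfg$read_length_dist) - 1) > 1e-8) {
    abort("read_length_dist must sum to 1 with support in 18..30 nt")
  }
  if (min(cfg$planted_span_intron) < 100 || min(cfg$planted_span_utr) < 100) {
    abort("planted cluster spans must be >= 100 bp")
  }
  if (min(cfg$planted_reads_range) < 10) {
    abort("planted reads per sample must be >= 10")
  }
  if (cfg$conservation_effect < 0) abort("conservation_effect must be >= 0")
  structure(cfg, class = "sim_config")
}

runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

#' Simulate a gene annotation and genome layout
#'
#' Places non-overlapping genes left to right along each chromosome, each
#' with 3-5 exons (so introns always exist), a CDS, and both UTRs; strands
#' are assigned at random. Centromeres occupy the middle 10% of each
#' chromosome. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `annotation` (a `gene_annotation`) and `layout`
#'   (chrom sizes + centromeres).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  layout <- list(
    chrom_sizes = tibble(chrom = chroms, length = as.integer(config$chrom_length)),
    centromeres = tibble(chrom = chroms,
                         start = as.integer(0.45 * config$chrom_length),
                         end = as.integer(0.55 * config$chrom_length))
  )
  genes <- list(); parts <- list()
  ci <- 1L
  cursor <- runif_int(1, config$intergenic_gap %/% 4L)
  for (g in seq_len(config$n_genes)) {
    n_ex <- runif_int(1, config$n_exons_range)
    ex_len <- runif_int(n_ex, config$exon_length)
    in_len <- runif_int(n_ex - 1, config$intron_length)
    u5 <- runif_int(1, config$utr5_length)
    u3 <- runif_int(1, config$utr3_length)
    strand <- sample(c("+", "-"), 1)
    # transcript-first/last exons must hold the UTR plus some CDS
    ex_len[1] <- max(ex_len[1], u5 + 60L)
    ex_len[n_ex] <- max(ex_len[n_ex], u3 + 60L)
    span <- sum(ex_len) + sum(in_len)
    start <- cursor
    if (start + span > config$chrom_length - 1000) {
      ci <- ci + 1L
      if (ci > config$n_chroms) {
        abort(sprintf("infeasible packing: %d genes do not fit in the genome", config$n_genes))
      }
      cursor <- runif_int(1, config$intergenic_gap %/% 4L)
      start <- cursor
    }
    # exon layout in genomic order; on '-' the transcript-first exon is rightmost
    if (strand == "-") { ex_len <- rev(ex_len); in_len <- rev(in_len) }
    ex_start <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
    ex_end <- ex_start + ex_len
    gene_id <- sprintf("gene%03d", g)
    if (strand == "+") {
      cds_lo <- start + u5; cds_hi <- ex_end[n_ex] - u3
    } else {
      cds_lo <- start + u3; cds_hi <- ex_end[n_ex] - u5
    }
    exon_tbl <- tibble(type = "exon", gene_id = gene_id, chrom = chroms[ci],
                       start = ex_start, end = ex_end, strand = strand)
    cds_s <- pmax(ex_start, cds_lo); cds_e <- pmin(ex_end, cds_hi)
    keep <- cds_e > cds_s
    cds_tbl <- tibble(type = "cds", gene_id = gene_id, chrom = chroms[ci],
                      start = cds_s[keep], end = cds_e[keep], strand = strand)
    parts[[g]] <- bind_rows(exon_tbl, cds_tbl)
    genes[[g]] <- tibble(gene_id = gene_id, chrom = chroms[ci],
                         start = start, end = ex_end[n_ex], strand = strand,
                         transcript_id = paste0(gene_id, ".1"))
    cursor <- ex_end[n_ex] + runif_int(1, config$intergenic_gap)
  }
  empty_features <- tibble(gene_id = character(), chrom = character(),
                           strand = character(), feature = character(),
                           start = integer(), end = integer())
  if (config$n_genes == 0) {
    return(list(annotation = new_annotation(
      tibble(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), transcript_id = character()),
      empty_features), layout = layout))
  }
  genes <- bind_rows(genes)
  features <- bind_rows(parts) |>
    split(~gene_id) |>
    purrr::map(derive_gene_features) |>
    bind_rows() |>
    arrange(.data$chrom, .data$start)
  list(annotation = new_annotation(genes, features), layout = layout)
}

#' Plant ground-truth siRNA clusters and their per-sample read counts
#'
#' Chooses host genes (without replacement), places each planted cluster
#' inside a host feature of the configured class, and draws per-sample read
#' counts: a baseline at 0 hat and lognormal-scale fold changes between
#' consecutive time points, floored at 10 reads so every planted cluster
#' meets the detection precondition in every sample.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return A list of class `sirtron_truth` with tibbles `clusters`
#'   (`cluster_id`, `gene_id`, `feature`, `chrom`, `start`, `end`) and
#'   `counts` (`cluster_id`, `plant`, `time_hat`, `reads`), plus the
#'   generator `rho` and the conservation uplift regions.
#' @export
simulate_truth <- function(config, annotation) {
  set.seed(config$seed + 1L)
  ann <- annotation$annotation
  n_feat <- round(config$n_planted * config$planted_feature_mix /
                    sum(config$planted_feature_mix))
  # rounding drift goes to introns
  n_feat["intron"] <- config$n_planted - sum(n_feat[names(n_feat) != "intron"])
  feature_of <- rep(names(n_feat), times = n_feat)
  hosts <- sample(ann$genes$gene_id, config$n_planted)
  clusters <- purrr::map2(hosts, feature_of, function(gid, feat) {
    span_range <- if (feat == "intron") config$planted_span_intron else config$planted_span_utr
    cand <- ann$features |>
      filter(.data$gene_id == gid, .data$feature == feat,
             .data$end - .data$start >= span_range[1] + 10L)
    if (nrow(cand) == 0) return(NULL)
    host <- cand[sample.int(nrow(cand), 1), ]
    span <- min(runif_int(1, span_range), host$end - host$start - 2L)
    s <- host$start + runif_int(1, c(0L, host$end - host$start - span))
    tibble(gene_id = gid, feature = feat, chrom = host$chrom,
           start = s, end = s + span)
  }) |> bind_rows()
  if (nrow(clusters) < config$n_planted) {
    abort("could not place every planted cluster; enlarge host features")
  }
  clusters <- clusters |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("truth%03d", row_number()), .before = 1)

  grid <- tidyr::expand_grid(cluster_id = clusters$cluster_id,
                             plant = config$plants)
  tps <- sort(config$time_points)
  counts <- grid |>
    mutate(base = runif_int(n(), config$planted_reads_range)) |>
    purrr::pmap(function(cluster_id, plant, base) {
      z <- rnorm(length(tps) - 1, 0, config$fc_sd)
      reads <- pmin(3000L, pmax(10L, as.integer(round(base * 2^cumsum(c(0, z))))))
      tibble(cluster_id = cluster_id, plant = plant, time_hat = tps, reads = reads)
    }) |>
    bind_rows()
  structure(list(clusters = clusters, counts = counts,
                 rho = config$anticorrelation_rho,
                 conservation_regions = clusters |>
                   filter(.data$feature == "intron") |>
                   select("chrom", "start", "end")),
            class = "sirtron_truth")
}

sample_lengths <- function(n, dist) {
  as.integer(sample(as.integer(names(dist)), n, replace = TRUE, prob = dist))
}

#' Generate a small filter FASTA of non-coding RNA sequences
#'
#' Eight miRNA-sized (21-24 nt) and two rRNA-sized (80 nt) random sequences;
#' contaminant reads emitted by [simulate_reads()] are verbatim substrings of
#' these.
#'
#' @param config A [sim_config()].
#' @return A named character vector of sequences.
#' @export
simulate_filter_fasta <- function(config) {
  set.seed(config$seed + 5L)
  lens <- c(runif_int(8, c(21L, 24L)), 80L, 80L)
  names(lens) <- c(sprintf("mir-%d", 1:8), "rRNA-1", "rRNA-2")
  vapply(lens, function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                 collapse = ""), character(1))
}

#' Simulate aligned small-RNA read libraries
#'
#' One library per plant x time point. Planted reads fall entirely inside
#' their cluster span (starts uniform, lengths from the configured 21/24-nt
#' biased distribution) and match the ground-truth counts exactly; background
#' reads are Poisson-distributed (`background_rate` per kbp) and uniform
#' genome-wide; an optional contaminant subset carries sequences copied from
#' the filter FASTA. All records have zero mismatches and a single mapping
#' site.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param truth Output of [simulate_truth()].
#' @param filter_seqs Optional named character vector from
#'   [simulate_filter_fasta()]; required when `contaminants_per_library > 0`.
#' @return A tibble of read alignments: `chrom`, `start`, `end`, `read_id`,
#'   `strand`, `length`, `mismatches`, `n_sites`, `sequence`, `plant`,
#'   `time_hat`, `origin` (`planted`/`background`/`contaminant`).
#' @export
simulate_reads <- function(config, annotation, truth, filter_seqs = NULL) {
  set.seed(config$seed + 2L)
  layout <- annotation$layout
  libs <- tidyr::expand_grid(plant = config$plants, time_hat = sort(config$time_points))
  out <- purrr::pmap(libs, function(plant, time_hat) {
    planted <- truth$counts |>
      filter(.data$plant == !!plant, .data$time_hat == !!time_hat) |>
      left_join(truth$clusters, by = "cluster_id")
    pl <- purrr::pmap(
      planted[c("chrom", "start", "end", "reads")],
      function(chrom, start, end, reads) {
        len <- sample_lengths(reads, config$read_length_dist)
        s <- start + as.integer(floor(runif(reads) * (end - start - len + 1)))
        tibble(chrom = chrom, start = s, end = s + len, strand =
                 sample(c("+", "-"), reads, replace = TRUE), length = len,
               origin = "planted")
      }) |> bind_rows()
    bg <- purrr::pmap(layout$chrom_sizes, function(chrom, length) {
      n <- rpois(1, config$background_rate * length / 1000)
      lens <- sample_lengths(n, config$read_length_dist)
      s <- as.integer(floor(runif(n) * (length - lens)))
      tibble(chrom = chrom, start = s, end = s + lens,
             strand = sample(c("+", "-"), n, replace = TRUE), length = lens,
             origin = "background")
    }) |> bind_rows()
    reads <- bind_rows(pl, bg) |> mutate(sequence = NA_character_)
    if (config$contaminants_per_library > 0) {
      if (is.null(filter_seqs)) abort("filter_seqs required when contaminants are configured")
      n <- config$contaminants_per_library
      src <- sample(filter_seqs, n, replace = TRUE)
      len <- pmin(nchar(src), sample_lengths(n, config$read_length_dist))
      off <- as.integer(floor(runif(n) * (nchar(src) - len + 1)))
      seqs <- substr(src, off + 1L, off + len)
      ch <- sample(layout$chrom_sizes$chrom, n, replace = TRUE)
      cl <- layout$chrom_sizes$length[match(ch, layout$chrom_sizes$chrom)]
      s <- as.integer(floor(runif(n) * (cl - len)))
      reads <- bind_rows(reads, tibble(chrom = ch, start = s, end = s + len,
                                       strand = sample(c("+", "-"), n, replace = TRUE),
                                       length = len, origin = "contaminant",
                                       sequence = unname(seqs)))
    }
    reads |>
      arrange(.data$chrom, .data$start, .data$end) |>
      mutate(read_id = sprintf("%s_%s_r%06d", plant, time_hat, row_number()),
             mismatches = 0L, n_sites = 1L, plant = plant, time_hat = time_hat)
  })
  bind_rows(out) |>
    select("chrom", "start", "end", "read_id", "strand", "length",
           "mismatches", "n_sites", "sequence", "plant", "time_hat", "origin")
}

#' Simulate gene expression anti-correlated with planted cluster expression
#'
#' Host-gene log2 fold changes between consecutive time points are drawn
#' conditionally on the realised planted-cluster fold changes so that their
#' correlation equals `anticorrelation_rho`; non-host genes change
#' independently. Baseline FPKM is lognormal and floored at 5 so no gene is
#' accidentally removed by the 1-FPKM floor; the configured number of decoy
#' genes is pinned at 0.5 FPKM to exercise the floor filter.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param truth Output of [simulate_truth()].
#' @return A tibble `gene_id`, `plant`, `time_hat`, `fpkm`.
#' @export
simulate_expression <- function(config, annotation, truth) {
  set.seed(config$seed + 3L)
  tps <- sort(config$time_points)
  rho <- config$anticorrelation_rho
  genes <- annotation$annotation$genes$gene_id
  hosts <- truth$clusters$gene_id
  host_of <- setNames(truth$clusters$gene_id, truth$clusters$cluster_id)

  # realised cluster log2 fold changes per plant/interval
  cfc <- truth$counts |>
    arrange(.data$cluster_id, .data$plant, .data$time_hat) |>
    group_by(.data$cluster_id, .data$plant) |>
    summarise(zc = list(diff(log2(.data$reads))), .groups = "drop") |>
    mutate(gene_id = host_of[.data$cluster_id])

  non_hosts <- setdiff(genes, hosts)
  low <- head(non_hosts, config$n_low_expression_genes)
  grid <- tidyr::expand_grid(gene_id = genes, plant = config$plants)
  # expressed-gene scale: lognormal around 100 FPKM, clamped at 30 so the
  # downstream pseudocount of 1 is negligible against any time point
  base <- pmax(30, rlnorm(length(genes), log(100), 0.5))
  names(base) <- genes
  rows <- purrr::pmap(grid, function(gene_id, plant) {
    gid <- gene_id; pl <- plant
    if (gid %in% low) {
      return(tibble(gene_id = gid, plant = pl, time_hat = tps, fpkm = 0.5))
    }
    zrow <- cfc |> filter(.data$gene_id == gid, .data$plant == pl)
    zg <- if (nrow(zrow) == 1) {
      zc <- zrow$zc[[1]]
      rho * zc + sqrt(1 - rho^2) * rnorm(length(zc), 0, config$fc_sd)
    } else {
      rnorm(length(tps) - 1, 0, config$fc_sd)
    }
    tibble(gene_id = gid, plant = pl, time_hat = tps,
           fpkm = base[[gid]] * 2^cumsum(c(0, zg)))
  })
  bind_rows(rows)
}

#' Simulate a per-base conservation track over gene features
#'
#' Scores are drawn per base as a feature-specific baseline (CDS high, introns
#' low, UTRs intermediate) plus Gaussian noise, with `conservation_effect`
#' added inside planted intronic clusters, then clipped to `[0, 1]`. Only
#' annotated CDS/UTR/intron bases are covered (mirroring a track computed
#' from gene-anchored alignments).
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param truth Output of [simulate_truth()].
#' @return A conservation track tibble: `chrom`, `start`, `end`, `score`,
#'   one row per covered base, scores rounded to 4 decimals.
#' @export
simulate_conservation <- function(config, annotation, truth) {
  set.seed(config$seed + 4L)
  feats <- annotation$annotation$features |>
    filter(.data$feature %in% FEATURE_LEVELS) |>
    arrange(.data$chrom, .data$start)
  per_feat <- purrr::pmap(feats[c("chrom", "start", "end", "feature")],
                          function(chrom, start, end, feature) {
    pos <- seq.int(start, end - 1L)
    tibble(chrom = chrom, start = pos, end = pos + 1L,
           score = config$conservation_baseline[[feature]] +
             rnorm(length(pos), 0, config$conservation_noise_sd))
  }) |> bind_rows()
  if (config$conservation_effect > 0 && nrow(truth$conservation_regions) > 0) {
    hits <- overlap_hits(per_feat, truth$conservation_regions)
    per_feat$score[unique(hits$x)] <- per_feat$score[unique(hits$x)] +
      config$conservation_effect
  }
  per_feat |> mutate(score = round(pmin(1, pmax(0, .data$score)), 4))
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs annotation, truth planting, read, expression and conservation
#' simulation in order, all deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `annotation`, `layout`, `truth`, `filter_seqs`,
#'   `reads`, `expression`, `conservation`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  truth <- simulate_truth(config, ann)
  filter_seqs <- if (config$contaminants_per_library > 0) {
    simulate_filter_fasta(config)
  } else NULL
  reads <- simulate_reads(config, ann, truth, filter_seqs)
  expression <- simulate_expression(config, ann, truth)
  conservation <- simulate_conservation(config, ann, truth)
  list(config = config, annotation = ann$annotation, layout = ann$layout,
       truth = truth, filter_seqs = filter_seqs, reads = reads,
       expression = expression, conservation = conservation)
}

#' Write a simulated dataset to plain-text files
#'
#' GFF3 annotation, per-library BED6+3 reads, wide FPKM TSV, bedGraph
#' conservation, filter FASTA, chrom-size/centromere TSVs and a JSON ground
#' truth, all byte-deterministic given the config seed.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- c(annotation = p("annotation.gff3"), chrom_sizes = p("chrom_sizes.tsv"),
             centromeres = p("centromeres.tsv"), expression = p("expression.tsv"),
             conservation = p("conservation.bedgraph"), truth = p("ground_truth.json"))
  write_gff3(list(genes = dataset$annotation$genes,
                  features = dataset$annotation$features), paths["annotation"])
  write_genome_layout(dataset$layout, paths["chrom_sizes"], paths["centromeres"])
  write_expression_table(dataset$expression, paths["expression"])
  write_bedgraph(dataset$conservation, paths["conservation"])
  write_ground_truth(dataset$truth, paths["truth"])
  if (!is.null(dataset$filter_seqs)) {
    paths["filter_fasta"] <- p("filter.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(dataset$filter_seqs),
                                paths["filter_fasta"])
  }
  libs <- dataset$reads |> distinct(.data$plant, .data$time_hat)
  for (i in seq_len(nrow(libs))) {
    lib <- dataset$reads |>
      filter(.data$plant == libs$plant[i], .data$time_hat == libs$time_hat[i])
    f <- p(sprintf("reads_%s_%s.bed", libs$plant[i], libs$time_hat[i]))
    paths[sprintf("reads_%s_%s", libs$plant[i], libs$time_hat[i])] <- f
    write_reads_bed(lib, f)
  }
  invisible(paths)
}

#' Write ground truth to JSON
#' @param truth A `sirtron_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(clusters = truth$clusters, counts = truth$counts,
                            rho = truth$rho,
                            conservation_regions = truth$conservation_regions),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read ground truth from JSON
#' @param path Path written by [write_ground_truth()].
#' @return A `sirtron_truth` list.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(clusters = as_tibble(x$clusters), counts = as_tibble(x$counts),
                 rho = x$rho, conservation_regions = as_tibble(x$conservation_regions)),
            class = "sirtron_truth")
}
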