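# End-to-end orchestration: preprocess -> cluster -> merge -> associate ->
# enrich -> conserve -> export, from a single validated config, with a JSON
# run manifest. Reruns with the same config are byte-identical (no
# timestamps in any output).

pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "sirtron_output",
    inputs = list(annotation = NULL, chrom_sizes = NULL, centromeres = NULL,
                  reads = NULL, expression = NULL, conservation = NULL,
                  filter_fasta = NULL, genome_fasta = NULL, orthologs = NULL),
    simulate = NULL,
    preprocess = list(min_len = 18L, max_len = 30L, max_mismatch = 0L,
                      max_sites = 5L, denominator = "post_filter",
                      weight_mode = "fractional"),
    cluster = list(epsilon = 100, minpts = 10L, auto = FALSE, k = 30L,
                   stranded = FALSE, min_span = NULL),
    association = list(min_fraction = 0.5, strict_containment = FALSE,
                       pseudocount = 1.0, expression_floor = 1.0),
    conservation = list(bin = 25L, n_resamples = 1000L, alpha = 0.05,
                        significant_fraction = 0.95, min_coverage = 0.5)
  )
}

merge_config <- function(defaults, user, path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown %s key: %s", path, unknown[1]))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) && k != "simulate" &&
        k != "reads") {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build a pipeline configuration
#'
#' Merges user settings over the documented defaults (18-30 nt reads, no
#' mismatches, up to 5 sites, post-filter RPM denominators; epsilon 100 bp,
#' minpts 10, k 30; 50% containment, pseudocount 1, 1-FPKM floor; 25-nt
#' bins, 1000 resamples, alpha 0.05). Unknown keys are rejected. Provide
#' either a `simulate` block (passed to [sim_config()]) or explicit input
#' paths.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   structure.
#' @return The validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  merge_config(pipeline_defaults(), config)
}

validate_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) return(invisible(cfg))
  req <- c("annotation", "chrom_sizes", "centromeres", "reads", "expression",
           "conservation")
  for (k in req) {
    if (is.null(cfg$inputs[[k]])) {
      abort(sprintf("missing required input '%s' (and no simulate block given)", k))
    }
  }
  paths <- c(cfg$inputs$annotation, cfg$inputs$chrom_sizes, cfg$inputs$centromeres,
             cfg$inputs$expression, cfg$inputs$conservation,
             vapply(cfg$inputs$reads, function(r) r$path, character(1)))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) abort(sprintf("input file not found: %s", missing[1]))
  invisible(cfg)
}

#' Run the full siRNA cluster analysis pipeline
#'
#' Executes preprocessing, per-sample cluster detection, per-plant and global
#' merging, gene association and fold-change correlation, feature enrichment
#' and chromosomal positioning, and the binned conservation test, writing
#' every result as a plain-text file plus a JSON manifest (config hash,
#' seeds, package version, per-stage record counts, output list). With a
#' `simulate` block the ground-truthed inputs are generated, written under
#' `<output_dir>/inputs`, and read back through the same file interfaces as
#' user data.
#'
#' @param config A config list or YAML path (see [pipeline_config()]).
#' @return Invisibly, a list with the main in-memory results (`libraries`,
#'   `detected`, `merged_by_plant`, `merged_all`, `assignment`, `pairs`,
#'   `correlation`, `enrichment`, `profile`, `bins`, `conservation_test`,
#'   `manifest`).
#' @export
run_all <- function(config = list()) {
  cfg <- pipeline_config(config)
  validate_pipeline_inputs(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  counts <- list()
  outputs <- character()

  # --- inputs ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(sim_config, c(cfg$simulate,
                                     if (is.null(cfg$simulate$seed)) list(seed = cfg$seed)))
    dataset <- simulate_dataset(sim_cfg)
    in_dir <- out("inputs")
    paths <- write_dataset(dataset, in_dir)
    outputs <- c(outputs, unname(paths))
    libs <- dataset$reads |> distinct(.data$plant, .data$time_hat)
    cfg$inputs <- list(
      annotation = unname(paths[["annotation"]]),
      chrom_sizes = unname(paths[["chrom_sizes"]]),
      centromeres = unname(paths[["centromeres"]]),
      expression = unname(paths[["expression"]]),
      conservation = unname(paths[["conservation"]]),
      filter_fasta = if ("filter_fasta" %in% names(paths)) unname(paths[["filter_fasta"]]),
      genome_fasta = cfg$inputs$genome_fasta,
      orthologs = cfg$inputs$orthologs,
      reads = purrr::pmap(libs, function(plant, time_hat) {
        list(plant = plant, time_hat = time_hat,
             path = unname(paths[[sprintf("reads_%s_%s", plant, time_hat)]]))
      }))
  }
  annotation <- read_gff3(cfg$inputs$annotation)
  layout <- read_genome_layout(cfg$inputs$chrom_sizes, cfg$inputs$centromeres)
  reads <- purrr::map(cfg$inputs$reads, function(r) {
    read_reads_bed(r$path, plant = r$plant, time_hat = as.integer(r$time_hat))
  }) |> bind_rows()
  expression <- read_expression_table(cfg$inputs$expression)
  track <- read_bedgraph(cfg$inputs$conservation)
  filter_seqs <- if (!is.null(cfg$inputs$filter_fasta)) read_fasta(cfg$inputs$filter_fasta)
  counts$reads_in <- nrow(reads)

  # --- preprocess -----------------------------------------------------------
  libraries <- preprocess_reads(reads, filter_seqs = filter_seqs,
                                min_len = cfg$preprocess$min_len,
                                max_len = cfg$preprocess$max_len,
                                max_mismatch = cfg$preprocess$max_mismatch,
                                max_sites = cfg$preprocess$max_sites,
                                denominator = cfg$preprocess$denominator)
  counts$reads_retained <- nrow(libraries$reads)
  hist <- length_histogram(libraries, cfg$preprocess$weight_mode)
  readr::write_tsv(hist, out("length_histogram.tsv"))
  outputs <- c(outputs, out("length_histogram.tsv"))

  # --- cluster detection ----------------------------------------------------
  epsilon <- cfg$cluster$epsilon
  minpts <- cfg$cluster$minpts
  if (isTRUE(cfg$cluster$auto)) {
    # parameters fitted once, on the first library, and reused for the rest
    first <- libraries$reads |>
      filter(.data$plant == cfg$inputs$reads[[1]]$plant,
             .data$time_hat == cfg$inputs$reads[[1]]$time_hat)
    profile <- kdist_profile(first, k = cfg$cluster$k)
    epsilon <- as.numeric(select_epsilon(profile))
    readr::write_tsv(tibble(rank = seq_along(profile),
                            kdist = as.numeric(profile)),
                     out("kdist_profile.tsv"))
    outputs <- c(outputs, out("kdist_profile.tsv"))
  }
  detected <- detect_clusters(libraries, epsilon = epsilon, minpts = minpts,
                              stranded = cfg$cluster$stranded,
                              min_span = cfg$cluster$min_span,
                              weight_mode = cfg$preprocess$weight_mode)
  counts$clusters_per_sample <- detected |>
    count(.data$plant, .data$time_hat) |>
    tidyr::unite("sample", "plant", "time_hat") |>
    tibble::deframe() |> as.list()

  # --- merge: per plant (cluster catalogues) and globally (regions) ---------
  plants <- unique(vapply(cfg$inputs$reads, function(r) r$plant, character(1)))
  merged_by_plant <- purrr::map(setNames(plants, plants), function(p) {
    m <- merge_clusters(detected |> filter(.data$plant == p))
    m$clusters$cluster_id <- paste0(p, "_", m$clusters$cluster_id)
    m$expression$cluster_id <- paste0(p, "_", m$expression$cluster_id)
    lib_p <- structure(list(reads = libraries$reads |> filter(.data$plant == p),
                            totals = libraries$totals |> filter(.data$plant == p)),
                       class = "srna_libraries")
    quantify_clusters(m, lib_p, cfg$preprocess$weight_mode)
  })
  merged_all <- merge_clusters(detected)
  counts$merged_clusters_per_plant <- purrr::map(merged_by_plant,
                                                 ~ nrow(.x$clusters))
  counts$merged_clusters_all <- nrow(merged_all$clusters)
  for (p in plants) {
    write_clusters_bed(merged_by_plant[[p]]$clusters,
                       out(sprintf("clusters_%s.bed", p)))
    readr::write_tsv(merged_by_plant[[p]]$expression,
                     out(sprintf("cluster_expression_%s.tsv", p)))
    outputs <- c(outputs, out(sprintf("clusters_%s.bed", p)),
                 out(sprintf("cluster_expression_%s.tsv", p)))
  }
  write_clusters_bed(merged_all$clusters, out("clusters_all.bed"))
  outputs <- c(outputs, out("clusters_all.bed"))

  # --- gene association and expression correlation --------------------------
  expr_kept <- filter_expressed_genes(expression, cfg$association$expression_floor)
  pairs <- purrr::map(plants, function(p) {
    m <- merged_by_plant[[p]]
    a <- assign_targets(m, annotation,
                        min_fraction = cfg$association$min_fraction,
                        strict_containment = cfg$association$strict_containment)
    gene_cluster_pairs(a, m$expression,
                       expr_kept |> filter(.data$plant == p),
                       pseudocount = cfg$association$pseudocount)
  }) |> bind_rows()
  correlation <- correlation_report(pairs)
  assignment <- assign_targets(merged_all, annotation,
                               min_fraction = cfg$association$min_fraction,
                               strict_containment = cfg$association$strict_containment)
  counts$gene_cluster_pairs <- nrow(pairs)
  counts$target_genes <- dplyr::n_distinct(assignment$pairs$gene_id)
  counts$intergenic_clusters <- nrow(assignment$intergenic)
  readr::write_tsv(pairs, out("pairs.tsv"))
  readr::write_tsv(tibble(gene_id = sort(unique(assignment$pairs$gene_id))),
                   out("target_genes.txt"), col_names = FALSE)
  write_clusters_bed(assignment$intergenic, out("intergenic_clusters.bed"))
  outputs <- c(outputs, out("pairs.tsv"), out("target_genes.txt"),
               out("intergenic_clusters.bed"))

  # --- enrichment and chromosomal positioning -------------------------------
  classified <- classify_cluster_feature(merged_all, assignment, annotation)
  enrichment <- feature_odds_ratio(classified, annotation)
  profile <- chrom_position_profile(merged_all, layout)
  readr::write_tsv(enrichment, out("enrichment.tsv"))
  readr::write_tsv(profile$density, out("chrom_profile.tsv"))
  outputs <- c(outputs, out("enrichment.tsv"), out("chrom_profile.tsv"))

  # --- conservation ---------------------------------------------------------
  bins <- bin_feature_regions(annotation, bin = cfg$conservation$bin) |>
    score_bins(track, min_coverage = cfg$conservation$min_coverage) |>
    label_cluster_bins(merged_all)
  cons <- conservation_test(bins,
                            n_resamples = cfg$conservation$n_resamples,
                            alpha = cfg$conservation$alpha,
                            seed = cfg$seed,
                            significant_fraction = cfg$conservation$significant_fraction)
  cumul <- cumulative_score_distribution(bins |> filter(.data$feature == "intron"))
  counts$conservation_bins <- nrow(bins)
  counts$cluster_bins <- sum(bins$is_cluster_bin)
  readr::write_tsv(bins, out("conservation_bins.tsv"))
  readr::write_tsv(tidy(cons), out("conservation_test.tsv"))
  jsonlite::write_json(tidy(cons), out("conservation_test.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(cumul, out("cumulative_conservation.tsv"))
  outputs <- c(outputs, out("conservation_bins.tsv"), out("conservation_test.tsv"),
               out("conservation_test.json"), out("cumulative_conservation.tsv"))

  # --- optional candidate selection and sequence export ---------------------
  if (!is.null(cfg$inputs$orthologs)) {
    orth <- readr::read_tsv(cfg$inputs$orthologs, col_types = readr::cols(),
                            progress = FALSE)
    candidates <- select_conserved_candidates(pairs, orth)
    readr::write_tsv(candidates, out("candidates.tsv"))
    outputs <- c(outputs, out("candidates.tsv"))
    counts$candidates <- nrow(candidates)
  }
  if (!is.null(cfg$inputs$genome_fasta)) {
    export_cluster_fasta(merged_all, cfg$inputs$genome_fasta,
                         out("clusters.fasta"))
    outputs <- c(outputs, out("clusters.fasta"))
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(config_hash = rlang::hash(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("sirtron")),
                   epsilon = epsilon, minpts = minpts,
                   counts = counts,
                   outputs = sort(unique(outputs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = cfg, libraries = libraries, detected = detected,
                 merged_by_plant = merged_by_plant, merged_all = merged_all,
                 assignment = assignment, pairs = pairs,
                 correlation = correlation, enrichment = enrichment,
                 profile = profile, bins = bins, conservation_test = cons,
                 manifest = manifest))
}
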