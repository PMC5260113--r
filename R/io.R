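# Plain-text file interfaces. Reads travel as BED6+3 (chrom, start, end,
# read_id, score, strand + length, mismatches, n_sites), conservation as
# bedGraph, expression as a wide TSV (gene_id x sample columns "plant_hat").

#' Write read alignments as BED6+3
#'
#' @param reads Read tibble (see [simulate_reads()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  out <- reads |>
    transmute(.data$chrom, .data$start, .data$end, .data$read_id, score = 0L,
              .data$strand, .data$length, .data$mismatches, .data$n_sites)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read BED6+3 read alignments
#'
#' @param path BED6+3 file path.
#' @param plant,time_hat Optional sample labels attached to every record.
#' @return A read tibble in 0-based half-open coordinates.
#' @export
read_reads_bed <- function(path, plant = NA_character_, time_hat = NA_integer_) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "read_id",
                                      "score", "strand", "length",
                                      "mismatches", "n_sites"),
                  col_types = "ciiciciii", progress = FALSE) |>
    select(-"score") |>
    mutate(sequence = NA_character_, plant = plant, time_hat = time_hat)
}

#' Write a conservation track as bedGraph
#' @param track Tibble `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%.4f", track$chrom, track$start,
                     track$end, track$score), con)
  invisible(path)
}

#' Read a bedGraph conservation track
#' @param path bedGraph path (no header line required; `track` lines skipped).
#' @return Tibble `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") & nzchar(lines)]
  m <- stringr::str_split_fixed(lines, "\t", 4)
  tibble(chrom = m[, 1], start = as.integer(m[, 2]),
         end = as.integer(m[, 3]), score = as.numeric(m[, 4]))
}

#' Write a long expression table as a wide TSV
#'
#' Columns are `gene_id` plus one `<plant>_<hat>` column per sample.
#'
#' @param expression Long tibble `gene_id`, `plant`, `time_hat`, `fpkm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  wide <- expression |>
    mutate(sample = paste0(.data$plant, "_", .data$time_hat)) |>
    select("gene_id", "sample", "fpkm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fpkm") |>
    arrange(.data$gene_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a wide FPKM table into long form
#'
#' @param path TSV with a `gene_id` column and one `<plant>_<hat>` column per
#'   sample.
#' @return Long tibble `gene_id`, `plant`, `time_hat`, `fpkm`.
#' @export
read_expression_table <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  wide |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample", values_to = "fpkm") |>
    tidyr::separate_wider_regex("sample",
                                patterns = c(plant = ".*", "_", time_hat = "[0-9]+")) |>
    mutate(time_hat = as.integer(.data$time_hat))
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write merged clusters as BED6
#'
#' Score column is the total weighted read count times ten, rounded.
#'
#' @param clusters Merged cluster tibble (see [merge_clusters()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  score <- if ("n_reads" %in% names(clusters)) {
    as.integer(round(clusters$n_reads * 10))
  } else 0L
  out <- tibble(chrom = clusters$chrom, start = clusters$start,
                end = clusters$end, name = clusters$cluster_id,
                score = score, strand = ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
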