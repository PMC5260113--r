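# Small-RNA preprocessing: non-coding-RNA removal by exact sequence match,
# length/mismatch/multi-mapping filters, and reads-per-million normalisation.

#' Remove reads matching a non-coding RNA filter set
#'
#' A read is removed iff its sequence is an exact substring of any filter
#' sequence on either strand (reverse-complement aware) — the sequence-level
#' reading of "perfectly maps to" a miRNA/rRNA/tRNA/snoRNA database entry.
#' Removal is by `read_id`: every alignment of a matched read is dropped.
#' With no filter set the operation is a pass-through with a warning. Reads
#' whose `sequence` is `NA` cannot match and are retained.
#'
#' @param reads Read tibble with `read_id` and `sequence` columns.
#' @param filter_seqs Named character vector of filter sequences (e.g. from
#'   [read_fasta()]), or `NULL`.
#' @return The retained reads.
#' @export
filter_ncrna <- function(reads, filter_seqs = NULL) {
  reads <- as_tibble(reads)
  if (is.null(filter_seqs) || length(filter_seqs) == 0) {
    warn("no ncRNA filter set supplied; reads passed through unfiltered")
    return(reads)
  }
  if (!"sequence" %in% names(reads)) {
    warn("reads carry no sequences; ncRNA filter is a pass-through")
    return(reads)
  }
  seqs <- unique(reads$sequence[!is.na(reads$sequence)])
  if (length(seqs) == 0) return(reads)
  seqs_norm <- toupper(chartr("Uu", "Tt", seqs))
  if (any(!grepl("^[ACGTN]+$", seqs_norm))) {
    bad <- seqs[which(!grepl("^[ACGTN]+$", seqs_norm))[1]]
    abort(sprintf("invalid nucleotide characters in read sequence '%s'", bad))
  }
  fwd <- toupper(chartr("Uu", "Tt", unname(filter_seqs)))
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
  haystack <- paste(c(fwd, rev), collapse = "\n")
  matched <- seqs[stringr::str_detect(haystack, stringr::fixed(seqs_norm))]
  drop_ids <- unique(reads$read_id[!is.na(reads$sequence) & reads$sequence %in% matched])
  reads |> filter(!(.data$read_id %in% drop_ids))
}

#' Filter alignments on length, mismatches and mapping multiplicity
#'
#' Default thresholds keep 18-30 nt reads with no mismatches and at most five
#' genomic mapping sites. Row order is preserved.
#'
#' @param reads Read tibble with `length`, `mismatches`, `n_sites`.
#' @param min_len,max_len Inclusive length bounds (nt).
#' @param max_mismatch Maximum mismatches.
#' @param max_sites Maximum mapping sites.
#' @return The retained reads.
#' @export
filter_alignments <- function(reads, min_len = 18L, max_len = 30L,
                              max_mismatch = 0L, max_sites = 5L) {
  as_tibble(reads) |>
    filter(.data$length >= min_len, .data$length <= max_len,
           .data$mismatches <= max_mismatch, .data$n_sites <= max_sites)
}

#' Reads-per-million normalisation
#'
#' @param count Read count (or vector of counts).
#' @param total_processed Library normalisation denominator (> 0).
#' @return `count * 1e6 / total_processed`.
#' @export
normalize_rpm <- function(count, total_processed) {
  if (length(total_processed) == 0 || any(total_processed <= 0)) {
    abort("total_processed must be > 0")
  }
  count * 1e6 / total_processed
}

# Internal: per-alignment counting weight. Fractional mode gives each
# alignment of a read with n mapping sites weight 1/n so a read never counts
# more than once; full mode counts every alignment as 1.
alignment_weights <- function(reads, weight_mode = c("fractional", "full")) {
  weight_mode <- match.arg(weight_mode)
  if (weight_mode == "fractional") 1 / reads$n_sites else rep(1, nrow(reads))
}

#' Preprocess small-RNA libraries
#'
#' Applies the ncRNA filter then the length/mismatch/multiplicity filters to
#' each library (a `plant` x `time_hat` combination) and computes the
#' normalisation denominator per library: the number of distinct retained
#' reads (`denominator = "post_filter"`, default) or of distinct input reads
#' (`"pre_filter"`).
#'
#' @param reads Read tibble covering one or more libraries (`plant`,
#'   `time_hat` columns).
#' @param filter_seqs Optional ncRNA filter sequences; omit to skip ncRNA
#'   filtering.
#' @inheritParams filter_alignments
#' @param denominator Which library size to normalise by.
#' @return A list of class `srna_libraries`: `reads` (retained alignments)
#'   and `totals` (tibble `plant`, `time_hat`, `total_processed`).
#' @export
preprocess_reads <- function(reads, filter_seqs = NULL, min_len = 18L,
                             max_len = 30L, max_mismatch = 0L, max_sites = 5L,
                             denominator = c("post_filter", "pre_filter")) {
  denominator <- match.arg(denominator)
  reads <- as_tibble(reads)
  pre_totals <- reads |>
    group_by(.data$plant, .data$time_hat) |>
    summarise(total_processed = n_distinct(.data$read_id), .groups = "drop")
  kept <- reads
  if (!is.null(filter_seqs)) kept <- filter_ncrna(kept, filter_seqs)
  kept <- filter_alignments(kept, min_len, max_len, max_mismatch, max_sites)
  totals <- if (denominator == "post_filter") {
    kept |>
      group_by(.data$plant, .data$time_hat) |>
      summarise(total_processed = n_distinct(.data$read_id), .groups = "drop")
  } else {
    pre_totals
  }
  structure(list(reads = kept, totals = totals), class = "srna_libraries")
}

#' @export
print.srna_libraries <- function(x, ...) {
  cat(sprintf("<srna_libraries> %d retained alignments across %d libraries\n",
              nrow(x$reads), nrow(x$totals)))
  print(x$totals)
  invisible(x)
}

#' Per-length RPM histogram of a library set
#'
#' Sums alignment weights per read length (18-30 nt) and library, normalised
#' to reads per million by each library's denominator. Lengths with no reads
#' appear with zero RPM.
#'
#' @param libraries An `srna_libraries` from [preprocess_reads()].
#' @param weight_mode Multi-mapping weight rule (see Details in
#'   [detect_clusters()]).
#' @return Tibble `plant`, `time_hat`, `length`, `rpm`.
#' @export
length_histogram <- function(libraries, weight_mode = c("fractional", "full")) {
  weight_mode <- match.arg(weight_mode)
  reads <- libraries$reads |> mutate(w = alignment_weights(libraries$reads, weight_mode))
  grid <- tidyr::expand_grid(libraries$totals[c("plant", "time_hat")],
                             length = 18:30)
  counts <- reads |>
    group_by(.data$plant, .data$time_hat, .data$length) |>
    summarise(w = sum(.data$w), .groups = "drop")
  grid |>
    left_join(counts, by = c("plant", "time_hat", "length")) |>
    left_join(libraries$totals, by = c("plant", "time_hat")) |>
    mutate(rpm = normalize_rpm(tidyr::replace_na(.data$w, 0), .data$total_processed)) |>
    select("plant", "time_hat", "length", "rpm")
}
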