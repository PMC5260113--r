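# Annotation model
#
# A gene annotation is a list of two tibbles:
#   genes:    gene_id, chrom, start, end, strand, transcript_id (representative)
#   features: gene_id, feature (exon/intron/cds/five_prime_utr/three_prime_utr),
#             chrom, start, end, strand
# plus an optional genome layout (chrom_sizes, centromeres). Coordinates are
# 0-based half-open. When a gene has several mRNAs the representative is the
# longest-spanning transcript, ties broken by the lexicographically smallest
# transcript id; introns are the gaps between its consecutive exons and UTRs
# are derived from the CDS extent in transcript orientation.

FEATURE_LEVELS <- c("five_prime_utr", "cds", "intron", "three_prime_utr")

new_annotation <- function(genes, features) {
  structure(list(genes = as_tibble(genes), features = as_tibble(features)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes, %d feature intervals\n",
              nrow(x$genes), nrow(x$features)))
  print(dplyr::count(x$features, .data$feature))
  invisible(x)
}

parse_gff3_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))
  m[, 2]
}

#' Read a GFF3 gene annotation
#'
#' Parses gene, mRNA and exon records (CDS optional) into a gene annotation.
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#' For multi-isoform genes the representative transcript is the one with the
#' longest genomic span (ties: smallest transcript id); introns are derived
#' from the gaps between its exons, and UTRs from its CDS when present.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_annotation`: list with tibbles `genes` and `features`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(body)
  fields <- stringr::str_split(lines[body], "\t")
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- line_no[which(nf != 9)[1]]
    abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns, found %d",
                  bad, nf[which(nf != 9)[1]]))
  }
  m <- do.call(rbind, fields)
  rec <- tibble(
    chrom = m[, 1], type = tolower(m[, 3]),
    start = suppressWarnings(as.integer(m[, 4])) - 1L,
    end = suppressWarnings(as.integer(m[, 5])),
    strand = m[, 7], attrs = m[, 9], line = line_no
  )
  if (anyNA(rec$start) || anyNA(rec$end)) {
    bad <- rec$line[which(is.na(rec$start) | is.na(rec$end))[1]]
    abort(sprintf("malformed GFF3 line %d: non-numeric coordinates", bad))
  }
  rec$id <- parse_gff3_attr(rec$attrs, "ID")
  rec$parent <- parse_gff3_attr(rec$attrs, "Parent")

  genes <- rec |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$id, chrom = .data$chrom, start = .data$start,
              end = .data$end, strand = .data$strand)
  mrnas <- rec |>
    filter(.data$type %in% c("mrna", "transcript")) |>
    transmute(transcript_id = .data$id, gene_id = .data$parent,
              start = .data$start, end = .data$end)
  parts <- rec |>
    filter(.data$type %in% c("exon", "cds")) |>
    transmute(type = .data$type, transcript_id = .data$parent,
              chrom = .data$chrom, start = .data$start, end = .data$end,
              strand = .data$strand, line = .data$line)

  # representative transcript: longest span, ties to smallest id
  reps <- mrnas |>
    mutate(span = .data$end - .data$start) |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$span), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", "transcript_id")
  genes <- left_join(genes, reps, by = "gene_id")

  rep_parts <- parts |> semi_join(reps, by = "transcript_id") |>
    left_join(reps, by = "transcript_id")

  # validate exons inside gene span
  chk <- rep_parts |> left_join(genes, by = "gene_id", suffix = c("", ".g"))
  bad <- chk$start < chk$start.g | chk$end > chk$end.g
  if (any(bad)) {
    abort(sprintf("GFF3 line %d: %s outside its gene span", chk$line[which(bad)[1]],
                  chk$type[which(bad)[1]]))
  }

  features <- rep_parts |>
    split(rep_parts$gene_id) |>
    purrr::map(derive_gene_features) |>
    bind_rows()
  if (nrow(features) == 0) {
    features <- tibble(gene_id = character(), feature = character(),
                       chrom = character(), start = integer(), end = integer(),
                       strand = character())
  }
  new_annotation(genes, features |> arrange(.data$chrom, .data$start))
}

# Internal: exon/CDS part records of one representative transcript ->
# exon/intron/cds/UTR feature tibble.
derive_gene_features <- function(parts) {
  gene_id <- parts$gene_id[1]
  chrom <- parts$chrom[1]
  strand <- parts$strand[1]
  exons <- parts |> filter(.data$type == "exon") |> arrange(.data$start)
  cds <- parts |> filter(.data$type == "cds") |> arrange(.data$start)
  out <- list()
  if (nrow(exons) > 0) {
    out$exon <- tibble(feature = "exon", start = exons$start, end = exons$end)
    if (nrow(exons) > 1) {
      istart <- exons$end[-nrow(exons)]
      iend <- exons$start[-1]
      keep <- iend > istart
      if (any(keep)) {
        out$intron <- tibble(feature = "intron", start = istart[keep], end = iend[keep])
      }
    }
  }
  if (nrow(cds) > 0) {
    out$cds <- tibble(feature = "cds", start = cds$start, end = cds$end)
    # CDS must lie within exons
    if (nrow(exons) > 0) {
      cov <- purrr::map2_dbl(cds$start, cds$end,
                             function(s, e) sum(bp_overlap(exons$start, exons$end, s, e)))
      if (any(cov < cds$end - cds$start)) {
        abort(sprintf("gene %s: CDS not contained in exons", gene_id))
      }
      utr <- derive_utr_intervals(exons, min(cds$start), max(cds$end), strand)
      out <- c(out, utr)
    }
  }
  bind_rows(out) |>
    mutate(gene_id = gene_id, chrom = chrom, strand = strand,
           .before = "feature")
}

# Internal: exonic sequence outside [cds_start, cds_end) split into 5'/3' UTR
# pieces, strand-aware. Returns list of tibbles keyed by label.
derive_utr_intervals <- function(exons, cds_start, cds_end, strand) {
  clip <- function(lo, hi) {
    s <- pmax(exons$start, lo); e <- pmin(exons$end, hi)
    keep <- e > s
    tibble(start = s[keep], end = e[keep])
  }
  left <- clip(-Inf, cds_start)
  right <- clip(cds_end, Inf)
  if (identical(strand, "-")) {
    five <- right; three <- left
  } else {
    five <- left; three <- right
  }
  out <- list()
  if (nrow(five) > 0) out$five <- five |> mutate(feature = "five_prime_utr", .before = 1)
  if (nrow(three) > 0) out$three <- three |> mutate(feature = "three_prime_utr", .before = 1)
  out
}

#' Derive UTR features for one gene from exon and CDS intervals
#'
#' Exonic sequence upstream of the first CDS base (in transcript orientation)
#' is labelled `five_prime_utr`, and downstream of the last CDS base
#' `three_prime_utr`. Strand-aware.
#'
#' @param exons Tibble of exon intervals (`start`, `end`), one transcript.
#' @param cds Tibble of CDS intervals (`start`, `end`).
#' @param strand `"+"` or `"-"`.
#' @return Tibble with columns `feature`, `start`, `end`.
#' @export
derive_utrs <- function(exons, cds, strand = "+") {
  exons <- as_tibble(exons) |> arrange(.data$start)
  cds <- as_tibble(cds)
  if (nrow(cds) == 0) abort("derive_utrs: CDS records required")
  cov <- purrr::map2_dbl(cds$start, cds$end,
                         function(s, e) sum(bp_overlap(exons$start, exons$end, s, e)))
  if (any(cov < cds$end - cds$start)) abort("derive_utrs: CDS not contained in exons")
  out <- derive_utr_intervals(exons, min(cds$start), max(cds$end), strand)
  res <- bind_rows(out)
  if (nrow(res) == 0) tibble(feature = character(), start = integer(), end = integer())
  else select(res, "feature", "start", "end")
}

#' Write a gene annotation to GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR records (one mRNA per gene — the
#' representative transcript), converting back to 1-based inclusive
#' coordinates. Output is deterministic: genes ordered by chromosome then
#' start.
#'
#' @param annotation A `gene_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- annotation$genes |> arrange(.data$chrom, .data$start, .data$gene_id)
  feats <- annotation$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  gff_type <- c(exon = "exon", cds = "CDS", intron = NA,
                five_prime_utr = "five_prime_UTR", three_prime_utr = "three_prime_UTR")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- g$transcript_id %||% paste0(g$gene_id, ".1")
    if (is.na(tid)) tid <- paste0(g$gene_id, ".1")
    writeLines(sprintf("%s\tsirtron\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\tsirtron\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, tid, g$gene_id), con)
    fs <- feats |> filter(.data$gene_id == g$gene_id, .data$feature != "intron") |>
      arrange(.data$start, .data$feature)
    if (nrow(fs) > 0) {
      phase <- if_else(fs$feature == "cds", "0", ".")
      writeLines(sprintf("%s\tsirtron\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
                         fs$chrom, gff_type[fs$feature], fs$start + 1L, fs$end,
                         fs$strand, phase, tid), con)
    }
  }
  invisible(path)
}

#' Read a genome layout (chromosome sizes and centromeres)
#'
#' @param chrom_sizes_path 2-column TSV: chrom, length (bp). No header.
#' @param centromeres_path 3-column TSV: chrom, start, end (0-based
#'   half-open). No header. Optional.
#' @return A list with tibbles `chrom_sizes` (`chrom`, `length`) and
#'   `centromeres` (`chrom`, `start`, `end`).
#' @export
read_genome_layout <- function(chrom_sizes_path, centromeres_path = NULL) {
  sizes <- readr::read_tsv(chrom_sizes_path, col_names = c("chrom", "length"),
                           col_types = "ci", progress = FALSE)
  cents <- if (!is.null(centromeres_path)) {
    readr::read_tsv(centromeres_path, col_names = c("chrom", "start", "end"),
                    col_types = "cii", progress = FALSE)
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }
  layout <- list(chrom_sizes = sizes, centromeres = cents)
  validate_layout(layout)
}

validate_layout <- function(layout) {
  if (nrow(layout$centromeres) > 0) {
    chk <- left_join(layout$centromeres, layout$chrom_sizes, by = "chrom")
    if (anyNA(chk$length) || any(chk$start < 0 | chk$end > chk$length)) {
      abort("centromere interval outside [0, chromosome length)")
    }
  }
  layout
}

#' Write a genome layout to TSV files
#'
#' @param layout A genome layout (see [read_genome_layout()]).
#' @param chrom_sizes_path,centromeres_path Output paths.
#' @return `chrom_sizes_path`, invisibly.
#' @export
write_genome_layout <- function(layout, chrom_sizes_path, centromeres_path = NULL) {
  readr::write_tsv(layout$chrom_sizes, chrom_sizes_path, col_names = FALSE)
  if (!is.null(centromeres_path)) {
    readr::write_tsv(layout$centromeres, centromeres_path, col_names = FALSE)
  }
  invisible(chrom_sizes_path)
}
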