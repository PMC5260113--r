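# Genomic intervals are plain tibbles with columns chrom, start, end (and
# optionally strand). Coordinates are 0-based half-open throughout the package;
# GFF3 (1-based inclusive) and BED (0-based half-open) are converted at the
# file boundary.

#' Validate an interval tibble
#'
#' Checks that `x` has `chrom`, `start` and `end` columns and that every
#' interval satisfies `0 <= start < end`.
#'
#' @param x A data frame of intervals.
#' @param what Label used in error messages.
#' @return `x`, invisibly coerced to a tibble.
#' @export
validate_intervals <- function(x, what = "intervals") {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s must have columns %s; missing: %s", what,
                  paste(req, collapse = ", "), paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$start >= x$end)) {
    bad <- which(x$start < 0 | x$start >= x$end)[1]
    abort(sprintf("%s: invalid interval at row %d (start=%s, end=%s); need 0 <= start < end",
                  what, bad, x$start[bad], x$end[bad]))
  }
  x
}

# Internal: convert 0-based half-open interval tibble to GRanges (1-based).
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Internal: hits between two 0-based interval tibbles (ignores strand).
overlap_hits <- function(x, y, minoverlap = 1L) {
  h <- GenomicRanges::findOverlaps(as_granges0(x), as_granges0(y),
                                   minoverlap = minoverlap, ignore.strand = TRUE)
  tibble(x = S4Vectors::queryHits(h), y = S4Vectors::subjectHits(h))
}

#' Find intervals overlapping a query
#'
#' Returns the rows of `intervals` that overlap `query` by at least one base
#' pair. Both arguments use 0-based half-open coordinates, so intervals that
#' merely touch (e.g. `[0,50)` vs `[50,60)`) do not overlap.
#'
#' @param intervals A tibble with `chrom`, `start`, `end`.
#' @param query A one-row data frame (or list) with `chrom`, `start`, `end`.
#' @return The overlapping rows of `intervals`, as a tibble.
#' @examples
#' ivs <- tibble::tibble(chrom = "chr1", start = c(0, 55), end = c(50, 70))
#' overlap_query(ivs, list(chrom = "chr1", start = 50, end = 60))
#' @export
overlap_query <- function(intervals, query) {
  intervals <- validate_intervals(intervals)
  query <- as_tibble(query[c("chrom", "start", "end")])
  query <- validate_intervals(query, "query")
  if (nrow(intervals) == 0) return(intervals)
  hits <- overlap_hits(intervals, query)
  intervals[sort(unique(hits$x)), ]
}

# Internal: bp overlap between [s1,e1) and [s2,e2) (vectorised).
bp_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Internal: merge overlapping intervals per chromosome (transitive union).
# Returns the reduced intervals plus, for each input row, the index of the
# merged interval it fell into.
reduce_intervals <- function(x) {
  gr <- as_granges0(x)
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  member_of <- integer(nrow(x))
  member_of[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  merged <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
  list(merged = merged, member_of = member_of)
}
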