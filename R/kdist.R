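# k-dist parameter selection. For every aligned read the distance (bp,
# between leftmost mapped positions) to its k-th nearest neighbouring read is
# computed; the sorted-descending k-dist curve shows a steep valley whose
# location is taken as the DBSCAN epsilon, unless the curve is uniform.

#' k-th nearest-neighbour distances of 1-D positions
#'
#' For each position, the absolute distance to its k-th nearest *other*
#' position (ties broken by distance only). Computed with a sorted two-sided
#' merge in O(n k) rather than all-pairs.
#'
#' @param positions Numeric vector of read start coordinates on one
#'   chromosome.
#' @param k Neighbour rank (>= 1).
#' @return Numeric vector of k-dist values, sorted in descending order, of
#'   class `kdist_profile` with attributes `k`. Fewer than `k + 1` positions
#'   yield an empty profile with a warning.
#' @export
kdist <- function(positions, k = 30L) {
  n <- length(positions)
  if (n <= k) {
    warn(sprintf("need more than k = %d positions for a k-dist profile (got %d)", k, n))
    return(structure(numeric(0), k = k, class = "kdist_profile"))
  }
  p <- sort(as.numeric(positions))
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- i - 1L; hi <- i + 1L
    d <- 0
    for (step in seq_len(k)) {
      dl <- if (lo >= 1L) p[i] - p[lo] else Inf
      dr <- if (hi <= n) p[hi] - p[i] else Inf
      if (dl <= dr) { d <- dl; lo <- lo - 1L } else { d <- dr; hi <- hi + 1L }
    }
    out[i] <- d
  }
  structure(sort(out, decreasing = TRUE), k = k, class = "kdist_profile")
}

#' Compute a k-dist profile over a library
#'
#' Runs [kdist()] per chromosome on read start coordinates and pools the
#' values into one descending profile.
#'
#' @param reads Read tibble with `chrom` and `start`.
#' @param k Neighbour rank.
#' @return A `kdist_profile` (sorted descending).
#' @export
kdist_profile <- function(reads, k = 30L) {
  vals <- reads |>
    split(~chrom) |>
    purrr::map(function(d) suppressWarnings(as.numeric(kdist(d$start, k)))) |>
    unlist(use.names = FALSE)
  structure(sort(vals, decreasing = TRUE), k = k, class = "kdist_profile")
}

#' Select DBSCAN epsilon from a k-dist profile
#'
#' Locates the valley of the sorted-descending k-dist curve as the point of
#' maximum perpendicular distance to the chord joining the curve's endpoints
#' (the knee heuristic); ties go to the smallest index, i.e. the largest
#' k-dist. A constant profile has no valley and raises an error; a knee at an
#' endpoint-adjacent index, or a near-linear curve whose maximum chord
#' distance is negligible against the value range, is flagged low-confidence.
#'
#' @param profile A `kdist_profile` (or any non-increasing numeric vector).
#' @return The selected epsilon (bp), with attributes `index` (knee position)
#'   and `low_confidence`.
#' @export
select_epsilon <- function(profile) {
  v <- as.numeric(profile)
  n <- length(v)
  if (n == 0) abort("empty k-dist profile")
  if (diff(range(v)) == 0) abort("no valley: k-dist is uniform")
  x <- seq_len(n)
  # perpendicular distance of each point to the chord (1, v1) -- (n, vn)
  dx <- n - 1; dy <- v[n] - v[1]
  dist <- abs(dy * (x - 1) - dx * (v - v[1])) / sqrt(dx^2 + dy^2)
  idx <- which.max(dist)
  # a near-linear curve has no real knee: the argmax is then numerically
  # arbitrary and the selection unreliable
  low_confidence <- idx <= 2L || idx >= n - 1L ||
    max(dist) < 0.01 * diff(range(v))
  structure(v[idx], index = idx, low_confidence = low_confidence,
            class = "selected_epsilon")
}

#' @export
print.selected_epsilon <- function(x, ...) {
  cat(sprintf("epsilon = %g bp (knee at index %d of the k-dist curve%s)\n",
              as.numeric(x), attr(x, "index"),
              if (isTRUE(attr(x, "low_confidence"))) "; low confidence" else ""))
  invisible(x)
}
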