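# Independent brute-force oracles the implementation is checked against.

# all-pairs k-th nearest neighbour distance (excluding self)
kdist_bruteforce <- function(positions, k) {
  vals <- vapply(seq_along(positions), function(i) {
    d <- sort(abs(positions[-i] - positions[i]))
    d[k]
  }, numeric(1))
  sort(vals, decreasing = TRUE)
}

# textbook DBSCAN by breadth-first expansion over the full distance matrix;
# border points claimed by the leftmost reaching core point
dbscan_bruteforce <- function(positions, epsilon, minpts) {
  n <- length(positions)
  if (n == 0) return(integer(0))
  d <- abs(outer(positions, positions, "-"))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= epsilon))
  core <- vapply(neigh, length, integer(1)) >= minpts
  cl <- integer(n)
  cid <- 0L
  for (i in order(positions)) {
    if (!core[i] || cl[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      if (cl[j] != 0L) next
      cl[j] <- cid
      if (core[j]) queue <- c(queue, neigh[[j]][cl[neigh[[j]]] == 0L & core[neigh[[j]]]])
    }
  }
  # border points: leftmost core within epsilon
  ord_core <- order(positions)
  ord_core <- ord_core[core[ord_core]]
  for (i in which(!core)) {
    reach <- ord_core[abs(positions[ord_core] - positions[i]) <= epsilon]
    if (length(reach) > 0) cl[i] <- cl[reach[1]]
  }
  cl
}

# canonical form of a clustering: list of member index sets, ordered by
# leftmost member, so labels do not matter in comparisons
clustering_sets <- function(positions, labels) {
  ids <- setdiff(unique(labels), 0L)
  sets <- lapply(ids, function(id) sort(which(labels == id)))
  sets[order(vapply(sets, function(s) min(positions[s]), numeric(1)))]
}

# sweep-line union of intervals on one chromosome
merge_sweepline <- function(start, end) {
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  ms <- s[1]; me <- e[1]; out_s <- c(); out_e <- c()
  for (i in seq_along(s)[-1]) {
    if (s[i] > me) { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
    else me <- max(me, e[i])
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# exhaustive max-perpendicular-distance knee over all indices
knee_bruteforce <- function(v) {
  n <- length(v); x <- seq_len(n)
  chord <- function(i) {
    num <- abs((v[n] - v[1]) * (x[i] - 1) - (n - 1) * (v[i] - v[1]))
    num / sqrt((n - 1)^2 + (v[n] - v[1])^2)
  }
  d <- vapply(x, chord, numeric(1))
  which.max(d)
}
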