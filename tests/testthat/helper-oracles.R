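# Independent oracles used to validate the main algorithms.

# Exhaustive Dollo oracle: minimize losses over all admissible gain
# placements (ancestors of the MRCA of presences, or the root under the
# root-presence assumption) and all subsets of loss branches. A subset is
# valid when its subtrees are pairwise disjoint, contain no presence, and
# cover every observed absence below the gain.
dollo_oracle <- function(tree, x, root_presence = FALSE) {
  info <- cpevol:::tree_index(tree)
  ones <- names(x)[!is.na(x) & x == 1]
  zeros <- names(x)[!is.na(x) & x == 0]
  if (!length(ones) && !root_presence) return(0L)
  gains <- if (root_presence) info$root else {
    g <- cpevol:::mrca_node(info, ones)
    out <- integer(0)
    while (!is.na(g)) { out <- c(out, g); g <- info$parent[g] }
    out
  }
  best <- Inf
  nodes <- seq_len(info$n_nodes)
  for (gain in gains) {
    belowg <- function(nd) {
      p <- nd
      while (!is.na(p)) { if (p == gain) return(TRUE); p <- info$parent[p] }
      FALSE
    }
    cand <- nodes[vapply(nodes, function(nd)
      nd != gain && belowg(nd) && !any(ones %in% info$below[[nd]]),
      logical(1))]
    zneed <- zeros[zeros %in% info$below[[gain]]]
    if (!length(zneed)) { best <- min(best, 0); next }
    found <- FALSE
    for (k in seq_len(min(length(cand), length(zneed)))) {
      for (ss in utils::combn(cand, k, simplify = FALSE)) {
        tips <- unlist(info$below[ss])
        if (anyDuplicated(tips)) next
        if (all(zneed %in% tips)) { found <- TRUE; break }
      }
      if (found) { best <- min(best, k); break }
    }
  }
  as.integer(best)
}

# Quadratic repeat oracle: all maximal exact repeats >= min_len found by
# scanning every diagonal of the (A, B) comparison matrix with run-length
# encoding; maximality holds at run boundaries by construction.
diagonal_pairs <- function(A, B, min_len, self) {
  va <- strsplit(A, "")[[1]]
  vb <- strsplit(B, "")[[1]]
  na <- length(va); nb <- length(vb)
  rows <- list()
  dmin <- if (self) 1L else -(na - 1L)
  for (d in dmin:(nb - 1L)) {
    # positions i in A matched to i + d in B
    i1 <- max(1L, 1L - d); i2 <- min(na, nb - d)
    if (i2 - i1 + 1L < min_len) next
    ii <- i1:i2
    eq <- va[ii] == vb[ii + d] & va[ii] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      p <- ii[starts[h]] - 1L          # 0-based start in A
      q <- p + d                        # 0-based start in B
      rows[[length(rows) + 1L]] <- c(p = p, q = q, len = r$lengths[h])
    }
  }
  if (!length(rows)) return(data.frame(p = integer(), q = integer(),
                                       len = integer()))
  as.data.frame(do.call(rbind, rows))
}

repeat_oracle <- function(S, min_len = 30L) {
  L <- nchar(S)
  dir <- diagonal_pairs(S, S, min_len, self = TRUE)
  if (nrow(dir)) dir <- data.frame(type = "direct", start1 = dir$p,
                                   start2 = dir$q, length = dir$len)
  R <- cpevol:::revcomp(S)
  inv <- diagonal_pairs(S, R, min_len, self = FALSE)
  if (nrow(inv)) {
    s2 <- L - inv$q - inv$len
    inv <- data.frame(type = "inverted", start1 = inv$p, start2 = s2,
                      length = inv$len)
    sw <- inv$start2 < inv$start1
    tmp <- inv$start1[sw]; inv$start1[sw] <- inv$start2[sw]; inv$start2[sw] <- tmp
    inv <- inv[inv$start1 != inv$start2, , drop = FALSE]
    inv <- inv[!duplicated(inv), , drop = FALSE]
  }
  out <- rbind(if (nrow(dir)) dir, if (nrow(inv)) inv)
  if (is.null(out)) out <- data.frame(type = character(), start1 = integer(),
                                      start2 = integer(), length = integer())
  out[order(out$type, out$start1, out$start2), , drop = FALSE]
}

# Brute-force minimal removals for two-arc segregation of a circular
# binary sequence (subset enumeration, small n only).
segregation_oracle <- function(x) {
  n <- length(x)
  for (k in 0:n) {
    for (ss in utils::combn(n, k, simplify = FALSE)) {
      y <- if (k) x[-ss] else x
      if (!length(y)) return(k)
      r <- rle(y)
      v <- r$values
      ok <- length(v) <= 2L || (length(v) == 3L && v[1] == v[3])
      if (ok) return(k)
    }
  }
  n
}
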