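## Exact signed reversal distance via the Hannenhalli-Pevzner breakpoint
## graph (cycles, unoriented components, hurdles, fortress), a
## breadth-first-search oracle for validation, pairwise distance matrices
## and nonnegative least-squares branch-length fitting.

#' Signed reversal distance between two gene orders
#'
#' Exact minimum number of signed reversals transforming \code{a} into
#' \code{b}, computed from the breakpoint graph:
#' \deqn{d = n + 1 - c + h + f}
#' with \eqn{c} the number of cycles, \eqn{h} the number of hurdles and
#' \eqn{f} the fortress indicator, under the standard capping of the linear
#' permutation. Circular orders are first reduced to a canonical linear
#' representative by cutting at an anchor gene fixed at +1 in position 1
#' (reflecting the whole order if needed), which makes the result invariant
#' under rotation and reflection.
#'
#' @param a,b \code{cp_gene_order} objects over the identical gene set, one
#'   copy per gene.
#' @return object of class \code{cp_revdist}: list with \code{n} (genes
#'   compared), \code{breakpoints}, \code{cycles}, \code{hurdles},
#'   \code{fortress}, \code{distance}.
#' @export
reversal_distance <- function(a, b) {
  perm <- relative_signed_permutation(a, b)
  stats <- hp_distance(perm)
  structure(stats, class = "cp_revdist")
}

#' @export
print.cp_revdist <- function(x, ...) {
  cat(sprintf("<cp_revdist> d = %d (n = %d, b = %d, c = %d, h = %d, f = %d)\n",
              x$distance, x$n, x$breakpoints, x$cycles, x$hurdles, x$fortress))
  invisible(x)
}

# Express a as a signed permutation relative to b (identity), after
# canonical linearization of circular orders: both are cut at the
# lexicographically smallest shared gene, fixed at +1, and the anchor is
# removed (it plays the role of the linear frame).
relative_signed_permutation <- function(a, b) {
  ga <- dedup_order(a); gb <- dedup_order(b)
  if (anyDuplicated(ga$symbol) || anyDuplicated(gb$symbol))
    stop("gene orders must contain one copy per gene")
  sd <- c(setdiff(ga$symbol, gb$symbol), setdiff(gb$symbol, ga$symbol))
  if (length(sd))
    stop("gene sets differ; symmetric difference: ", paste(sd, collapse = ", "))
  circ <- a$topology == "circular" && b$topology == "circular"
  if (circ) {
    anchor <- min(ga$symbol)
    ga <- canonical_rotation(ga, anchor)
    gb <- canonical_rotation(gb, anchor)
    # drop the anchor: it frames the linearized permutation
    ga <- ga[-1L, , drop = FALSE]
    gb <- gb[-1L, , drop = FALSE]
  }
  id <- stats::setNames(seq_len(nrow(gb)), gb$symbol)
  sg <- stats::setNames(gb$sign, gb$symbol)
  unname(id[ga$symbol]) * ga$sign * unname(sg[ga$symbol])
}

# rotate a circular order so `anchor` is first with sign +1 (reflect the
# whole order, i.e. reverse and negate, if the anchor is on the - strand)
canonical_rotation <- function(g, anchor) {
  i <- which(g$symbol == anchor)[1]
  n <- nrow(g)
  g <- g[((seq_len(n) + i - 2L) %% n) + 1L, , drop = FALSE]
  if (g$sign[1] < 0) {
    g <- g[rev(seq_len(n)), , drop = FALSE]
    g$sign <- -g$sign
    g <- g[c(n, seq_len(n - 1L)), , drop = FALSE]  # keep anchor first
  }
  rownames(g) <- NULL
  g
}

#' Hannenhalli-Pevzner statistics of a signed permutation
#'
#' @param perm signed permutation of 1..n (integer vector, target identity).
#' @return list: n, breakpoints, cycles, hurdles, fortress, distance.
#' @export
hp_distance <- function(perm) {
  n <- length(perm)
  if (n == 0L)
    return(list(n = 0L, breakpoints = 0L, cycles = 0L, hurdles = 0L,
                fortress = 0L, distance = 0L))
  stopifnot(setequal(abs(perm), seq_len(n)))
  # unsigned doubling with frame 0 .. 2n+1
  u <- integer(2L * n + 2L)
  u[1] <- 0L
  for (i in seq_len(n)) {
    x <- perm[i]
    u[2L * i] <- if (x > 0) 2L * x - 1L else 2L * abs(x)
    u[2L * i + 1L] <- if (x > 0) 2L * x else 2L * abs(x) - 1L
  }
  u[2L * n + 2L] <- 2L * n + 1L
  pos <- integer(2L * n + 2L)      # pos[v+1] = 0-based position of value v
  pos[u + 1L] <- seq_along(u) - 1L

  # breakpoints: black edge (positions 2i, 2i+1) is an adjacency iff the
  # gray partner of its left endpoint is its right endpoint
  m <- n + 1L                      # number of black (= gray) edges
  gray_p <- integer(m); gray_q <- integer(m)
  for (i in seq_len(m)) {          # gray edge joins values 2i-2 and 2i-1
    p <- pos[2L * i - 1L]; q <- pos[2L * i]
    gray_p[i] <- min(p, q); gray_q[i] <- max(p, q)
  }
  adjacency <- gray_q - gray_p == 1L & (gray_p %% 2L) == 0L
  breakpoints <- sum(!adjacency)

  # cycles: walk alternating black/gray edges over positions
  cyc_id <- integer(2L * n + 2L)   # per position, 1-based cycle id
  n_cyc <- 0L
  for (s in seq_len(2L * n + 2L)) {
    if (cyc_id[s] != 0L) next
    n_cyc <- n_cyc + 1L
    p <- s - 1L                    # 0-based position
    repeat {
      cyc_id[p + 1L] <- n_cyc
      # black edge: positions 2k <-> 2k+1
      p2 <- if (p %% 2L == 0L) p + 1L else p - 1L
      cyc_id[p2 + 1L] <- n_cyc
      # gray edge from value at p2
      v <- u[p2 + 1L]
      w <- if (v %% 2L == 0L) v + 1L else v - 1L
      p <- pos[w + 1L]
      if (cyc_id[p + 1L] != 0L) break
    }
  }
  cycles <- n_cyc

  # gray edge i belongs to the cycle of its endpoints; trivial cycles
  # (adjacencies) are excluded from component analysis
  edge_cyc <- cyc_id[gray_p + 1L]
  nontrivial <- !adjacency
  # an edge is oriented iff its endpoints' positions have unequal parity
  # offsets after pairing, i.e. (q - p) is even
  oriented_edge <- ((gray_q - gray_p) %% 2L) == 0L

  comp <- hp_components(gray_p[nontrivial], gray_q[nontrivial],
                        edge_cyc[nontrivial], oriented_edge[nontrivial])
  unor <- comp[!comp$oriented, , drop = FALSE]
  hset <- hp_hurdles(unor)
  h <- length(hset$hurdles)
  f <- 0L
  if (h > 0L && h %% 2L == 1L && all(hset$super[hset$hurdles])) f <- 1L
  d <- n + 1L - cycles + h + f
  list(n = n, breakpoints = as.integer(breakpoints),
       cycles = as.integer(cycles), hurdles = as.integer(h),
       fortress = as.integer(f), distance = as.integer(d))
}

# connected components of the interleaving graph over cycles.
# returns data.frame(comp, lo, hi, oriented) per component
hp_components <- function(p, q, cyc, oriented) {
  if (!length(p))
    return(data.frame(comp = integer(), lo = integer(), hi = integer(),
                      oriented = logical()))
  ids <- sort(unique(cyc))
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[rx] <<- ry
  }
  key <- match(cyc, ids)
  # sweep: stack-free O(m^2) interleaving test (m is small: <= n+1)
  mle <- length(p)
  for (i in seq_len(mle - 1L)) for (j in (i + 1L):mle) {
    if ((p[i] < p[j] && p[j] < q[i] && q[i] < q[j]) ||
        (p[j] < p[i] && p[i] < q[j] && q[j] < q[i]))
      union_(key[i], key[j])
  }
  root <- vapply(key, find, integer(1))
  comp_ids <- unique(root)
  out <- lapply(comp_ids, function(r) {
    sel <- root == r
    data.frame(comp = r, lo = min(p[sel]), hi = max(q[sel]),
               oriented = any(oriented[sel]))
  })
  do.call(rbind, out)
}

# hurdles among unoriented components: minimal components (span containing
# no other unoriented component) plus the greatest component if its span
# contains all other unoriented components. Super-hurdles are hurdles whose
# deletion would turn a protecting non-hurdle component into a hurdle.
hp_hurdles <- function(unor) {
  k <- nrow(unor)
  if (k == 0L) return(list(hurdles = integer(0), super = logical(0)))
  hurdle_set <- function(lo, hi) {
    kk <- length(lo)
    if (kk == 0L) return(integer(0))
    contains <- function(i, j)            # span i strictly contains span j
      lo[i] <= lo[j] && hi[i] >= hi[j] && !(lo[i] == lo[j] && hi[i] == hi[j])
    minimal <- vapply(seq_len(kk), function(i)
      !any(vapply(seq_len(kk), function(j) i != j && contains(i, j),
                  logical(1))), logical(1))
    hs <- which(minimal)
    if (kk > 1L) {
      great <- which(vapply(seq_len(kk), function(i)
        all(vapply(seq_len(kk), function(j)
          i == j || contains(i, j), logical(1))), logical(1)))
      hs <- sort(unique(c(hs, great)))
    }
    hs
  }
  hs <- hurdle_set(unor$lo, unor$hi)
  super <- logical(k)
  for (hh in hs) {
    rest <- setdiff(seq_len(k), hh)
    hs2 <- hurdle_set(unor$lo[rest], unor$hi[rest])
    # deletion of a hurdle normally lowers the count; if it does not, a
    # protected non-hurdle became a hurdle and hh is a super-hurdle
    super[hh] <- length(hs2) >= length(hs)
  }
  list(hurdles = hs, super = super)
}

#' Brute-force reversal distance by breadth-first search
#'
#' Independent oracle: exact distance found by breadth-first search over all
#' signed permutations reachable from the identity, feasible for
#' \code{n <= n_max}. Distance tables are cached per n within a session.
#'
#' @param a,b \code{cp_gene_order} objects (or \code{a} an integer signed
#'   permutation and \code{b} missing).
#' @param n_max refusal threshold (default 7).
#' @return integer distance.
#' @export
brute_force_distance <- function(a, b, n_max = 7L) {
  perm <- if (inherits(a, "cp_gene_order")) relative_signed_permutation(a, b)
          else as.integer(a)
  n <- length(perm)
  if (n == 0L) return(0L)
  if (n > n_max) stop("brute_force_distance: n = ", n, " exceeds n_max = ", n_max)
  tab <- bfs_distance_table(n)
  key <- encode_signed_perm(perm)
  d <- tab$dist[match(key, tab$key)]
  if (is.na(d)) stop("state not reached in BFS (internal error)")
  as.integer(d)
}

# encode a signed permutation of 1..n as a single number base 2n
encode_signed_perm <- function(perm) {
  n <- length(perm)
  code <- ifelse(perm > 0, perm - 1L, n - perm - 1L)  # 0..2n-1
  sum(code * (2 * n)^(seq_len(n) - 1))
}

.bfs_cache <- new.env(parent = emptyenv())

# full BFS from the identity over the signed reversal graph for size n;
# returns list(key = sorted numeric keys, dist = integer distances)
bfs_distance_table <- function(n) {
  nm <- as.character(n)
  if (!is.null(.bfs_cache[[nm]])) return(.bfs_cache[[nm]])
  revs <- which(upper.tri(matrix(TRUE, n, n), diag = TRUE), arr.ind = TRUE)
  base <- (2 * n)^(seq_len(n) - 1)
  encode_mat <- function(M) {   # rows = states
    code <- ifelse(M > 0, M - 1L, n - M - 1L)
    as.vector(code %*% base)
  }
  frontier <- matrix(seq_len(n), nrow = 1L)
  keys <- encode_mat(frontier)
  dist <- c(0L)
  visited <- keys
  depth <- 0L
  while (nrow(frontier) > 0L) {
    depth <- depth + 1L
    nxt <- vector("list", nrow(revs))
    for (r in seq_len(nrow(revs))) {
      i <- revs[r, 1]; j <- revs[r, 2]
      M <- frontier
      M[, i:j] <- -M[, j:i, drop = FALSE]
      nxt[[r]] <- M
    }
    cand <- do.call(rbind, nxt)
    ck <- encode_mat(cand)
    new <- !duplicated(ck) & !(ck %in% visited)
    if (!any(new)) break
    frontier <- cand[new, , drop = FALSE]
    ck <- ck[new]
    visited <- c(visited, ck)
    keys <- c(keys, ck)
    dist <- c(dist, rep(depth, length(ck)))
  }
  res <- list(key = keys, dist = dist)
  .bfs_cache[[nm]] <- res
  res
}

#' Pairwise reversal distance matrix
#'
#' @param orders list of \code{cp_gene_order} reduced to a shared gene set.
#' @param gene_set optional character vector restricting to a catalog before
#'   computing (each order is filtered and deduplicated).
#' @return object of class \code{cp_distmat}: symmetric integer matrix with
#'   taxon dimnames.
#' @export
distance_matrix <- function(orders, gene_set = NULL) {
  if (length(orders) < 2L) stop("need at least two gene orders")
  if (!is.null(gene_set)) {
    orders <- lapply(orders, function(o) {
      g <- dedup_order(o)
      g <- g[g$symbol %in% gene_set, , drop = FALSE]
      structure(list(taxon_id = o$taxon_id, genes = g, topology = o$topology),
                class = "cp_gene_order")
    })
  }
  taxa <- vapply(orders, `[[`, character(1), "taxon_id")
  k <- length(orders)
  m <- matrix(0L, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- tryCatch(reversal_distance(orders[[i]], orders[[j]])$distance,
                  error = function(e) NA_integer_)
    m[i, j] <- m[j, i] <- d
  }
  structure(m, class = c("cp_distmat", class(m)))
}

#' Fit additive branch lengths to a distance matrix on a fixed tree
#'
#' Nonnegative least-squares fit of per-branch lengths so that path sums
#' between leaves approximate the pairwise reversal distances. This is a
#' distance-based approximation to rearrangement branch lengths (no
#' ancestral gene orders are reconstructed).
#'
#' @param dm matrix from [distance_matrix()] (or any symmetric matrix with
#'   taxon dimnames).
#' @param tree rooted \code{phylo} tree whose tip labels are contained in
#'   the matrix taxa.
#' @return list: \code{tree} (phylo with fitted \code{edge.length}),
#'   \code{lengths} (per edge, named by child node), \code{residual}
#'   (sum of squared differences).
#' @export
fit_branch_lengths <- function(dm, tree) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(dm)))
    stop("tree tips missing from distance matrix: ",
         paste(setdiff(tips, rownames(dm)), collapse = ", "))
  dm <- dm[tips, tips]
  n <- length(tips)
  ne <- nrow(tree$edge)
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), ne)
  dvec <- numeric(ncol(pairs))
  paths <- ape::nodepath(tree)
  for (kk in seq_len(ncol(pairs))) {
    i <- pairs[1, kk]; j <- pairs[2, kk]
    pth <- intersect_path(tree, i, j)
    A[kk, pth] <- 1
    dvec[kk] <- dm[i, j]
  }
  fit <- pracma::lsqnonneg(A, dvec)
  lens <- fit$x
  child <- tree$edge[, 2]
  labels <- ifelse(child <= n, tips[child], paste0("node", child))
  tree$edge.length <- lens
  list(tree = tree, lengths = stats::setNames(lens, labels),
       residual = sum((A %*% lens - dvec)^2))
}

# edge indices on the path between tips i and j
intersect_path <- function(tree, i, j) {
  np <- ape::nodepath(tree, i, j)
  e <- tree$edge
  idx <- integer(length(np) - 1L)
  for (k in seq_len(length(np) - 1L)) {
    a <- np[k]; b <- np[k + 1L]
    hit <- which((e[, 1] == a & e[, 2] == b) | (e[, 1] == b & e[, 2] == a))
    idx[k] <- hit[1]
  }
  idx
}
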