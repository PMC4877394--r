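## Large inverted repeat detection and quadripartite (IR/SSC/LSC) mapping.
##
## Intervals are 0-based half-open on the circular coordinate system of the
## genome; an interval with end <= start wraps the origin.

#' Detect the large inverted repeat and delimit the quadripartite regions
#'
#' Finds the longest pair of disjoint, reverse-complementary segments of at
#' least \code{min_len} bp (extended maximally at both junctions) and derives
#' the SSC and LSC single-copy regions. IR copies in chloroplast assemblies
#' are typically identical, so matching is exact by default; a small
#' \code{max_mismatch_frac} enables a mismatch-tolerant seed-and-extend mode.
#' When several disjoint pairs tie in length, a pair whose copies contain an
#' annotated rRNA gene wins (the IR is defined by the rDNA operon it
#' encodes); remaining ties go to the smallest start coordinate.
#'
#' @param genome a \code{cp_genome} (circular).
#' @param min_len minimum IR copy length in bp (default 1000).
#' @param max_mismatch_frac tolerated mismatch fraction between the two
#'   copies (default 0 = exact).
#' @return an object of class \code{cp_qmap}: \code{has_ir}, \code{ir_a},
#'   \code{ir_b}, \code{ssc}, \code{lsc} (each \code{c(start, end)}),
#'   \code{ir_length}, \code{identity}.
#' @export
detect_inverted_repeat <- function(genome, min_len = 1000, max_mismatch_frac = 0) {
  S <- genome$sequence
  L <- nchar(S)
  no_ir <- structure(list(has_ir = FALSE, ir_a = NULL, ir_b = NULL,
                          ssc = NULL, lsc = NULL, ir_length = 0L,
                          identity = NA_real_), class = "cp_qmap")
  if (L < 2 * min_len) {
    warning("genome shorter than 2*min_len; no IR search performed")
    return(no_ir)
  }
  cand <- find_inverted_matches(S, circular = genome$topology == "circular",
                                min_len = min_len,
                                max_mismatch = max_mismatch_frac)
  if (nrow(cand) == 0L) return(no_ir)

  best_len <- max(cand$len)
  best <- cand[cand$len == best_len, , drop = FALSE]
  if (nrow(best) > 1L) {
    rr <- vapply(seq_len(nrow(best)), function(i) {
      ir_has_rrna(genome, best$a_start[i], best$len[i]) &&
        ir_has_rrna(genome, best$b_start[i], best$len[i])
    }, logical(1))
    if (any(rr)) best <- best[rr, , drop = FALSE]
    best <- best[order(best$a_start), , drop = FALSE]
  }
  hit <- best[1, ]
  ir_a <- c(hit$a_start, (hit$a_start + hit$len) %% L)
  ir_b <- c(hit$b_start, (hit$b_start + hit$len) %% L)
  # single-copy regions: the two circular gaps between the IR copies
  gap1 <- c(ir_a[2], ir_b[1])
  gap2 <- c(ir_b[2], ir_a[1])
  len1 <- (gap1[2] - gap1[1]) %% L
  len2 <- (gap2[2] - gap2[1]) %% L
  if (len1 <= len2) { ssc <- gap1; lsc <- gap2 } else { ssc <- gap2; lsc <- gap1 }
  structure(list(has_ir = TRUE, ir_a = ir_a, ir_b = ir_b, ssc = ssc,
                 lsc = lsc, ir_length = as.integer(hit$len),
                 identity = hit$identity), class = "cp_qmap")
}

#' @export
print.cp_qmap <- function(x, ...) {
  if (!x$has_ir) {
    cat("<cp_qmap> no inverted repeat detected\n")
  } else {
    cat(sprintf("<cp_qmap> IR %s bp (identity %.4f)\n",
                format(x$ir_length, big.mark = ","), x$identity))
    cat(sprintf("  IR-A [%d,%d)  IR-B [%d,%d)  SSC [%d,%d)  LSC [%d,%d)\n",
                x$ir_a[1], x$ir_a[2], x$ir_b[1], x$ir_b[2],
                x$ssc[1], x$ssc[2], x$lsc[1], x$lsc[2]))
  }
  invisible(x)
}

# does the interval [start, start+len) contain (part of) an rRNA gene?
ir_has_rrna <- function(genome, start, len) {
  L <- nchar(genome$sequence)
  for (f in genome$features) {
    if (f$category != "rRNA") next
    p <- feature_start(f)
    if (((p - start) %% L) < len) return(TRUE)
  }
  FALSE
}

# All candidate maximal inverted-repeat pairs >= min_len.
# Returns data.frame(a_start, b_start, len, identity); coordinates mod L,
# a_start chosen so that copy A precedes copy B in the canonical ordering.
find_inverted_matches <- function(S, circular, min_len, max_mismatch = 0) {
  L <- nchar(S)
  k <- min(31L, min_len)
  # search in doubled sequence for rotation invariance on circles
  TT <- if (circular) paste0(S, S) else S
  R <- revcomp(TT)
  n <- nchar(TT)
  step <- max(1L, min_len - k + 1L)
  hits <- kmer_matches(TT, R, k, step = step)
  if (nrow(hits) == 0L)
    return(data.frame(a_start = integer(), b_start = integer(),
                      len = integer(), identity = numeric()))
  # extend each seed maximally (exact); mismatch tolerance handled after
  ext <- extend_matches(TT, R, hits$p, hits$q, k,
                        max_mismatch = max_mismatch)
  # map R coordinates back: R[q, q+len) == revcomp(TT[n-q-len, n-q))
  a <- ext$p; len <- ext$len
  b <- n - ext$q - len
  keep <- len >= min_len
  a <- a[keep]; b <- b[keep]; len <- len[keep]; idn <- ext$identity[keep]
  if (!length(a))
    return(data.frame(a_start = integer(), b_start = integer(),
                      len = integer(), identity = numeric()))
  # canonical pair on the circle
  am <- a %% L; bm <- b %% L
  sw <- bm < am
  tmp <- am[sw]; am[sw] <- bm[sw]; bm[sw] <- tmp
  cap <- pmin(len, L)
  df <- data.frame(a_start = am, b_start = bm, len = cap, identity = idn)
  df <- df[!duplicated(df[, c("a_start", "b_start", "len")]), , drop = FALSE]
  # drop self-overlapping pairs (copies must be disjoint on the circle)
  ok <- vapply(seq_len(nrow(df)), function(i) {
    d <- (df$b_start[i] - df$a_start[i]) %% L
    d >= df$len[i] && (L - d) >= df$len[i]
  }, logical(1))
  df <- df[ok, , drop = FALSE]
  # drop pairs strictly contained in a longer reported pair
  if (nrow(df) > 1L) {
    df <- df[order(-df$len), , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))[-1]) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        da <- (df$a_start[i] - df$a_start[j]) %% L
        db <- (df$b_start[i] + df$len[i] - df$a_start[j]) %% L
        if (da < df$len[j] && db <= df$len[j]) { keep[i] <- FALSE; break }
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  df
}

# Positions of shared k-mers between A (sampled every `step` bp, so any
# common substring of length >= step + k - 1 contains a sampled seed) and
# B (fully indexed). Seeds on the same diagonal are thinned to run starts,
# since adjacent seeds extend to the same maximal match.
kmer_matches <- function(A, B, k, step = 1L) {
  na <- nchar(A) - k + 1L
  nb <- nchar(B) - k + 1L
  if (na < 1L || nb < 1L) return(data.frame(p = integer(), q = integer()))
  apos <- seq(1L, na, by = step)
  ka <- substring(A, apos, apos + k - 1L)
  kb <- substring(B, 1:nb, k:(nb + k - 1L))
  pb <- split(seq_len(nb) - 1L, kb)
  hit <- ka %in% names(pb)
  if (!any(hit)) return(data.frame(p = integer(), q = integer()))
  qlist <- pb[ka[hit]]
  res_p <- rep(apos[hit] - 1L, lengths(qlist))
  res_q <- unlist(qlist, use.names = FALSE)
  d <- res_p - res_q
  o <- order(d, res_p)
  res_p <- res_p[o]; res_q <- res_q[o]; d <- d[o]
  run_start <- c(TRUE, !(d[-1] == d[-length(d)] &
                           res_p[-1] <= res_p[-length(res_p)] + step))
  data.frame(p = res_p[run_start], q = res_q[run_start])
}

# maximal exact (or mismatch-bounded) extension of seed matches
extend_matches <- function(A, B, p, q, k, max_mismatch = 0) {
  av <- strsplit(A, "")[[1]]
  bv <- strsplit(B, "")[[1]]
  n <- length(p)
  len <- integer(n); idn <- numeric(n); ps <- integer(n); qs <- integer(n)
  for (i in seq_len(n)) {
    s <- p[i]; t <- q[i]; e <- p[i] + k; f <- q[i] + k  # 0-based half-open
    mm <- 0L
    # exact left extension
    while (s > 0L && t > 0L && av[s] == bv[t]) { s <- s - 1L; t <- t - 1L }
    while (e < length(av) && f < length(bv) && av[e + 1L] == bv[f + 1L]) {
      e <- e + 1L; f <- f + 1L
    }
    if (max_mismatch > 0) {
      # greedy mismatch-tolerant extension while overall rate stays bounded
      repeat {
        cur <- e - s
        ok <- FALSE
        if (s > 0L && t > 0L && (mm + 1) / (cur + 1) <= max_mismatch) {
          s2 <- s - 1L; t2 <- t - 1L; mm2 <- mm + (av[s2 + 1L] != bv[t2 + 1L])
          if (mm2 / (cur + 1) <= max_mismatch) {
            s <- s2; t <- t2; mm <- mm2; ok <- TRUE
            while (s > 0L && t > 0L && av[s] == bv[t]) { s <- s - 1L; t <- t - 1L }
          }
        }
        cur <- e - s
        if (e < length(av) && f < length(bv) && (mm + 1) / (cur + 1) <= max_mismatch) {
          mm2 <- mm + (av[e + 1L] != bv[f + 1L])
          if (mm2 / (cur + 1) <= max_mismatch) {
            e <- e + 1L; f <- f + 1L; mm <- mm2; ok <- TRUE
            while (e < length(av) && f < length(bv) && av[e + 1L] == bv[f + 1L]) {
              e <- e + 1L; f <- f + 1L
            }
          }
        }
        if (!ok) break
      }
    }
    ps[i] <- s; qs[i] <- t; len[i] <- e - s; idn[i] <- 1 - mm / (e - s)
  }
  data.frame(p = ps, q = qs, len = len, identity = idn)
}

## ------------------------------------------------------- gene partitioning

#' Assign each gene to the region (IR, SSC, LSC) holding it
#'
#' Genes are labeled by the region containing the majority of their coding
#' length; genes straddling a junction keep the majority label and are
#' flagged. In an IR-less genome every gene is labeled \code{SC}.
#'
#' @param genome a \code{cp_genome}.
#' @param qmap a \code{cp_qmap} from [detect_inverted_repeat()].
#' @return data.frame: gene, copy, category, region, straddles.
#' @export
partition_genes <- function(genome, qmap) {
  L <- nchar(genome$sequence)
  res <- lapply(genome$features, function(f) {
    if (!qmap$has_ir) {
      return(data.frame(gene = f$name, copy = f$copy_index,
                        category = f$category, region = "SC",
                        straddles = FALSE, stringsAsFactors = FALSE))
    }
    regions <- list(IR = qmap$ir_a, IR = qmap$ir_b, SSC = qmap$ssc,
                    LSC = qmap$lsc)
    ov <- vapply(regions, function(r) {
      sum(apply(f$exons, 1L, function(e) interval_overlap(e, r, L)))
    }, numeric(1))
    lab <- c("IR", "IR", "SSC", "LSC")
    tot <- tapply(ov, lab[seq_along(ov)], sum)
    region <- names(tot)[which.max(tot)]
    data.frame(gene = f$name, copy = f$copy_index, category = f$category,
               region = region, straddles = sum(tot > 0) > 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# overlap in bp of two circular intervals (0-based half-open, may wrap)
interval_overlap <- function(x, y, L) {
  unwrap <- function(iv) {
    if (iv[2] > iv[1]) list(iv) else list(c(iv[1], L), c(0, iv[2]))
  }
  tot <- 0
  for (a in unwrap(x)) for (b in unwrap(y)) {
    tot <- tot + max(0, min(a[2], b[2]) - max(a[1], b[1]))
  }
  tot
}

#' Label genes by their side relative to the rDNA operon in a reference
#'
#' In a reference genome with an ancestral quadripartite organization, the
#' rDNA-operon genes are labeled \code{rdna}; other genes get
#' \code{ssc-side} or \code{lsc-side} according to the single-copy region
#' they reside in (IR-resident non-operon genes take the side of the nearest
#' junction).
#'
#' @param genome reference \code{cp_genome}.
#' @param qmap its \code{cp_qmap}.
#' @return data.frame: gene, ancestral_side.
#' @export
ancestral_sides <- function(genome, qmap) {
  part <- partition_genes(genome, qmap)
  rdna <- rdna_operon_genes()
  side <- ifelse(part$gene %in% rdna, "rdna",
                 ifelse(part$region == "SSC", "ssc-side",
                        ifelse(part$region == "LSC", "lsc-side", NA)))
  if (qmap$has_ir && anyNA(side)) {
    # IR-resident, non-operon genes: side of the closer junction
    L <- nchar(genome$sequence)
    for (i in which(is.na(side))) {
      f <- genome$features[[which(vapply(genome$features, function(z)
        z$name == part$gene[i] && z$copy_index == part$copy[i],
        logical(1)))[1]]]
      p <- feature_start(f)
      d_to_ssc <- min((qmap$ssc[1] - p) %% L, (p - qmap$ssc[2]) %% L)
      d_to_lsc <- min((qmap$lsc[1] - p) %% L, (p - qmap$lsc[2]) %% L)
      side[i] <- if (d_to_ssc <= d_to_lsc) "ssc-side" else "lsc-side"
    }
  }
  side[is.na(side)] <- "unclassified"
  unique(data.frame(gene = part$gene, ancestral_side = side,
                    stringsAsFactors = FALSE))
}

#' Segregation of ancestral SSC-side and LSC-side genes in a target genome
#'
#' Given a target genome's circular gene order and per-gene ancestral sides
#' taken from a reference, reports the minimum number of genes whose removal
#' leaves the ssc-side and lsc-side genes in two contiguous arcs. The
#' optimum over all circular two-arc splits is computed exactly.
#'
#' @param target_order a \code{cp_gene_order} (see [extract_signed_order()])
#'   or character vector of gene symbols in circular order.
#' @param sides data.frame from [ancestral_sides()] (reference genome).
#' @return list: \code{segregation_violations}, \code{n_scored},
#'   \code{shared_fraction}, \code{sides} (per-gene labels on the target).
#' @export
classify_partitioning <- function(target_order, sides) {
  genes <- if (inherits(target_order, "cp_gene_order"))
    target_order$genes$symbol else as.character(target_order)
  lab <- sides$ancestral_side[match(genes, sides$gene)]
  shared <- mean(!is.na(lab))
  if (shared < 0.5)
    warning("fewer than 50% of target genes shared with the reference")
  keep <- !is.na(lab) & lab %in% c("ssc-side", "lsc-side")
  x <- ifelse(lab[keep] == "ssc-side", 1L, 0L)  # circular binary sequence
  n <- length(x)
  if (n == 0L)
    return(list(segregation_violations = 0L, n_scored = 0L,
                shared_fraction = shared,
                sides = data.frame(gene = genes, side = lab)))
  # min removals so the circular sequence has one arc of 1s and one of 0s:
  # choose an arc (start s, length l) to hold the 1s; cost = 0s inside the
  # arc + 1s outside it; minimize exactly over all circular arcs
  cs2 <- c(0L, cumsum(c(x, x)))    # doubled for wrap-around arcs
  total1 <- sum(x)
  best <- total1                    # empty arc: remove every 1
  for (s in seq_len(n)) {
    l <- 0:n
    ones_in <- cs2[s + l] - cs2[s]
    cost <- (l - ones_in) + (total1 - ones_in)
    best <- min(best, cost)
  }
  list(segregation_violations = as.integer(best), n_scored = n,
       shared_fraction = shared,
       sides = data.frame(gene = genes, side = lab, stringsAsFactors = FALSE))
}

#' Write a quadripartite summary row
#' @param genome a \code{cp_genome}; @param qmap its map.
#' @return one-row data.frame (intervals serialized 0-based half-open).
#' @export
qmap_row <- function(genome, qmap) {
  fmt <- function(iv) if (is.null(iv)) "" else sprintf("%d-%d", iv[1], iv[2])
  data.frame(taxon = genome$taxon_id, has_ir = qmap$has_ir,
             ir_a = fmt(qmap$ir_a), ir_b = fmt(qmap$ir_b),
             ssc = fmt(qmap$ssc), lsc = fmt(qmap$lsc),
             ir_length = qmap$ir_length, identity = qmap$identity,
             stringsAsFactors = FALSE)
}
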