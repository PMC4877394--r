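## Nucleotide composition, small-repeat content, colinear divergence and
## the tRNA decoding audit.

#' G+C content of one or more sequences
#'
#' Computed as (G+C)/(A+C+G+T); N positions are excluded from the
#' denominator.
#'
#' @param regions character vector of DNA strings.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(regions) {
  s <- paste(toupper(regions), collapse = "")
  if (nchar(s) == 0L) stop("empty sequence set")
  counts <- table(strsplit(s, "")[[1]])
  gc <- sum(counts[c("G", "C")], na.rm = TRUE)
  at <- sum(counts[c("A", "T")], na.rm = TRUE)
  if (gc + at == 0) stop("no unambiguous bases")
  gc / (gc + at)
}

#' G+C content at the three codon positions
#'
#' Concatenates the coding sequences codon-wise (incomplete terminal codons
#' trimmed) and reports the positionwise G+C fractions.
#'
#' @param genes character vector (or list) of in-frame CDS sequences.
#' @return numeric vector of three fractions (positions 1, 2, 3).
#' @export
gc_by_codon_position <- function(genes) {
  genes <- unlist(genes, use.names = FALSE)
  if (!length(genes)) stop("empty gene set")
  trimmed <- vapply(genes, function(g) {
    n <- nchar(g) - nchar(g) %% 3
    substr(toupper(g), 1L, n)
  }, character(1))
  s <- paste(trimmed, collapse = "")
  if (nchar(s) == 0L) stop("no complete codons")
  v <- strsplit(s, "")[[1]]
  npos <- length(v)
  codons <- paste0(v[seq(1, npos, 3)], v[seq(2, npos, 3)], v[seq(3, npos, 3)])
  stops <- sum(codons[-length(codons)] %in% c("TAA", "TAG", "TGA"))
  if (stops > 0) warning(stops, " internal stop codons in concatenate")
  vapply(1:3, function(p) {
    b <- v[seq(p, npos, 3)]
    b <- b[b %in% c("A", "C", "G", "T")]
    mean(b %in% c("G", "C"))
  }, numeric(1))
}

## -------------------------------------------------------------- repeats

#' Find maximal exact repeats (direct and inverted)
#'
#' All maximal pairs of exact repeated segments of at least \code{min_len}
#' bp, forward ("direct") and reverse-complementary ("inverted"), as a
#' repeat-masking catalog. A pair is reported only if inextensible on both
#' sides. The large IR (or any interval) can be excluded via \code{mask}.
#'
#' @param genome a \code{cp_genome} or a DNA string.
#' @param min_len minimum repeat length (default 30).
#' @param types subset of \code{c("direct", "inverted")}.
#' @param mask optional matrix of \code{[start,end)} intervals excluded from
#'   the search (e.g. the large IR copies).
#' @return object of class \code{cp_repeats}: data.frame (type, start1,
#'   end1, start2, end2, length) with attribute \code{masked} (IRanges of
#'   the masked union) and \code{genome_length}.
#' @export
find_repeats <- function(genome, min_len = 30L, types = c("direct", "inverted"),
                         mask = NULL) {
  S <- if (inherits(genome, "cp_genome")) genome$sequence else toupper(genome)
  L <- nchar(S)
  if (!is.null(mask)) {
    # replace masked intervals by N runs so no repeat crosses them
    for (r in seq_len(nrow(mask))) {
      a <- mask[r, 1]; b <- mask[r, 2]
      if (b > a) substr(S, a + 1L, b) <- strrep("N", b - a)
    }
  }
  res <- list()
  if ("direct" %in% types) {
    dm <- maximal_pairs(S, S, min_len, self = TRUE)
    if (nrow(dm)) res[[length(res) + 1L]] <-
        data.frame(type = "direct", start1 = dm$p, end1 = dm$p + dm$len,
                   start2 = dm$q, end2 = dm$q + dm$len, length = dm$len)
  }
  if ("inverted" %in% types) {
    R <- revcomp(S)
    im <- maximal_pairs(S, R, min_len, self = FALSE)
    if (nrow(im)) {
      s2 <- L - im$q - im$len
      df <- data.frame(type = "inverted", start1 = im$p, end1 = im$p + im$len,
                       start2 = s2, end2 = s2 + im$len, length = im$len)
      # canonical order, drop mirrored duplicates and self-pairs
      sw <- df$start2 < df$start1
      tmp <- df[sw, c("start2", "end2")]
      df[sw, c("start2", "end2")] <- df[sw, c("start1", "end1")]
      df[sw, c("start1", "end1")] <- tmp
      df <- df[!(df$start1 == df$start2), , drop = FALSE]
      df <- df[!duplicated(df[, c("start1", "start2", "length")]), , drop = FALSE]
      res[[length(res) + 1L]] <- df
    }
  }
  out <- if (length(res)) do.call(rbind, res)
    else data.frame(type = character(), start1 = integer(), end1 = integer(),
                    start2 = integer(), end2 = integer(), length = integer())
  rownames(out) <- NULL
  iv <- IRanges::IRanges(start = c(out$start1, out$start2) + 1L,
                         end = c(out$end1, out$end2))
  attr(out, "masked") <- IRanges::reduce(iv)
  attr(out, "genome_length") <- L
  attr(out, "min_len") <- min_len
  class(out) <- c("cp_repeats", "data.frame")
  out
}

# maximal exact matching pairs >= min_len between A and B (seeded on
# min_len-mers). self = TRUE compares A against itself (p < q, non-identical
# diagonal) and collapses overlapping self-repeat seeds to maximal pairs.
maximal_pairs <- function(A, B, min_len, self) {
  k <- as.integer(min_len)
  na <- nchar(A) - k + 1L
  if (na < 1L) return(data.frame(p = integer(), q = integer(), len = integer()))
  ka <- substring(A, 1:na, k:(na + k - 1L))
  valid <- !grepl("N", ka, fixed = TRUE)
  pb <- split((seq_len(na) - 1L)[valid], ka[valid])
  if (self) {
    qa <- pb
  } else {
    nb <- nchar(B) - k + 1L
    kb <- substring(B, 1:nb, k:(nb + k - 1L))
    validb <- !grepl("N", kb, fixed = TRUE)
    qa <- split((seq_len(nb) - 1L)[validb], kb[validb])
  }
  keys <- if (self) names(pb)[lengths(pb) > 1L]
          else intersect(names(pb), names(qa))
  if (!length(keys))
    return(data.frame(p = integer(), q = integer(), len = integer()))
  pbs <- pb[keys]; qas <- qa[keys]
  ps <- integer(0); qs <- integer(0)
  for (z in seq_along(keys)) {
    g <- expand.grid(p = pbs[[z]], q = qas[[z]])
    if (self) g <- g[g$p < g$q, , drop = FALSE]
    ps <- c(ps, g$p); qs <- c(qs, g$q)
  }
  if (!length(ps))
    return(data.frame(p = integer(), q = integer(), len = integer()))
  # thin seeds per diagonal to run starts
  d <- ps - qs
  o <- order(d, ps)
  ps <- ps[o]; qs <- qs[o]; d <- d[o]
  run_start <- c(TRUE, !(d[-1] == d[-length(d)] & ps[-1] == ps[-length(ps)] + 1L))
  ps <- ps[run_start]; qs <- qs[run_start]
  av <- strsplit(A, "")[[1]]
  bv <- strsplit(B, "")[[1]]
  n <- length(ps)
  P <- integer(n); Q <- integer(n); LEN <- integer(n)
  for (i in seq_len(n)) {
    s <- ps[i]; t <- qs[i]; e <- s + k; f <- t + k
    while (s > 0L && t > 0L && av[s] == bv[t] && av[s] != "N") {
      s <- s - 1L; t <- t - 1L
    }
    while (e < length(av) && f < length(bv) && av[e + 1L] == bv[f + 1L] &&
           av[e + 1L] != "N") { e <- e + 1L; f <- f + 1L }
    P[i] <- s; Q[i] <- t; LEN[i] <- e - s
  }
  out <- data.frame(p = P, q = Q, len = LEN)
  out[!duplicated(out), , drop = FALSE]
}

#' Composition summary of repeated vs unique sequence
#'
#' @param genome a \code{cp_genome} or DNA string.
#' @param catalog a \code{cp_repeats} from [find_repeats()].
#' @return list: \code{masked_fraction}, \code{gc_repeat}, \code{gc_unique}
#'   (the last two as percentages).
#' @export
repeat_summary <- function(genome, catalog) {
  S <- if (inherits(genome, "cp_genome")) genome$sequence else toupper(genome)
  L <- nchar(S)
  masked <- attr(catalog, "masked")
  if (length(masked) == 0L) {
    return(list(masked_fraction = 0, gc_repeat = NA_real_,
                gc_unique = 100 * gc_content(S)))
  }
  keep <- rep(TRUE, L)
  st <- IRanges::start(masked); en <- IRanges::end(masked)
  for (i in seq_along(st)) keep[st[i]:en[i]] <- FALSE
  v <- strsplit(S, "")[[1]]
  rep_seq <- paste(v[!keep], collapse = "")
  uni_seq <- paste(v[keep], collapse = "")
  list(masked_fraction = sum(!keep) / L,
       gc_repeat = 100 * gc_content(rep_seq),
       gc_unique = if (nchar(uni_seq)) 100 * gc_content(uni_seq) else NA_real_)
}

#' Soft-mask a genome sequence by a repeat catalog
#'
#' Repeat regions in lower case, the rest in capitals.
#' @inheritParams repeat_summary
#' @return DNA string with repeats soft-masked.
#' @export
soft_mask <- function(genome, catalog) {
  S <- if (inherits(genome, "cp_genome")) genome$sequence else toupper(genome)
  masked <- attr(catalog, "masked")
  v <- strsplit(S, "")[[1]]
  st <- IRanges::start(masked); en <- IRanges::end(masked)
  for (i in seq_along(st)) v[st[i]:en[i]] <- tolower(v[st[i]:en[i]])
  paste(v, collapse = "")
}

## -------------------------------------------------- colinear divergence

#' Divergence between two colinear genomes
#'
#' Anchors the two sequences on unique shared k-mers, chains the anchors
#' colinearly, globally aligns the inter-anchor gaps, and counts divergent
#' positions: substitution sites one by one and each contiguous indel run as
#' a single event.
#'
#' @param a,b DNA strings (or \code{cp_genome}s) assumed colinear.
#' @param anchor_k anchor k-mer size (default 31).
#' @return object of class \code{cp_divergence}: \code{aligned_fraction},
#'   \code{substitution_sites}, \code{indel_events}, \code{indel_lengths},
#'   \code{total_sites} (substitutions + indel events), \code{colinear}.
#' @export
colinear_divergence <- function(a, b, anchor_k = 31L) {
  A <- if (inherits(a, "cp_genome")) a$sequence else toupper(a)
  B <- if (inherits(b, "cp_genome")) b$sequence else toupper(b)
  k <- as.integer(anchor_k)
  ka <- substring(A, 1:(nchar(A) - k + 1L), k:nchar(A))
  kb <- substring(B, 1:(nchar(B) - k + 1L), k:nchar(B))
  ua <- ka[!(ka %in% ka[duplicated(ka)])]
  ub <- kb[!(kb %in% kb[duplicated(kb)])]
  shared <- intersect(ua, ub)
  pa <- match(shared, ka); pb <- match(shared, kb)
  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]
  # longest colinear chain (increasing in both): LIS on pb
  if (length(pa)) {
    lis <- longest_increasing(pb)
    pa <- pa[lis]; pb <- pb[lis]
    # greedy chain of non-overlapping anchors (spacing >= k in both)
    sel <- logical(length(pa))
    last_a <- -k; last_b <- -k
    for (i in seq_along(pa)) {
      if (pa[i] - last_a >= k && pb[i] - last_b >= k) {
        sel[i] <- TRUE; last_a <- pa[i]; last_b <- pb[i]
      }
    }
    pa <- pa[sel]; pb <- pb[sel]
  }
  if (!length(pa)) {
    warning("no colinear anchor chain found; genomes may not be colinear")
    return(structure(list(aligned_fraction = 0, substitution_sites = NA_integer_,
                          indel_events = NA_integer_, indel_lengths = integer(0),
                          total_sites = NA_integer_, colinear = FALSE),
                     class = "cp_divergence"))
  }
  anchored <- length(pa) * k
  if (anchored / min(nchar(A), nchar(B)) < 0.5) {
    warning("anchor chain covers < 50% of the shorter genome; genomes may not be colinear")
    return(structure(list(aligned_fraction = anchored / min(nchar(A), nchar(B)),
                          substitution_sites = NA_integer_,
                          indel_events = NA_integer_,
                          indel_lengths = integer(0),
                          total_sites = NA_integer_, colinear = FALSE),
                     class = "cp_divergence"))
  }
  subs <- 0L; indels <- integer(0)
  aligned_bp <- anchored
  gaps_a <- c(pa[1] - 1L, diff(pa) - k, nchar(A) - (pa[length(pa)] + k - 1L))
  gaps_b <- c(pb[1] - 1L, diff(pb) - k, nchar(B) - (pb[length(pb)] + k - 1L))
  starts_a <- c(1L, pa + k); starts_b <- c(1L, pb + k)
  for (i in seq_along(gaps_a)) {
    ga <- gaps_a[i]; gb <- gaps_b[i]
    if (ga == 0L && gb == 0L) next
    if (as.double(ga + 1) * (gb + 1) > 2.5e7) {
      # gap too large for dense alignment: count one structural event
      indels <- c(indels, abs(ga - gb))
      aligned_bp <- aligned_bp + min(ga, gb)
      next
    }
    sa <- substr(A, starts_a[i], starts_a[i] + ga - 1L)
    sb <- substr(B, starts_b[i], starts_b[i] + gb - 1L)
    cmp <- align_gap(sa, sb)
    subs <- subs + cmp$subs
    indels <- c(indels, cmp$indel_lengths)
    aligned_bp <- aligned_bp + min(ga, gb)
  }
  af <- aligned_bp / min(nchar(A), nchar(B))
  colinear <- TRUE
  structure(list(aligned_fraction = af, substitution_sites = as.integer(subs),
                 indel_events = length(indels), indel_lengths = indels,
                 total_sites = as.integer(subs + length(indels)),
                 colinear = colinear),
            class = "cp_divergence")
}

#' @export
print.cp_divergence <- function(x, ...) {
  cat(sprintf("<cp_divergence> %d divergent sites (%d substitutions, %d indel events), aligned fraction %.3f\n",
              x$total_sites, x$substitution_sites, x$indel_events,
              x$aligned_fraction))
  invisible(x)
}

# indices of a longest strictly increasing subsequence
longest_increasing <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- integer(n); tails_idx <- integer(n); prev <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    lo <- 1L; hi <- m
    while (lo <= hi) {            # binary search: first tail >= x[i]
      mid <- (lo + hi) %/% 2L
      if (tails[mid] < x[i]) lo <- mid + 1L else hi <- mid - 1L
    }
    pos <- lo
    tails[pos] <- x[i]; tails_idx[pos] <- i
    if (pos > m) m <- pos
    prev[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
  }
  out <- integer(m); i <- tails_idx[m]; j <- m
  while (i > 0L) { out[j] <- i; i <- prev[i]; j <- j - 1L }
  out[out > 0L]
}

# global alignment of a gap pair; counts mismatches and indel runs
align_gap <- function(sa, sb) {
  if (nchar(sa) == 0L && nchar(sb) == 0L)
    return(list(subs = 0L, indel_lengths = integer(0)))
  if (nchar(sa) == 0L) return(list(subs = 0L, indel_lengths = nchar(sb)))
  if (nchar(sb) == 0L) return(list(subs = 0L, indel_lengths = nchar(sa)))
  al <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                      substitutionMatrix =
                                        Biostrings::nucleotideSubstitutionMatrix(
                                          match = 1, mismatch = -1),
                                      gapOpening = 4, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(al))
  ps <- as.character(Biostrings::alignedSubject(al))
  va <- strsplit(pa, "")[[1]]; vs <- strsplit(ps, "")[[1]]
  gap <- va == "-" | vs == "-"
  subs <- sum(!gap & va != vs)
  runs <- rle(gap)
  indel_lengths <- runs$lengths[runs$values]
  list(subs = as.integer(subs), indel_lengths = as.integer(indel_lengths))
}

## ----------------------------------------------------- tRNA decoding audit

#' Audit whether the encoded tRNA set can decode all used codons
#'
#' Tabulates codon usage over the protein-coding features, derives the
#' anticodon set from tRNA gene names (\code{trnX(yyy)}), and lists sense
#' codons that no encoded tRNA can read. Wobble rules: the first two codon
#' positions pair strictly; at the third position anticodon G reads C/U,
#' U reads A/G (or any base when \code{superwobble}), A reads U, C reads G.
#' \code{trnI(cau)} is taken to read AUA (lysidine modification) and
#' \code{trnMe(cau)}/\code{trnMf(cau)} AUG.
#'
#' @param genome a \code{cp_genome} with CDS and tRNA annotations.
#' @param superwobble allow U to read all four third-position bases in
#'   four-fold degenerate boxes (default FALSE).
#' @return object of class \code{cp_codon_audit}: \code{usage} (named codon
#'   counts), \code{anticodons}, \code{undecodable} (used codons with no
#'   reader).
#' @export
codon_decoding_audit <- function(genome, superwobble = FALSE) {
  cds <- Filter(function(f) f$category == "protein", genome$features)
  trna <- Filter(function(f) f$category == "tRNA", genome$features)
  usage <- integer(0)
  if (length(cds)) {
    seqs <- vapply(cds, function(f) feature_sequence(genome, f), character(1))
    v <- strsplit(paste(vapply(seqs, function(g)
      substr(g, 1, nchar(g) - nchar(g) %% 3), character(1)), collapse = ""),
      "")[[1]]
    if (length(v)) {
      codons <- paste0(v[seq(1, length(v), 3)], v[seq(2, length(v), 3)],
                       v[seq(3, length(v), 3)])
      codons <- codons[!grepl("N", codons)]
      usage <- table(codons)
      usage <- usage[!(names(usage) %in% c("TAA", "TAG", "TGA"))]
    }
  }
  acs <- unique(vapply(trna, `[[`, character(1), "name"))
  readable <- character(0)
  for (nm in acs) {
    m <- regmatches(nm, regexec("^trn([A-Za-z]+)\\(([a-z]{3})\\)$", nm))[[1]]
    if (length(m) < 3L) next
    aa <- m[2]; ac <- toupper(m[3])
    if (ac == "CAU") {
      readable <- c(readable, if (aa == "I") "ATA" else "ATG")
      next
    }
    acv <- strsplit(ac, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
    codon12 <- paste0(comp[acv[3]], comp[acv[2]])
    third <- switch(acv[1],
                    G = c("C", "T"),
                    T = if (superwobble) c("A", "G", "C", "T") else c("A", "G"),
                    U = if (superwobble) c("A", "G", "C", "T") else c("A", "G"),
                    A = c("T", "C", "A"),  # A34 deaminated to inosine
                    C = "G")
    readable <- c(readable, paste0(codon12, third))
  }
  readable <- unique(readable)
  undec <- setdiff(names(usage), readable)
  structure(list(usage = usage, anticodons = acs,
                 undecodable = sort(undec)),
            class = "cp_codon_audit")
}

#' @export
print.cp_codon_audit <- function(x, ...) {
  cat(sprintf("<cp_codon_audit> %d codon types used, %d tRNAs, %d undecodable codons\n",
              length(x$usage), length(x$anticodons), length(x$undecodable)))
  if (length(x$undecodable))
    cat("  undecodable:", paste(x$undecodable, collapse = " "), "\n")
  invisible(x)
}
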