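## Signed gene orders, signed adjacencies (gene pairs) and synteny blocks.

#' Extract the signed gene order of a genome
#'
#' Genes are ordered by genomic coordinate from the origin; the sign is the
#' coding strand. With \code{dedup = "one-ir-copy"} the IR-B copy of each
#' duplicated gene is dropped (requires \code{qmap}); duplicates outside the
#' IR keep the lowest-coordinate copy, with a log message.
#'
#' @param genome a \code{cp_genome} with normalized names.
#' @param categories feature categories to keep.
#' @param catalog optional character vector restricting genes to a catalog.
#' @param dedup \code{"keep-all"} or \code{"one-ir-copy"}.
#' @param qmap optional \code{cp_qmap}, used by \code{"one-ir-copy"}.
#' @return object of class \code{cp_gene_order}: \code{taxon_id},
#'   \code{genes} (data.frame symbol, copy, sign), \code{topology}.
#' @export
extract_signed_order <- function(genome,
                                 categories = c("protein", "tRNA", "rRNA", "tmRNA"),
                                 catalog = NULL,
                                 dedup = c("keep-all", "one-ir-copy"),
                                 qmap = NULL) {
  dedup <- match.arg(dedup)
  L <- nchar(genome$sequence)
  keep <- vapply(genome$features, function(f) {
    f$category %in% categories && (is.null(catalog) || f$name %in% catalog)
  }, logical(1))
  feats <- genome$features[keep]
  df <- data.frame(
    symbol = vapply(feats, `[[`, character(1), "name"),
    copy = vapply(feats, `[[`, integer(1), "copy_index"),
    sign = vapply(feats, `[[`, integer(1), "strand"),
    start = vapply(feats, feature_start, numeric(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$start), , drop = FALSE]
  if (dedup == "one-ir-copy" && anyDuplicated(df$symbol)) {
    drop <- logical(nrow(df))
    for (nm in unique(df$symbol[duplicated(df$symbol)])) {
      idx <- which(df$symbol == nm)
      in_b <- if (!is.null(qmap) && isTRUE(qmap$has_ir)) {
        ((df$start[idx] - qmap$ir_b[1]) %% L) < qmap$ir_length
      } else rep(FALSE, length(idx))
      if (any(in_b) && !all(in_b)) {
        drop[idx[in_b]] <- TRUE
        idx <- idx[!in_b]
      }
      if (length(idx) > 1L) {       # still duplicated outside the IR
        message(sprintf("gene %s duplicated outside IR in %s; keeping lowest-coordinate copy",
                        nm, genome$taxon_id))
        drop[idx[-1]] <- TRUE
      }
    }
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(list(taxon_id = genome$taxon_id,
                 genes = df[, c("symbol", "copy", "sign")],
                 topology = genome$topology),
            class = "cp_gene_order")
}

#' Build a signed gene order directly from symbols and signs
#' @param taxon_id label; @param symbols gene symbols in order;
#' @param signs +1/-1 per gene; @param topology circular or linear.
#' @export
signed_order <- function(taxon_id, symbols, signs,
                         topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(length(symbols) == length(signs), all(signs %in% c(-1, 1)))
  structure(list(taxon_id = taxon_id,
                 genes = data.frame(symbol = as.character(symbols),
                                    copy = 1L, sign = as.integer(signs),
                                    stringsAsFactors = FALSE),
                 topology = topology),
            class = "cp_gene_order")
}

#' @export
print.cp_gene_order <- function(x, ...) {
  s <- paste0(ifelse(x$genes$sign > 0, "+", "-"), x$genes$symbol)
  cat(sprintf("<cp_gene_order> %s (%s, %d genes)\n", x$taxon_id, x$topology,
              nrow(x$genes)))
  cat(" ", paste(utils::head(s, 12), collapse = " "),
      if (nrow(x$genes) > 12) "...", "\n")
  invisible(x)
}

# canonical string form of a signed pair: (a,b) is identified with (-b,-a)
canonical_pair <- function(a, sa, b, sb) {
  f1 <- paste0(ifelse(sa > 0, "+", "-"), a, "|", ifelse(sb > 0, "+", "-"), b)
  f2 <- paste0(ifelse(sb > 0, "-", "+"), b, "|", ifelse(sa > 0, "-", "+"), a)
  pmin(f1, f2)
}

#' Signed adjacencies (gene pairs) of a gene order
#'
#' Each neighboring pair with its orientations, canonicalized so that a
#' pair and its reverse complement are the same character: \code{(a,b)}
#' is identified with \code{(-b,-a)}. A circular order of n genes yields n
#' pairs, a linear order n-1.
#'
#' @param order a \code{cp_gene_order}.
#' @return character vector of canonical pair labels.
#' @export
signed_adjacencies <- function(order) {
  g <- order$genes
  n <- nrow(g)
  if (n == 0L) stop("empty gene order")
  if (n == 1L) return(character(0))
  i <- seq_len(if (order$topology == "circular") n else n - 1L)
  j <- if (order$topology == "circular") c(seq_len(n)[-1], 1L) else i + 1L
  unique(canonical_pair(g$symbol[i], g$sign[i], g$symbol[j], g$sign[j]))
}

#' Matrix of signed gene pairs shared by several genomes
#'
#' Binary character matrix over the pairs present in at least
#' \code{min_taxa} genomes. In a taxon where either member gene of a pair is
#' absent (lost), the state is missing (\code{NA}), not 0.
#'
#' @param orders list of \code{cp_gene_order}.
#' @param min_taxa minimum number of genomes carrying a pair (default 3).
#' @return a \code{cp_char_matrix} of kind \code{gene_pair} (see
#'   [character_matrix()]).
#' @export
shared_pair_matrix <- function(orders, min_taxa = 3L) {
  taxa <- vapply(orders, `[[`, character(1), "taxon_id")
  adj <- lapply(orders, signed_adjacencies)
  all_pairs <- sort(unique(unlist(adj)))
  counts <- table(unlist(lapply(adj, unique)))
  keep <- names(counts)[counts >= min_taxa]
  keep <- intersect(all_pairs, keep)
  gene_sets <- lapply(orders, function(o) unique(o$genes$symbol))
  members <- strsplit(gsub("[+-]", "", keep), "\\|")
  m <- matrix(0L, nrow = length(taxa), ncol = length(keep),
              dimnames = list(taxa, keep))
  for (i in seq_along(orders)) {
    m[i, keep %in% adj[[i]]] <- 1L
    lost <- !vapply(members, function(ab) all(ab %in% gene_sets[[i]]), logical(1))
    m[i, lost] <- NA
  }
  character_matrix(m, kind = "gene_pair")
}

## ------------------------------------------------------------- synteny

#' Synteny blocks between two gene orders
#'
#' Blocks are maximal runs of genes consecutive in both genomes with a
#' consistent relative orientation (a block matched in inverted orientation
#' has all signs flipped and its order reversed), computed on the common
#' gene set (one copy per gene: duplicates are resolved to the
#' lowest-coordinate copy). Circular orders are cut at a deterministic
#' anchor and the block spanning the cut is re-merged, so the result is
#' rotation invariant. Singleton blocks are allowed unless
#' \code{min_block_genes > 1}.
#'
#' @param a,b \code{cp_gene_order} objects.
#' @param min_block_genes blocks with fewer genes are reported but flagged.
#' @return object of class \code{cp_synteny}: data.frame of blocks
#'   (block, a_first, a_last, b_first, b_last, orientation, n_genes, genes)
#'   plus attributes \code{n_common}, \code{breakpoints}.
#' @export
synteny_blocks <- function(a, b, min_block_genes = 1L) {
  ra <- dedup_order(a); rb <- dedup_order(b)
  common <- intersect(ra$symbol, rb$symbol)
  if (length(common) == 0L) {
    out <- data.frame(block = integer(), a_first = character(),
                      a_last = character(), b_first = character(),
                      b_last = character(), orientation = character(),
                      n_genes = integer(), genes = character())
    attr(out, "n_common") <- 0L; attr(out, "breakpoints") <- 0L
    class(out) <- c("cp_synteny", "data.frame")
    return(out)
  }
  ra <- ra[ra$symbol %in% common, , drop = FALSE]
  rb <- rb[rb$symbol %in% common, , drop = FALSE]
  circ <- a$topology == "circular" && b$topology == "circular"
  # relabel: gene i = position in a (sign relative to a's strand)
  pos_a <- stats::setNames(seq_len(nrow(ra)), ra$symbol)
  sgn_a <- stats::setNames(ra$sign, ra$symbol)
  perm <- unname(pos_a[rb$symbol]) * (rb$sign * unname(sgn_a[rb$symbol]))
  n <- length(perm)
  # runs in b consecutive in a with consistent orientation
  nxt_ok <- function(x, y) {
    isTRUE(x > 0 && y > 0 && y == succ(x, n, circ)) ||
      isTRUE(x < 0 && y < 0 && -x == succ(-y, n, circ))
  }
  brk <- c(TRUE, vapply(seq_len(n - 1L),
                        function(i) !nxt_ok(perm[i], perm[i + 1L]), logical(1)))
  block_id <- cumsum(brk)
  # circular: merge the block spanning the cut in b (last run joins first)
  if (circ && n > 1L && max(block_id) > 1L && nxt_ok(perm[n], perm[1L])) {
    block_id[block_id == max(block_id)] <- 1L
  }
  ids <- unique(block_id)
  rows <- lapply(seq_along(ids), function(kk) {
    idx <- which(block_id == ids[kk])
    if (kk == 1L && circ && any(diff(idx) > 1L)) { # wrapped block: reorder
      gap <- which(diff(idx) > 1L)
      idx <- c(idx[(gap + 1L):length(idx)], idx[1:gap])
    }
    syms <- rb$symbol[idx]
    orient <- if (all(perm[idx] < 0)) "inverted" else "same"
    data.frame(block = kk,
               a_first = ra$symbol[abs(perm[idx[1]])],
               a_last = ra$symbol[abs(perm[idx[length(idx)]])],
               b_first = syms[1], b_last = syms[length(syms)],
               orientation = orient, n_genes = length(idx),
               genes = paste(syms, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_common") <- n
  nb <- nrow(out)
  attr(out, "breakpoints") <- if (circ) (if (nb == 1L) 0L else nb) else nb - 1L
  attr(out, "min_block_genes") <- min_block_genes
  class(out) <- c("cp_synteny", "data.frame")
  out
}

# successor of position i in genome a (circular wraps)
succ <- function(i, n, circ) if (i < n) i + 1L else if (circ) 1L else NA_integer_

# reduce an order to one copy per symbol (lowest coordinate first)
dedup_order <- function(o) {
  g <- o$genes
  g[!duplicated(g$symbol), , drop = FALSE]
}

#' @export
print.cp_synteny <- function(x, ...) {
  cat(sprintf("<cp_synteny> %d blocks over %d common genes (%d breakpoints)\n",
              nrow(x), attr(x, "n_common"), attr(x, "breakpoints")))
  print.data.frame(utils::head(as.data.frame(x)[, c("block", "a_first", "a_last",
                                                    "orientation", "n_genes")], 10))
  invisible(x)
}

#' Classify genes present in only one of two genomes
#'
#' A gene present in genome A but not B is an "internal excision" if its
#' two flanking genes (nearest shared genes on either side in A) are
#' adjacent within a single synteny block of the comparison; otherwise it is
#' "breakpoint-associated".
#'
#' @param a_full,b_full full (unreduced) \code{cp_gene_order} objects.
#' @param blocks result of [synteny_blocks()] on the same pair.
#' @return data.frame: gene, present_in, class.
#' @export
classify_missing_genes <- function(a_full, b_full, blocks) {
  ga <- dedup_order(a_full); gb <- dedup_order(b_full)
  common <- intersect(ga$symbol, gb$symbol)
  res <- list()
  one_side <- function(donor, other, donor_name) {
    missing <- setdiff(donor$symbol, other$symbol)
    lapply(missing, function(m) {
      i <- which(donor$symbol == m)
      n <- nrow(donor)
      circ <- a_full$topology == "circular"
      lft <- i; rgt <- i
      repeat { lft <- if (lft > 1L) lft - 1L else if (circ) n else NA
               if (is.na(lft) || donor$symbol[lft] %in% common) break }
      repeat { rgt <- if (rgt < n) rgt + 1L else if (circ) 1L else NA
               if (is.na(rgt) || donor$symbol[rgt] %in% common) break }
      cls <- "breakpoint-associated"
      if (!is.na(lft) && !is.na(rgt)) {
        fl <- donor$symbol[lft]; fr <- donor$symbol[rgt]
        within <- vapply(strsplit(blocks$genes, ","), function(gs) {
          pi <- match(fl, gs); pj <- match(fr, gs)
          !is.na(pi) && !is.na(pj) && abs(pi - pj) == 1L
        }, logical(1))
        if (any(within)) cls <- "internal excision"
      }
      data.frame(gene = m, present_in = donor_name, class = cls,
                 stringsAsFactors = FALSE)
    })
  }
  res <- c(one_side(ga, gb, a_full$taxon_id), one_side(gb, ga, b_full$taxon_id))
  if (!length(res))
    return(data.frame(gene = character(), present_in = character(),
                      class = character()))
  do.call(rbind, res)
}
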