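#' Ancestral chloroplast gene catalog
#'
#' The 144 standard genes inferred to have been present in the chloroplast
#' genome of the common ancestor of streptophytes: 90 genes retained in all
#' compared streptophyte genomes plus 54 genes (42 protein-coding, 11 tRNA
#' genes and the tmRNA gene \code{ssrA}) lost at least once during
#' streptophyte algal diversification. Gene symbols follow the standard
#' plastid nomenclature, with tRNA anticodons in parentheses, e.g.
#' \code{trnK(uuu)}.
#'
#' @param set which gene set to return: the full ancestral complement
#'   (\code{"ancestral"}, 144 genes), the universally retained set
#'   (\code{"retained"}, 90 genes), the reduced shared set used for
#'   rearrangement analyses (\code{"shared89"}, 89 genes: the retained set
#'   without \code{rrf}, whose identification was contentious in one genome),
#'   or only the genes lost at least once (\code{"lost"}, 54 genes).
#' @return a data.frame with columns \code{gene} (symbol) and \code{category}
#'   (\code{protein}, \code{tRNA}, \code{rRNA} or \code{tmRNA}).
#' @export
gene_catalog <- function(set = c("ancestral", "retained", "shared89", "lost")) {
  set <- match.arg(set)
  ret <- .retained_genes()
  lost <- .lost_genes()
  out <- switch(set,
    ancestral = rbind(ret, lost),
    retained  = ret,
    shared89  = ret[ret$gene != "rrf", , drop = FALSE],
    lost      = lost
  )
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# the 90 genes present in every compared streptophyte chloroplast genome
.retained_genes <- function() {
  protein <- c(
    "atpA", "atpB", "atpE", "atpF", "atpH", "atpI", "cemA",
    "chlB", "chlL", "chlN", "clpP", "ftsH",
    "ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG", "ndhH",
    "ndhI", "ndhJ",
    "petA", "petB", "petD", "petG", "petL",
    "psaA", "psaB", "psaC", "psaI", "psaJ",
    "psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH", "psbI",
    "psbJ", "psbK", "psbL", "psbM", "psbN", "psbT", "psbZ",
    "rbcL", "rpl2", "rpl20", "rpl33", "rpl36",
    "rpoB", "rpoC1", "rpoC2",
    "rps2", "rps8", "rps11", "rps18", "rps19",
    "ycf1", "ycf4", "ycf12"
  )
  trna <- c(
    "trnA(ugc)", "trnC(gca)", "trnD(guc)", "trnE(uuc)", "trnF(gaa)",
    "trnG(gcc)", "trnH(gug)", "trnI(cau)", "trnI(gau)", "trnK(uuu)",
    "trnL(uaa)", "trnL(uag)", "trnMe(cau)", "trnMf(cau)", "trnN(guu)",
    "trnP(ugg)", "trnQ(uug)", "trnR(acg)", "trnR(ucu)", "trnS(gcu)",
    "trnS(gga)", "trnS(uga)", "trnW(cca)", "trnY(gua)"
  )
  rrna <- c("rrf", "rrl", "rrs")
  data.frame(
    gene = c(protein, trna, rrna),
    category = c(rep("protein", length(protein)), rep("tRNA", length(trna)),
                 rep("rRNA", length(rrna))),
    stringsAsFactors = FALSE
  )
}

# the 54 ancestral genes lost at least once among streptophyte algae
.lost_genes <- function() {
  protein <- c(
    "accD", "ccsA", "chlI", "cysA", "cysT", "ftsI", "ftsW", "infA",
    "minD", "minE", "ndhK", "odpB", "petM", "petN", "psaM",
    "rpl5", "rpl12", "rpl14", "rpl16", "rpl19", "rpl21", "rpl22",
    "rpl23", "rpl32", "rpoA",
    "rps3", "rps4", "rps7", "rps9", "rps10", "rps12", "rps14", "rps15",
    "rps16", "tilS", "tufA",
    "ycf3", "ycf20", "ycf47", "ycf62", "ycf65", "ycf66"
  )
  trna <- c(
    "trnG(ucc)", "trnL(caa)", "trnL(gag)", "trnR(ccg)", "trnR(ucg)",
    "trnS(cga)", "trnT(ggu)", "trnT(ugu)", "trnV(aac)", "trnV(gac)",
    "trnV(uac)"
  )
  data.frame(
    gene = c(protein, trna, "ssrA"),
    category = c(rep("protein", length(protein)), rep("tRNA", length(trna)),
                 "tmRNA"),
    stringsAsFactors = FALSE
  )
}

#' Genes of the chloroplast rDNA operon, in ancestral transcription order
#'
#' @return character vector \code{rrs, trnI(gau), trnA(ugc), rrl, rrf}.
#' @export
rdna_operon_genes <- function() {
  c("rrs", "trnI(gau)", "trnA(ugc)", "rrl", "rrf")
}

#' Default gene-name synonym table
#'
#' Maps common source spellings (GenBank-style \code{trnK-UUU},
#' underscore-delimited anticodons, rRNA product names) to the canonical
#' symbols used by [gene_catalog()].
#'
#' @return data.frame with columns \code{source_name} and
#'   \code{canonical_name}.
#' @export
default_synonyms <- function() {
  cat <- gene_catalog("ancestral")
  trna <- cat$gene[cat$category == "tRNA"]
  aa <- sub("^trn([A-Za-z]+)\\(.*$", "\\1", trna)
  ac <- sub("^trn[A-Za-z]+\\((.*)\\)$", "\\1", trna)
  dash  <- paste0("trn", aa, "-", toupper(gsub("u", "t", ac)))
  dashu <- paste0("trn", aa, "-", toupper(ac))
  under <- paste0("trn", aa, "_", ac)
  rib <- data.frame(
    source_name = c("16S ribosomal RNA", "23S ribosomal RNA",
                    "5S ribosomal RNA", "4.5S ribosomal RNA",
                    "rrn16", "rrn23", "rrn5", "16S", "23S", "5S"),
    canonical_name = c("rrs", "rrl", "rrf", "rrl",
                       "rrs", "rrl", "rrf", "rrs", "rrl", "rrf"),
    stringsAsFactors = FALSE
  )
  out <- rbind(
    data.frame(source_name = dash, canonical_name = trna,
               stringsAsFactors = FALSE),
    data.frame(source_name = dashu, canonical_name = trna,
               stringsAsFactors = FALSE),
    data.frame(source_name = under, canonical_name = trna,
               stringsAsFactors = FALSE),
    rib
  )
  out[!duplicated(out$source_name), , drop = FALSE]
}
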