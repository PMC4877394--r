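## Annotated-genome container and flat-file I/O.
##
## Internal coordinates are 0-based half-open throughout; GenBank and GFF3
## use 1-based inclusive coordinates and are converted at the boundary.
## An exon on a circular sequence may wrap the origin, represented as an
## interval whose end is <= its start (it runs start..L then 0..end).

#' Construct an annotated genome
#'
#' @param taxon_id short unique label.
#' @param sequence DNA string over A, C, G, T, N (upper-cased on input).
#' @param topology \code{"circular"} or \code{"linear"}.
#' @param features list of features built with [gene_feature()].
#' @param source free-text provenance.
#' @return an object of class \code{cp_genome}.
#' @export
annotated_genome <- function(taxon_id, sequence, topology = c("circular", "linear"),
                             features = list(), source = "") {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains characters outside {A,C,G,T,N}")
  for (f in features) {
    ex <- f$exons
    if (any(ex < 0) || any(ex > L))
      stop(sprintf("feature '%s': exon coordinates outside [0, %d]", f$name, L))
  }
  if (length(features) > 1L) {
    features <- features[order(vapply(features, feature_start, numeric(1)))]
  }
  structure(
    list(taxon_id = taxon_id, sequence = sequence, topology = topology,
         features = features, source = source),
    class = "cp_genome"
  )
}

#' Construct a gene feature
#'
#' @param name gene symbol, e.g. \code{rbcL}, \code{trnK(uuu)}.
#' @param category one of \code{protein}, \code{tRNA}, \code{rRNA},
#'   \code{tmRNA}, \code{ORF}.
#' @param exons two-column matrix of 0-based half-open \code{[start, end)}
#'   intervals, listed in transcription order. On a circular sequence an
#'   exon with \code{end <= start} wraps the origin.
#' @param strand +1 or -1.
#' @param copy_index integer distinguishing duplicate copies of a gene.
#' @param introns optional data.frame of intron sites carried by this gene,
#'   with columns \code{site_label}, \code{intron_class} (\code{"I"} or
#'   \code{"II"}), \code{cis_or_trans}, \code{has_orf}.
#' @export
gene_feature <- function(name, category, exons, strand, copy_index = 1L,
                         introns = NULL) {
  if (is.vector(exons)) exons <- matrix(exons, ncol = 2, byrow = TRUE)
  stopifnot(ncol(exons) == 2, strand %in% c(1L, -1L, 1, -1))
  colnames(exons) <- c("start", "end")
  list(name = name, category = category, exons = exons,
       strand = as.integer(strand), copy_index = as.integer(copy_index),
       introns = introns)
}

# genomic start of a feature: minimum coordinate over its exons
feature_start <- function(f) min(f$exons[, 1])

# total coding length in bp (wrap-aware when L given)
feature_length <- function(f, L = NA) {
  len <- f$exons[, 2] - f$exons[, 1]
  if (!is.na(L)) len[len <= 0] <- len[len <= 0] + L
  sum(len)
}

#' @export
print.cp_genome <- function(x, ...) {
  cat(sprintf("<cp_genome> %s: %s %s bp, %d features\n", x$taxon_id,
              x$topology, format(nchar(x$sequence), big.mark = ","),
              length(x$features)))
  invisible(x)
}

# reverse complement of a character DNA string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# extract a (possibly wrapping) interval from a genome sequence
extract_interval <- function(sequence, start, end) {
  L <- nchar(sequence)
  if (end > start) {
    substr(sequence, start + 1L, end)
  } else {
    paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end))
  }
}

# spliced transcript-ordered sequence of a feature (strand applied)
feature_sequence <- function(genome, f) {
  parts <- apply(f$exons, 1L, function(e)
    extract_interval(genome$sequence, e[1], e[2]))
  s <- paste(parts, collapse = "")
  if (f$strand < 0) revcomp(s) else s
}

## ---------------------------------------------------------------- GenBank

#' Read a GenBank flat file
#'
#' Parses LOCUS, FEATURES (gene/CDS/tRNA/rRNA/tmRNA keys, including
#' \code{join}/\code{complement} compound locations) and ORIGIN sections.
#' Typed entries (CDS, tRNA, rRNA, tmRNA) take precedence over bare
#' \code{gene} entries for the same gene name. A location of the form
#' \code{join(a..L,1..b)} on a circular sequence becomes a single exon
#' wrapping the origin.
#'
#' @param path GenBank flat file.
#' @param intron_sites optional data.frame (\code{gene}, \code{site_label},
#'   \code{intron_class}, \code{cis_or_trans}, \code{has_orf}) used to label
#'   the introns implied by multi-exon structures.
#' @return a [annotated_genome()] object.
#' @export
read_genbank <- function(path, intron_sites = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("malformed GenBank record: no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  taxon_id <- locus[2]
  L_declared <- suppressWarnings(as.integer(locus[3]))
  topology <- if (any(grepl("circular", locus, ignore.case = TRUE))) "circular" else "linear"

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) stop("malformed GenBank record: no ORIGIN section")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!is.na(L_declared) && nchar(sequence) != L_declared)
    warning(sprintf("declared length %d differs from sequence length %d",
                    L_declared, nchar(sequence)))
  L <- nchar(sequence)

  entries <- list()
  if (length(feat_i)) {
    i <- feat_i[1] + 1L
    while (i < orig_i[1]) {
      ln <- lines[i]
      if (grepl("^ {5}\\S", ln)) {
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        j <- i + 1L
        # continuation lines of the location (no qualifier slash)
        while (j < orig_i[1] && grepl("^ {21}", lines[j]) &&
               !grepl("^\\s+/", lines[j])) {
          loc <- paste0(loc, trimws(lines[j]))
          j <- j + 1L
        }
        quals <- character()
        while (j < orig_i[1] && !grepl("^ {5}\\S", lines[j]) &&
               !grepl("^ORIGIN", lines[j])) {
          quals <- c(quals, trimws(lines[j]))
          j <- j + 1L
        }
        entries[[length(entries) + 1L]] <-
          list(key = key, loc = loc, quals = quals, line = i)
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }

  get_qual <- function(quals, name) {
    hits <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (!length(hits)) return(NA_character_)
    gsub("\"", "", sub(paste0("^/", name, "="), "", hits[1]))
  }

  keep_keys <- c("CDS", "tRNA", "rRNA", "tmRNA", "gene")
  feats <- list()
  seen <- character()
  for (pass in c("typed", "gene")) {
    for (e in entries) {
      if (!(e$key %in% keep_keys)) next
      if (pass == "typed" && e$key == "gene") next
      if (pass == "gene" && e$key != "gene") next
      nm <- get_qual(e$quals, "gene")
      if (is.na(nm)) nm <- get_qual(e$quals, "locus_tag")
      if (is.na(nm)) nm <- get_qual(e$quals, "product")
      if (is.na(nm)) next
      if (pass == "gene" && nm %in% seen) next
      pl <- tryCatch(parse_gb_location(e$loc, L, topology),
                     error = function(err)
                       stop(sprintf("malformed location at line %d: %s",
                                    e$line, e$loc)))
      category <- switch(e$key,
        CDS = if (grepl("^orf", nm, ignore.case = TRUE)) "ORF" else "protein",
        tRNA = "tRNA", rRNA = "rRNA", tmRNA = "tmRNA",
        gene = if (grepl("^orf", nm, ignore.case = TRUE)) "ORF"
               else if (grepl("^trn", nm)) "tRNA"
               else if (grepl("^rr[sfl]", nm)) "rRNA" else "protein")
      introns <- NULL
      n_int <- nrow(pl$exons) - 1L
      if (n_int > 0L && !is.null(intron_sites)) {
        hit <- intron_sites[intron_sites$gene == nm, , drop = FALSE]
        if (nrow(hit)) introns <- utils::head(hit[, setdiff(names(hit), "gene"),
                                                  drop = FALSE], n_int)
      }
      feats[[length(feats) + 1L]] <-
        gene_feature(nm, category, pl$exons, pl$strand, introns = introns)
      seen <- c(seen, nm)
    }
  }
  if (!length(feats)) warning("no gene features found in ", path)
  g <- annotated_genome(taxon_id, sequence, topology, feats,
                        source = paste0("genbank:", path))
  assign_copy_indices(g)
}

# parse a GenBank location string into exons (0-based half-open) + strand
parse_gb_location <- function(loc, L, topology) {
  strand <- 1L
  s <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", s)) {
    strand <- -1L
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) s <- sub("^join\\((.*)\\)$", "\\1", s)
  inner_comp <- grepl("^complement\\(", s)
  parts <- strsplit(s, ",")[[1]]
  iv <- t(vapply(parts, function(p) {
    p <- sub("^complement\\((.*)\\)$", "\\1", p)
    if (grepl("\\.\\.", p)) {
      ab <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    } else ab <- c(as.numeric(p), as.numeric(p))
    if (any(is.na(ab))) stop("bad interval: ", p)
    c(ab[1] - 1, ab[2])  # to 0-based half-open
  }, numeric(2)))
  if (inner_comp && strand == 1L) strand <- -1L
  # merge a join spanning the origin into one wrapping exon
  if (topology == "circular" && nrow(iv) >= 2L) {
    n <- nrow(iv)
    if (iv[n, 1] > iv[1, 1] && iv[n, 2] == L && iv[1, 1] == 0) {
      # e.g. join(1..b, a..L) listed with wrap last, or join(a..L, 1..b)
    }
    if (iv[1, 2] == L && iv[2, 1] == 0 && n >= 2L) {
      wrap <- c(iv[1, 1], iv[2, 2])
      iv <- rbind(wrap, if (n > 2L) iv[3:n, , drop = FALSE])
    }
  }
  if (strand == -1L) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  colnames(iv) <- c("start", "end")
  rownames(iv) <- NULL
  list(exons = iv, strand = strand)
}

#' Write a GenBank flat file
#'
#' Minimal writer emitting LOCUS, FEATURES (one typed entry per feature)
#' and ORIGIN sections; inverse of [read_genbank()] on its own output.
#'
#' @param genome a \code{cp_genome}.
#' @param path output file.
#' @export
write_genbank <- function(genome, path) {
  L <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                     genome$taxon_id, L, genome$topology), con)
  writeLines(sprintf("DEFINITION  %s chloroplast genome.", genome$taxon_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (f in genome$features) {
    key <- switch(f$category, protein = "CDS", ORF = "CDS",
                  tRNA = "tRNA", rRNA = "rRNA", tmRNA = "tmRNA", "gene")
    iv <- f$exons
    if (f$strand < 0) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
    segs <- apply(iv, 1L, function(e) {
      if (e[2] > e[1]) sprintf("%d..%d", e[1] + 1, e[2])
      else sprintf("%d..%d,1..%d", e[1] + 1, L, e[2])  # origin wrap
    })
    loc <- paste(segs, collapse = ",")
    if (grepl(",", loc)) loc <- sprintf("join(%s)", loc)
    if (f$strand < 0) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(genome$sequence, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ------------------------------------------------------------- GFF3/FASTA

#' Read a GFF3 + FASTA pair
#'
#' Expects \code{gene} rows with \code{exon} children (and optional
#' \code{intron} children); GFF 1-based inclusive coordinates are converted
#' to the internal 0-based half-open convention. Unknown feature types are
#' skipped with a logged count.
#'
#' @param gff GFF3 file (as written by [write_gff_fasta()] or compatible).
#' @param fasta FASTA file with a single sequence.
#' @return a [annotated_genome()] object.
#' @export
read_gff_fasta <- function(gff, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("FASTA must contain exactly one sequence")
  seq_id <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])

  gr <- rtracklayer::import(gff)
  df <- as.data.frame(gr)
  if (nrow(df) && !all(as.character(df$seqnames) %in% seq_id))
    stop(sprintf("GFF seqid '%s' does not match FASTA id '%s'",
                 as.character(df$seqnames[1]), seq_id))
  topology <- "circular"
  hdr <- readLines(gff, n = 20L)
  if (any(grepl("topology=linear", hdr))) topology <- "linear"

  known <- c("gene", "exon", "intron", "region")
  unknown <- setdiff(unique(as.character(df$type)), known)
  if (length(unknown))
    message(sprintf("skipping %d rows of unknown feature types: %s",
                    sum(df$type %in% unknown), paste(unknown, collapse = ", ")))

  genes <- df[df$type == "gene", , drop = FALSE]
  feats <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    id <- g$ID
    kids <- df[df$type == "exon" &
                 vapply(df$Parent, function(p) id %in% p, logical(1)), ,
               drop = FALSE]
    strand <- if (as.character(g$strand) == "-") -1L else 1L
    if (nrow(kids) == 0L) {
      ex <- cbind(start = g$start - 1, end = g$end)
    } else {
      kids <- kids[order(kids$start), , drop = FALSE]
      ex <- cbind(start = kids$start - 1, end = kids$end)
      # rejoin an exon split at the origin by the writer
      if (!is.null(kids$origin_split) && any(!is.na(kids$origin_split))) {
        sp <- which(!is.na(kids$origin_split))
        L <- nchar(sequence)
        lo <- sp[ex[sp, 1] == 0][1]; hi <- sp[ex[sp, 2] == L][1]
        if (!is.na(lo) && !is.na(hi)) {
          wrap <- c(ex[hi, 1], ex[lo, 2])
          ex <- ex[-c(lo, hi), , drop = FALSE]
          ex <- rbind(ex, wrap)
        }
      }
      if (strand < 0) ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    }
    ints <- df[df$type == "intron" &
                 vapply(df$Parent, function(p) id %in% p, logical(1)), ,
               drop = FALSE]
    introns <- NULL
    if (nrow(ints)) {
      introns <- data.frame(
        site_label = as.character(ints$site_label),
        intron_class = as.character(ints$intron_class),
        cis_or_trans = as.character(ints$cis_or_trans),
        has_orf = as.logical(ints$has_orf),
        stringsAsFactors = FALSE
      )
    }
    copy <- if (!is.null(g$copy_index) && !is.na(g$copy_index))
      as.integer(g$copy_index) else 1L
    feats[[length(feats) + 1L]] <-
      gene_feature(as.character(g$Name), as.character(g$category), ex,
                   strand, copy, introns)
  }
  annotated_genome(seq_id, sequence, topology, feats,
                   source = paste0("gff3:", gff))
}

#' Write a GFF3 + FASTA pair
#'
#' @param genome a \code{cp_genome}.
#' @param gff,fasta output paths.
#' @export
write_gff_fasta <- function(genome, gff, fasta) {
  L <- nchar(genome$sequence)
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$taxon_id, L), con)
  writeLines(sprintf("# topology=%s", genome$topology), con)
  rows <- character()
  for (k in seq_along(genome$features)) {
    f <- genome$features[[k]]
    id <- sprintf("gene%04d", k)
    strand <- if (f$strand < 0) "-" else "+"
    ex <- f$exons
    span <- c(min(ex[, 1]), max(ifelse(ex[, 2] <= ex[, 1], L, ex[, 2])))
    attr_g <- sprintf("ID=%s;Name=%s;category=%s;copy_index=%d",
                      id, f$name, f$category, f$copy_index)
    rows <- c(rows, sprintf("%s\tcpevol\tgene\t%d\t%d\t.\t%s\t.\t%s",
                            genome$taxon_id, span[1] + 1, span[2], strand, attr_g))
    for (e in seq_len(nrow(ex))) {
      s <- ex[e, 1]; t <- ex[e, 2]
      if (t > s) {
        rows <- c(rows, sprintf("%s\tcpevol\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                genome$taxon_id, s + 1, t, strand, id))
      } else {  # wrap: split at origin, marked for rejoin on read
        rows <- c(rows,
          sprintf("%s\tcpevol\texon\t%d\t%d\t.\t%s\t.\tParent=%s;origin_split=1",
                  genome$taxon_id, s + 1, L, strand, id),
          sprintf("%s\tcpevol\texon\t%d\t%d\t.\t%s\t.\tParent=%s;origin_split=1",
                  genome$taxon_id, 1, t, strand, id))
      }
    }
    if (!is.null(f$introns)) {
      for (e in seq_len(nrow(f$introns))) {
        it <- f$introns[e, ]
        rows <- c(rows, sprintf(
          "%s\tcpevol\tintron\t%d\t%d\t.\t%s\t.\tParent=%s;site_label=%s;intron_class=%s;cis_or_trans=%s;has_orf=%s",
          genome$taxon_id, span[1] + 1, span[2], strand, id,
          it$site_label, it$intron_class, it$cis_or_trans,
          tolower(as.character(it$has_orf))))
      }
    }
  }
  writeLines(rows, con)
  close(con)
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- genome$taxon_id
  Biostrings::writeXStringSet(dna, fasta)
  invisible(gff)
}

#' Write a per-gene TSV table
#'
#' Columns: taxon, gene, copy, start, end, strand, category (coordinates
#' 0-based half-open over the feature span).
#' @param genome a \code{cp_genome}.
#' @param path output TSV.
#' @export
write_gene_table <- function(genome, path) {
  df <- gene_table(genome)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene table of an annotated genome
#' @param genome a \code{cp_genome}.
#' @return data.frame: taxon, gene, copy, start, end, strand, category.
#' @export
gene_table <- function(genome) {
  L <- nchar(genome$sequence)
  do.call(rbind, lapply(genome$features, function(f) {
    ex <- f$exons
    data.frame(taxon = genome$taxon_id, gene = f$name, copy = f$copy_index,
               start = min(ex[, 1]),
               end = max(ifelse(ex[, 2] <= ex[, 1], L, ex[, 2])),
               strand = f$strand, category = f$category,
               stringsAsFactors = FALSE)
  }))
}

## ----------------------------------------------------------- name mapping

#' Normalize gene nomenclature
#'
#' Renames features according to a synonym table so genomes from different
#' sources become comparable; unmapped names are preserved and logged.
#' Duplicate copies are then re-assigned \code{copy_index} in coordinate
#' order.
#'
#' @param genome a \code{cp_genome}.
#' @param synonyms data.frame with columns \code{source_name},
#'   \code{canonical_name} (default [default_synonyms()]).
#' @export
normalize_gene_names <- function(genome, synonyms = default_synonyms()) {
  if (anyDuplicated(synonyms$source_name)) {
    dup <- synonyms$source_name[duplicated(synonyms$source_name)]
    bad <- unique(dup[vapply(dup, function(d)
      length(unique(synonyms$canonical_name[synonyms$source_name == d])) > 1L,
      logical(1))])
    if (length(bad))
      stop("synonym table maps to multiple canonical targets: ",
           paste(bad, collapse = ", "))
  }
  map <- stats::setNames(synonyms$canonical_name, synonyms$source_name)
  unmapped <- character()
  canon <- gene_catalog("ancestral")$gene
  for (k in seq_along(genome$features)) {
    nm <- genome$features[[k]]$name
    if (nm %in% names(map)) {
      genome$features[[k]]$name <- unname(map[nm])
    } else if (!(nm %in% canon)) {
      unmapped <- c(unmapped, nm)
    }
  }
  if (length(unmapped))
    message("unmapped gene names preserved: ",
            paste(unique(unmapped), collapse = ", "))
  assign_copy_indices(genome)
}

# re-assign copy_index per gene name in coordinate order
assign_copy_indices <- function(genome) {
  nms <- vapply(genome$features, `[[`, character(1), "name")
  for (nm in unique(nms)) {
    idx <- which(nms == nm)
    for (j in seq_along(idx)) genome$features[[idx[j]]]$copy_index <- j
  }
  genome
}
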