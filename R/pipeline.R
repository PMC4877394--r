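## End-to-end comparative runs and study metadata accessors.

#' Streptophyte study metadata
#'
#' The packaged table of streptophyte chloroplast genomes (taxon, accession,
#' genome and IR sizes, gene and intron counts, IR presence) and the rooted
#' species phylogeny used for character mapping. IR presence is encoded from
#' the IR size column (present vs blank); the partially sequenced
#' \emph{Klebsormidium} sp. SAG 51.86, whose IR/SSC junction could not be
#' delimited, is coded missing.
#'
#' @return \code{study_taxa()}: data.frame; \code{study_tree()}: rooted
#'   \code{phylo}.
#' @export
study_taxa <- function() {
  path <- system.file("extdata", "streptophyte_taxa.tsv", package = "cpevol")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname study_taxa
#' @export
study_tree <- function() {
  path <- system.file("extdata", "streptophyte_tree.nwk", package = "cpevol")
  ape::read.tree(path)
}

#' IR presence/absence character matrix from the study table
#'
#' @return a \code{cp_char_matrix} with a single \code{ir} character.
#' @export
study_ir_matrix <- function() {
  tt <- study_taxa()
  states <- matrix(tt$has_ir, ncol = 1,
                   dimnames = list(tt$taxon, "IR"))
  character_matrix(states, kind = "ir")
}

#' Count loss events falling inside a clade
#'
#' @param scn a \code{cp_events} scenario.
#' @param tree the tree it was computed on.
#' @param clade_taxa tip labels delimiting the clade: an event branch is in
#'   the clade when every tip below it belongs to \code{clade_taxa}.
#' @return integer count of loss events.
#' @export
count_losses_in_clade <- function(scn, tree, clade_taxa) {
  info <- tree_index(tree)
  pb <- scn$per_branch
  pb <- pb[pb$event == "loss", , drop = FALSE]
  inside <- vapply(pb$branch, function(lbl) {
    nd <- match(lbl, info$node_label)
    if (is.na(nd)) return(FALSE)
    all(info$below[[nd]] %in% clade_taxa)
  }, logical(1))
  sum(inside)
}

#' Run a full comparative analysis
#'
#' Orchestrates the pipeline stages on a set of annotated genomes: general
#' features (size, quadripartite regions, G+C, gene/intron counts, repeat
#' fraction), pairwise synteny and reversal distances, character matrices
#' with Dollo event scenarios, and a run manifest.
#'
#' @param genomes list of \code{cp_genome} (names normalized).
#' @param tree optional rooted \code{phylo} for the character stages.
#' @param out_dir output directory for the report bundle (TSV/JSON).
#' @param min_ir_len minimum IR length for detection.
#' @param repeat_min_len minimum small-repeat length.
#' @param min_taxa minimum genomes sharing a gene pair.
#' @param seed seed recorded in the manifest.
#' @param stages subset of \code{c("features", "synteny", "distance",
#'   "characters")}.
#' @return invisible list with the computed tables.
#' @export
run_compare <- function(genomes, tree = NULL, out_dir,
                        min_ir_len = 1000L, repeat_min_len = 30L,
                        min_taxa = 3L, seed = 1L,
                        stages = c("features", "synteny", "distance",
                                   "characters")) {
  if (length(genomes) < 2L) stop("need at least two genomes")
  if ("characters" %in% stages && is.null(tree))
    stop("character stages require a tree")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cpevol",
                   version = as.character(utils::packageVersion("cpevol")),
                   seed = seed,
                   parameters = list(min_ir_len = min_ir_len,
                                     repeat_min_len = repeat_min_len,
                                     min_taxa = min_taxa),
                   stages = list())
  result <- list()

  qmaps <- lapply(genomes, detect_inverted_repeat, min_len = min_ir_len)
  orders <- mapply(function(g, q)
    extract_signed_order(g, qmap = q, dedup = "one-ir-copy"),
    genomes, qmaps, SIMPLIFY = FALSE)

  if ("features" %in% stages) {
    rows <- mapply(function(g, q) {
      L <- nchar(g$sequence)
      mask <- if (q$has_ir) rbind(iv_mat(q$ir_a, L), iv_mat(q$ir_b, L)) else NULL
      reps <- find_repeats(g, min_len = repeat_min_len, mask = mask)
      rs <- repeat_summary(g, reps)
      n_introns <- sum(vapply(g$features, function(f)
        if (is.null(f$introns)) 0L else nrow(f$introns), integer(1)))
      cbind(qmap_row(g, q),
            data.frame(size = L, gc_pct = round(100 * gc_content(g$sequence), 1),
                       n_genes = length(unique(vapply(g$features, `[[`,
                                                      character(1), "name"))),
                       n_introns = n_introns,
                       repeat_pct = round(100 * rs$masked_fraction, 2)))
    }, genomes, qmaps, SIMPLIFY = FALSE)
    features <- do.call(rbind, rows)
    utils::write.table(features, file.path(out_dir, "general_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$features <- features
    manifest$stages$features <- "ok"
  }

  if ("synteny" %in% stages) {
    k <- length(orders)
    rows <- list()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      bl <- synteny_blocks(orders[[i]], orders[[j]])
      rows[[length(rows) + 1L]] <-
        data.frame(taxon_a = orders[[i]]$taxon_id,
                   taxon_b = orders[[j]]$taxon_id,
                   n_blocks = nrow(bl), n_common = attr(bl, "n_common"),
                   breakpoints = attr(bl, "breakpoints"))
    }
    synteny <- do.call(rbind, rows)
    utils::write.table(synteny, file.path(out_dir, "synteny_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$synteny <- synteny
    manifest$stages$synteny <- "ok"
  }

  if ("distance" %in% stages) {
    shared <- Reduce(intersect, lapply(orders, function(o) o$genes$symbol))
    dm <- distance_matrix(orders, gene_set = shared)
    utils::write.table(as.data.frame(unclass(dm)),
                       file.path(out_dir, "reversal_distances.tsv"),
                       sep = "\t", quote = FALSE)
    result$distances <- dm
    if (!is.null(tree) && all(tree$tip.label %in% rownames(dm))) {
      fit <- fit_branch_lengths(dm, tree)
      ape::write.tree(fit$tree, file.path(out_dir, "reversal_branch_lengths.nwk"))
      result$branch_lengths <- fit
    }
    manifest$stages$distance <- "ok"
  }

  if ("characters" %in% stages) {
    gm <- build_gene_matrix(genomes)
    im <- build_intron_matrix(genomes)
    pm <- shared_pair_matrix(orders, min_taxa = min_taxa)
    write_char_matrix(gm, file.path(out_dir, "gene_matrix.tsv"))
    write_char_matrix(im, file.path(out_dir, "intron_matrix.tsv"))
    write_char_matrix(pm, file.path(out_dir, "gene_pair_matrix.tsv"))
    scn_g <- dollo_map(gm, tree)
    scn_i <- dollo_map(im, tree)
    utils::write.table(scn_g$per_character,
                       file.path(out_dir, "gene_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scn_i$per_character,
                       file.path(out_dir, "intron_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$gene_scenario <- scn_g
    result$intron_scenario <- scn_i
    result$pair_matrix <- pm
    manifest$stages$characters <- "ok"
  }

  cfg_string <- paste(deparse(manifest$parameters), collapse = "")
  manifest$config_hash <- sum(utf8ToInt(cfg_string) * seq_along(utf8ToInt(cfg_string)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

iv_mat <- function(iv, L) {
  if (iv[2] > iv[1]) matrix(iv, ncol = 2)
  else rbind(c(iv[1], L), c(0L, iv[2]))
}
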