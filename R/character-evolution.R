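## Binary character matrices (genes, introns, gene pairs, IR presence) and
## parsimony mapping of gains/losses on a fixed rooted tree.
##
## Dollo parsimony: at most one gain per character; any number of
## independent losses below it; characters cannot be regained.

#' Construct a binary character matrix
#'
#' @param states taxa x characters matrix over \{1, 0, NA\} (NA = missing,
#'   written \code{?} on disk); dimnames required.
#' @param kind character kind, one of \code{gene}, \code{intron},
#'   \code{gene_pair}, \code{ir}; recycled over characters.
#' @return object of class \code{cp_char_matrix}.
#' @export
character_matrix <- function(states, kind = "gene") {
  states <- as.matrix(states)
  if (nrow(states) > 0L && is.null(rownames(states)))
    stop("states must have taxa rownames")
  if (ncol(states) > 0L && is.null(colnames(states)))
    stop("states must have character colnames")
  if (anyDuplicated(colnames(states))) stop("character labels must be unique")
  ok <- states %in% c(0L, 1L) | is.na(states)
  if (!all(ok)) stop("states must be 0, 1 or NA")
  mode(states) <- "integer"
  structure(list(states = states,
                 kind = rep_len(kind, ncol(states))),
            class = "cp_char_matrix")
}

#' @export
print.cp_char_matrix <- function(x, ...) {
  cat(sprintf("<cp_char_matrix> %d taxa x %d characters (%s)\n",
              nrow(x$states), ncol(x$states),
              paste(unique(x$kind), collapse = ", ")))
  invisible(x)
}

#' Gene presence/absence matrix over an ancestral catalog
#'
#' One character per catalog gene; 1 when at least one copy is annotated.
#' For partially sequenced genomes, genes listed in
#' \code{unscreened[[taxon]]} are marked missing (NA) rather than absent.
#'
#' @param genomes list of \code{cp_genome} with normalized names.
#' @param catalog character vector of gene symbols (default the ancestral
#'   144-gene complement).
#' @param unscreened optional named list (taxon -> genes coded NA).
#' @export
build_gene_matrix <- function(genomes, catalog = gene_catalog("ancestral")$gene,
                              unscreened = NULL) {
  if (!length(catalog)) {
    m <- matrix(integer(0), nrow = length(genomes), ncol = 0,
                dimnames = list(vapply(genomes, `[[`, character(1), "taxon_id"),
                                character(0)))
    return(character_matrix(m, kind = "gene"))
  }
  taxa <- vapply(genomes, `[[`, character(1), "taxon_id")
  m <- matrix(0L, length(taxa), length(catalog),
              dimnames = list(taxa, catalog))
  for (i in seq_along(genomes)) {
    present <- unique(vapply(genomes[[i]]$features, `[[`, character(1), "name"))
    if (!any(catalog %in% present))
      stop("taxon ", taxa[i], " has no catalog genes; mis-parsed input?")
    m[i, catalog %in% present] <- 1L
    if (!is.null(unscreened[[taxa[i]]]))
      m[i, catalog %in% unscreened[[taxa[i]]]] <- NA
  }
  character_matrix(m, kind = "gene")
}

#' Intron presence/absence matrix over a site catalog
#'
#' One character per intron site label; the state is missing (NA) wherever
#' the host gene itself is absent, so that intron losses caused by host-gene
#' losses are not scored.
#'
#' @param genomes list of \code{cp_genome}.
#' @param site_catalog data.frame with columns \code{host_gene},
#'   \code{site_label}; defaults to the union of annotated sites.
#' @export
build_intron_matrix <- function(genomes, site_catalog = NULL) {
  taxa <- vapply(genomes, `[[`, character(1), "taxon_id")
  per_taxon <- lapply(genomes, function(g) {
    do.call(rbind, c(list(data.frame(host = character(), site = character())),
      lapply(g$features, function(f) {
        if (is.null(f$introns) || !nrow(f$introns)) return(NULL)
        data.frame(host = f$name, site = f$introns$site_label,
                   stringsAsFactors = FALSE)
      })))
  })
  if (is.null(site_catalog)) {
    allsites <- unique(do.call(rbind, per_taxon))
    site_catalog <- data.frame(host_gene = allsites$host,
                               site_label = allsites$site,
                               stringsAsFactors = FALSE)
  }
  cat_genes <- gene_catalog("ancestral")$gene
  bad <- setdiff(site_catalog$host_gene, cat_genes)
  if (length(bad))
    stop("intron sites reference non-catalog genes: ", paste(bad, collapse = ", "))
  site_catalog <- site_catalog[order(site_catalog$site_label), , drop = FALSE]
  m <- matrix(0L, length(taxa), nrow(site_catalog),
              dimnames = list(taxa, site_catalog$site_label))
  for (i in seq_along(genomes)) {
    genes_i <- vapply(genomes[[i]]$features, `[[`, character(1), "name")
    m[i, !(site_catalog$host_gene %in% genes_i)] <- NA
    hit <- per_taxon[[i]]$site
    m[i, colnames(m) %in% hit] <- 1L
  }
  character_matrix(m, kind = "intron")
}

## ------------------------------------------------------------ Dollo map

#' Map gains and losses under Dollo parsimony
#'
#' For each character the single gain is placed at the root (when
#' \code{assume_root_presence}) or at the most recent common ancestor of the
#' taxa carrying the character. Losses are the minimal set of branches below
#' the gain such that every 0-taxon lies below exactly one loss and no
#' 1-taxon below any; missing states impose no constraint. Among minimal
#' placements, each loss is put on the deepest admissible branch (the branch
#' above the MRCA of the 0-taxa it covers); the number of equally minimal
#' alternative placements is reported.
#'
#' @param matrix a \code{cp_char_matrix}.
#' @param tree rooted \code{phylo}; matrix taxa must be tip labels.
#' @param assume_root_presence logical, per character kind: default TRUE for
#'   \code{gene} (ancestral complement), FALSE otherwise. May be a single
#'   flag or a named vector by kind.
#' @return object of class \code{cp_events}: \code{per_character}
#'   data.frame (character, kind, gain_node, n_losses, loss_branches,
#'   alt_placements, classification), \code{per_branch} data.frame
#'   (branch, character, event), totals in \code{gains} and \code{losses}.
#' @export
dollo_map <- function(matrix, tree, assume_root_presence = NULL) {
  st <- matrix$states
  check_tree_taxa(tree, rownames(st))
  info <- tree_index(tree)
  root_flag <- resolve_root_flag(assume_root_presence, matrix$kind)
  rows <- vector("list", ncol(st))
  branch_events <- list()
  for (k in seq_len(ncol(st))) {
    x <- st[rownames(st), k]
    ones <- names(x)[!is.na(x) & x == 1L]
    zeros <- names(x)[!is.na(x) & x == 0L]
    if (!length(ones) && !root_flag[k]) {
      warning("character ", colnames(st)[k],
              ": no presence and no root assumption; zero events")
      rows[[k]] <- data.frame(character = colnames(st)[k], kind = matrix$kind[k],
                              gain_node = NA_character_, n_losses = 0L,
                              loss_branches = "", alt_placements = 0L,
                              classification = "none", stringsAsFactors = FALSE)
      next
    }
    gain <- if (root_flag[k]) info$root else mrca_node(info, ones)
    dl <- dollo_losses(info, gain, ones, zeros)
    lbl <- vapply(dl$branches, function(b) info$node_label[b], character(1))
    cls <- if (length(dl$branches) == 1L) "synapomorphic"
           else if (length(dl$branches) > 1L) "homoplasic" else "none"
    rows[[k]] <- data.frame(character = colnames(st)[k], kind = matrix$kind[k],
                            gain_node = info$node_label[gain],
                            n_losses = length(dl$branches),
                            loss_branches = paste(lbl, collapse = ","),
                            alt_placements = dl$alternatives,
                            classification = cls, stringsAsFactors = FALSE)
    if (length(dl$branches))
      branch_events[[length(branch_events) + 1L]] <-
        data.frame(branch = lbl, character = colnames(st)[k], event = "loss",
                   stringsAsFactors = FALSE)
    if (!root_flag[k])
      branch_events[[length(branch_events) + 1L]] <-
        data.frame(branch = info$node_label[gain], character = colnames(st)[k],
                   event = "gain", stringsAsFactors = FALSE)
  }
  empty_pc <- data.frame(character = character(), kind = character(),
                         gain_node = character(), n_losses = integer(),
                         loss_branches = character(),
                         alt_placements = integer(),
                         classification = character())
  per_char <- if (length(rows)) do.call(rbind, rows) else empty_pc
  per_branch <- if (length(branch_events)) do.call(rbind, branch_events)
    else data.frame(branch = character(), character = character(),
                    event = character())
  structure(list(per_character = per_char, per_branch = per_branch,
                 gains = sum(per_char$gain_node != "" &
                               !is.na(per_char$gain_node) & !root_flag),
                 losses = sum(per_char$n_losses), method = "dollo",
                 tree = tree),
            class = "cp_events")
}

#' @export
print.cp_events <- function(x, ...) {
  cat(sprintf("<cp_events> %s parsimony: %d characters, %d losses, %d gains\n",
              x$method, nrow(x$per_character), x$losses, x$gains))
  invisible(x)
}

# ---- tree helpers (edges identified by their child node) -----------------

check_tree_taxa <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("matrix taxa not in tree: ", paste(miss, collapse = ", "))
}

tree_index <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- integer(nn); parent[] <- NA
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  # postorder list of tips below each node
  below <- vector("list", nn)
  for (tp in seq_len(n)) below[[tp]] <- tree$tip.label[tp]
  # simple repeated sweep (trees are small)
  repeat {
    done <- TRUE
    for (nd in unique(tree$edge[, 1])) {
      ch <- kids[[as.character(nd)]]
      if (all(vapply(ch, function(c2) !is.null(below[[c2]]), logical(1)))) {
        val <- unique(unlist(below[ch]))
        if (is.null(below[[nd]]) || !setequal(below[[nd]], val)) {
          below[[nd]] <- val
          done <- FALSE
        }
      }
    }
    if (done) break
  }
  node_label <- c(tree$tip.label,
                  if (!is.null(tree$node.label) && length(tree$node.label))
                    tree$node.label else paste0("node", (n + 1):nn))
  if (length(node_label) < nn)
    node_label <- c(node_label, paste0("node", (length(node_label) + 1):nn))
  list(tree = tree, n_tips = n, n_nodes = nn, parent = parent, root = root,
       kids = kids, below = below, node_label = node_label)
}

mrca_node <- function(info, tips) {
  if (length(tips) == 1L) return(match(tips, info$tree$tip.label))
  cand <- which(vapply(seq_len(info$n_nodes), function(nd)
    !is.null(info$below[[nd]]) && all(tips %in% info$below[[nd]]), logical(1)))
  # deepest node containing all tips = the one with fewest tips below
  cand[which.min(vapply(cand, function(nd) length(info$below[[nd]]), integer(1)))]
}

# minimal Dollo losses below `gain`: one loss at the MRCA of the 0-tips of
# each maximal 1-free subtree below the gain that contains a 0-tip
dollo_losses <- function(info, gain, ones, zeros) {
  if (!length(zeros)) return(list(branches = integer(0), alternatives = 0L))
  has_one <- vapply(seq_len(info$n_nodes), function(nd)
    any(ones %in% info$below[[nd]]), logical(1))
  has_zero <- vapply(seq_len(info$n_nodes), function(nd)
    any(zeros %in% info$below[[nd]]), logical(1))
  below_gain <- function(nd) {
    p <- nd
    while (!is.na(p)) { if (p == gain) return(TRUE); p <- info$parent[p] }
    FALSE
  }
  if (!length(ones)) {
    # presence assumed at the root only: the root branch does not exist, so
    # the maximal coverable subtrees are the root's children
    heads <- Filter(function(nd) has_zero[nd], info$kids[[as.character(gain)]])
  } else {
    # maximal 1-free subtrees strictly below the gain
    heads <- which(vapply(seq_len(info$n_nodes), function(nd) {
      if (has_one[nd] || !has_zero[nd]) return(FALSE)
      if (nd == gain || !below_gain(nd)) return(FALSE)
      has_one[info$parent[nd]]
    }, logical(1)))
  }
  branches <- integer(0); alts <- 0L
  for (h in heads) {
    z <- intersect(zeros, info$below[[h]])
    tgt <- mrca_node(info, z)
    branches <- c(branches, tgt)
    # equally minimal placements: any branch from h down to tgt
    p <- tgt; depth <- 1L
    while (p != h && !is.na(info$parent[p])) { p <- info$parent[p]; depth <- depth + 1L }
    alts <- alts + (depth - 1L)
  }
  list(branches = branches, alternatives = alts)
}

resolve_root_flag <- function(flag, kinds) {
  if (is.null(flag)) {
    return(kinds == "gene")
  }
  if (length(flag) == 1L && is.null(names(flag))) return(rep(flag, length(kinds)))
  out <- flag[kinds]
  out[is.na(out)] <- FALSE
  unname(out)
}

## ------------------------------------------------- Fitch/Wagner parsimony

#' Minimal-change (Fitch/Wagner) mapping of binary characters
#'
#' Unit-cost small parsimony allowing repeated gains; for binary characters
#' ordered (Wagner) and unordered (Fitch) costs coincide. Missing states are
#' unconstrained. Ties in the backtrack prefer the parent state, then
#' absence, making the reconstruction deterministic.
#'
#' @inheritParams dollo_map
#' @return a \code{cp_events} object (method \code{fitch}).
#' @export
fitch_wagner_map <- function(matrix, tree) {
  st <- matrix$states
  check_tree_taxa(tree, rownames(st))
  info <- tree_index(tree)
  rows <- vector("list", ncol(st))
  branch_events <- list()
  for (k in seq_len(ncol(st))) {
    x <- st[rownames(st), k]
    rec <- sankoff_binary(info, x)
    ev <- rec$events   # data.frame(child, from, to)
    gains <- ev[ev$to == 1L, , drop = FALSE]
    losses <- ev[ev$to == 0L, , drop = FALSE]
    lblg <- info$node_label[gains$child]
    lbll <- info$node_label[losses$child]
    n_ev <- nrow(ev)
    rows[[k]] <- data.frame(
      character = colnames(st)[k], kind = matrix$kind[k],
      gain_node = if (nrow(gains)) paste(lblg, collapse = ",") else
        if (rec$root_state == 1L) info$node_label[info$root] else NA_character_,
      n_losses = nrow(losses),
      loss_branches = paste(lbll, collapse = ","),
      alt_placements = NA_integer_,
      classification = if (n_ev == 1L) "synapomorphic"
                       else if (n_ev > 1L) "homoplasic" else "none",
      stringsAsFactors = FALSE)
    if (n_ev) {
      branch_events[[length(branch_events) + 1L]] <- data.frame(
        branch = info$node_label[ev$child], character = colnames(st)[k],
        event = ifelse(ev$to == 1L, "gain", "loss"), stringsAsFactors = FALSE)
    }
  }
  per_char <- do.call(rbind, rows)
  per_branch <- if (length(branch_events)) do.call(rbind, branch_events)
    else data.frame(branch = character(), character = character(),
                    event = character())
  structure(list(per_character = per_char, per_branch = per_branch,
                 gains = sum(per_branch$event == "gain"),
                 losses = sum(per_branch$event == "loss"),
                 method = "fitch", tree = tree),
            class = "cp_events")
}

# Sankoff unit-cost DP for one binary character; returns minimal events
sankoff_binary <- function(info, x) {
  INF <- 1e9
  cost <- matrix(NA_real_, info$n_nodes, 2)  # states 0, 1
  order_nodes <- postorder_nodes(info)
  for (nd in order_nodes) {
    if (nd <= info$n_tips) {
      s <- x[info$tree$tip.label[nd]]
      cost[nd, ] <- if (is.na(s)) c(0, 0) else if (s == 0L) c(0, INF) else c(INF, 0)
    } else {
      ch <- info$kids[[as.character(nd)]]
      for (s in 0:1) {
        tot <- 0
        for (c2 in ch) tot <- tot + min(cost[c2, s + 1], cost[c2, 2 - s] + 1)
        cost[nd, s + 1] <- tot
      }
    }
  }
  root_state <- if (cost[info$root, 1] <= cost[info$root, 2]) 0L else 1L
  # preorder backtrack
  state <- integer(info$n_nodes); state[] <- NA
  state[info$root] <- root_state
  events <- list()
  for (nd in rev(order_nodes)) {
    if (nd <= info$n_tips) next
    ch <- info$kids[[as.character(nd)]]
    for (c2 in ch) {
      s <- state[nd]
      keep <- cost[c2, s + 1]
      flip <- cost[c2, 2 - s] + 1
      state[c2] <- if (keep <= flip) s else 1L - s
      if (state[c2] != s)
        events[[length(events) + 1L]] <-
          data.frame(child = c2, from = s, to = state[c2])
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(child = integer(), from = integer(), to = integer())
  list(root_state = root_state, states = state, events = ev)
}

postorder_nodes <- function(info) {
  # children before parents
  out <- integer(0)
  visit <- function(nd) {
    ch <- info$kids[[as.character(nd)]]
    for (c2 in ch) visit(c2)
    out <<- c(out, nd)
  }
  visit(info$root)
  out
}

#' Summarize an event scenario
#'
#' @param scn a \code{cp_events} object.
#' @return list: \code{per_character} with classification,
#'   \code{loss_histogram} (table of per-character loss counts),
#'   \code{per_branch} event table, \code{total_losses},
#'   \code{n_synapomorphic}, \code{n_homoplasic}.
#' @export
classify_events <- function(scn) {
  pc <- scn$per_character
  hist <- table(pc$n_losses)
  list(per_character = pc[, c("character", "kind", "n_losses", "classification")],
       loss_histogram = hist,
       per_branch = scn$per_branch,
       total_losses = sum(pc$n_losses),
       n_synapomorphic = sum(pc$classification == "synapomorphic"),
       n_homoplasic = sum(pc$classification == "homoplasic"))
}

## -------------------------------------------------------------- matrix IO

#' Read/write character matrices as TSV (states 1, 0, ?)
#' @param x a \code{cp_char_matrix}; @param path file path.
#' @export
write_char_matrix <- function(x, path) {
  m <- x$states
  out <- apply(m, c(1, 2), function(v) if (is.na(v)) "?" else as.character(v))
  df <- data.frame(taxon = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_char_matrix
#' @param kind character kind for the matrix read.
#' @export
read_char_matrix <- function(path, kind = "gene") {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$taxon
  m[m == "?"] <- NA
  mode(m) <- "integer"
  character_matrix(m, kind = kind)
}

#' Write a character matrix as a NEXUS characters block
#' @inheritParams write_char_matrix
#' @export
write_nexus_matrix <- function(x, path) {
  m <- x$states
  dat <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    ifelse(is.na(v), "?", as.character(v))
  })
  names(dat) <- rownames(m)
  ape::write.nexus.data(dat, path, format = "standard", interleaved = FALSE)
  invisible(path)
}

#' @rdname write_nexus_matrix
#' @export
read_nexus_matrix <- function(path, kind = "gene") {
  dat <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(dat, function(v) {
    v[v == "?"] <- NA
    as.integer(v)
  }))
  colnames(m) <- paste0("char", seq_len(ncol(m)))
  character_matrix(m, kind = kind)
}
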