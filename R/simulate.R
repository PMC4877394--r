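## Seeded simulator of chloroplast genome evolution along a rooted tree.
##
## The evolving genome is represented as a structured layout (lists of gene
## and spacer elements for the LSC, IR and SSC regions; the IR is stored
## once as a template and rendered twice), so rearrangement events act on
## gene order with intergenic breakpoints and never split a gene. While the
## IR exists, any event touching it affects both copies (concerted
## evolution); an ir_loss event drops copy B. Ground truth (per-branch event
## log, leaf genomes, quadripartite maps) is recorded and can be replayed.

#' Simulation configuration
#'
#' Defaults emulate a streptophyte-like ancestral chloroplast genome: the
#' full 144-gene ancestral complement, a quadripartite architecture whose IR
#' carries the 5-gene rDNA operon (plus \code{trnR(acg)}), an SSC with a
#' small gene set, and desk-scale per-branch event rates.
#'
#' @param seed integer seed fixing all randomness end to end.
#' @param catalog data.frame as [gene_catalog()].
#' @param ir_extra_genes genes placed in the IR besides the rDNA operon.
#' @param ssc_n number of genes assigned to the SSC.
#' @param gc baseline G+C fraction of generated sequence.
#' @param spacer_range intergenic spacer length range (bp).
#' @param protein_len_range protein gene length range (codons).
#' @param intron_sites data.frame(host_gene, site_label, intron_class,
#'   cis_or_trans, has_orf, present) of sites the simulation may use;
#'   \code{present} marks sites carried by the ancestor.
#' @param rates named expected per-branch event counts (poisson):
#'   reversal, gene_loss, intron_gain, intron_loss, ir_loss,
#'   ir_boundary_shift; plus per-bp rates subst and indel.
#' @param indel_mean mean geometric indel length.
#' @param branch_events optional named list (child node label -> list of
#'   event templates) overriding the sampled counts with planted events.
#' @return list of class \code{cp_sim_config}.
#' @export
simulation_config <- function(seed = 1L,
                              catalog = gene_catalog("ancestral"),
                              ir_extra_genes = "trnR(acg)",
                              ssc_n = 18L,
                              gc = 0.35,
                              spacer_range = c(60L, 300L),
                              protein_len_range = c(100L, 500L),
                              intron_sites = default_intron_sites(),
                              rates = c(reversal = 2, gene_loss = 1,
                                        intron_gain = 0.2, intron_loss = 0.7,
                                        ir_loss = 0.05, ir_boundary_shift = 0.3,
                                        subst = 0.002, indel = 2e-04),
                              indel_mean = 2,
                              branch_events = NULL) {
  structure(list(seed = as.integer(seed), catalog = catalog,
                 ir_extra_genes = ir_extra_genes, ssc_n = as.integer(ssc_n),
                 gc = gc, spacer_range = spacer_range,
                 protein_len_range = as.integer(protein_len_range),
                 intron_sites = intron_sites, rates = rates,
                 indel_mean = indel_mean, branch_events = branch_events),
            class = "cp_sim_config")
}

#' Default intron-site table used by the simulator
#' @return data.frame of named cis-spliced sites on catalog genes.
#' @export
default_intron_sites <- function() {
  data.frame(
    host_gene = c("trnL(uaa)", "rpl16", "trnG(ucc)", "atpF", "clpP",
                  "petB", "ndhA", "trnK(uuu)"),
    site_label = c("trnL(uaa)_35", "rpl16_9", "trnG(ucc)_23", "atpF_145",
                   "clpP_363", "petB_6", "ndhA_553", "trnK(uuu)_37"),
    intron_class = c("I", "II", "II", "II", "II", "II", "II", "II"),
    cis_or_trans = "cis",
    has_orf = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    present = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# element constructors -----------------------------------------------------
sim_gene <- function(name, category, seq, strand = 1L, introns = NULL) {
  list(kind = "gene", name = name, category = category, seq = seq,
       strand = strand, introns = introns)
}
sim_spacer <- function(seq) list(kind = "spacer", seq = seq, strand = 1L)

#' Simulate an ancestral quadripartite genome
#'
#' Builds a circular genome whose IR template holds the rDNA operon in the
#' order rrs, trnI(gau), trnA(ugc), rrl, rrf, with the remaining catalog
#' genes split between SSC and LSC and random intergenic spacers.
#'
#' @param cfg a [simulation_config()].
#' @return list of class \code{cp_sim_state} (layout); render with
#'   [render_genome()].
#' @export
simulate_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  cat <- cfg$catalog
  operon <- rdna_operon_genes()
  ir_genes <- c(operon, intersect(cfg$ir_extra_genes, cat$gene))
  rest <- setdiff(cat$gene, ir_genes)
  ssc_genes <- sample(rest, min(cfg$ssc_n, length(rest)))
  lsc_genes <- setdiff(rest, ssc_genes)

  glen <- function(gene) {
    categ <- cat$category[match(gene, cat$gene)]
    if (is.na(categ)) categ <- "protein"
    switch(categ,
           protein = 3L * sample(cfg$protein_len_range[1]:cfg$protein_len_range[2], 1L),
           tRNA = 72L, tmRNA = 350L,
           rRNA = switch(gene, rrs = 1491L, rrl = 2901L, rrf = 120L, 900L),
           900L)
  }
  mk_gene <- function(gene) {
    categ <- cat$category[match(gene, cat$gene)]
    introns <- NULL
    sites <- cfg$intron_sites
    hit <- sites[sites$present & sites$host_gene == gene, , drop = FALSE]
    g <- sim_gene(gene, categ, random_dna(glen(gene), cfg$gc),
                  strand = sample(c(1L, -1L), 1L))
    if (nrow(hit)) {
      pos <- as.integer(round(nchar(g$seq) * seq(0.3, 0.7,
                                                 length.out = nrow(hit))))
      g$introns <- data.frame(hit[, c("site_label", "intron_class",
                                      "cis_or_trans", "has_orf")],
                              pos = pos,
                              seq = vapply(seq_len(nrow(hit)), function(i)
                                random_dna(300L, cfg$gc), character(1)),
                              stringsAsFactors = FALSE)
    }
    g
  }
  spacer <- function() sim_spacer(random_dna(
    sample(cfg$spacer_range[1]:cfg$spacer_range[2], 1L), cfg$gc))
  weave <- function(genes, strands = NULL) {
    out <- list()
    for (i in seq_along(genes)) {
      g <- mk_gene(genes[i])
      if (!is.null(strands)) g$strand <- strands[i]
      out <- c(out, list(g), list(spacer()))
    }
    out
  }
  ira <- weave(ir_genes, strands = rep(1L, length(ir_genes)))
  ssc <- c(list(spacer()), weave(ssc_genes))
  lsc <- c(list(spacer()), weave(lsc_genes))
  structure(list(has_ir = TRUE, lsc = lsc, ira = ira, ssc = ssc, sc = NULL,
                 taxon_id = "ancestor"),
            class = "cp_sim_state")
}

# ordered element list of a state's full circle (IR-B rendered virtually)
state_regions <- function(state) {
  if (state$has_ir) list(lsc = state$lsc, ira = state$ira, ssc = state$ssc)
  else list(sc = state$sc)
}

#' Render a simulation state into an annotated genome
#'
#' @param state a \code{cp_sim_state}.
#' @param taxon_id label for the rendered genome.
#' @return list: \code{genome} (a \code{cp_genome}), \code{qmap} (planted
#'   quadripartite map, or no-IR map), \code{order} (truth
#'   \code{cp_gene_order}).
#' @export
render_genome <- function(state, taxon_id = state$taxon_id) {
  elem_seq <- function(el) {
    s <- el$seq
    if (el$kind == "gene" && !is.null(el$introns) && nrow(el$introns)) {
      ord <- order(el$introns$pos)
      parts <- character(0); last <- 0L
      for (i in ord) {
        parts <- c(parts, substr(s, last + 1L, el$introns$pos[i]),
                   el$introns$seq[i])
        last <- el$introns$pos[i]
      }
      s <- paste(c(parts, substr(s, last + 1L, nchar(s))), collapse = "")
    }
    if (el$strand < 0) revcomp(s) else s
  }
  feats <- list()
  seq_parts <- character(0)
  pos <- 0L
  emit <- function(el, mirrored = FALSE) {
    s <- elem_seq(el)
    if (mirrored) s <- revcomp(s)
    n <- nchar(s)
    if (el$kind == "gene") {
      strand <- if (mirrored) -el$strand else el$strand
      ex <- gene_exon_intervals(el, pos, strand)
      introns <- if (!is.null(el$introns) && nrow(el$introns))
        el$introns[, c("site_label", "intron_class", "cis_or_trans",
                       "has_orf")] else NULL
      feats[[length(feats) + 1L]] <<-
        gene_feature(el$name, el$category, ex, strand, introns = introns)
    }
    seq_parts <<- c(seq_parts, s)
    pos <<- pos + n
  }
  regions <- state_regions(state)
  bounds <- list()
  for (rn in names(regions)) {
    start <- pos
    for (el in regions[[rn]]) emit(el)
    bounds[[rn]] <- c(start, pos)
  }
  if (state$has_ir) {
    start <- pos
    for (el in rev(state$ira)) emit(el, mirrored = TRUE)
    bounds[["irb"]] <- c(start, pos)
  }
  sequence <- paste(seq_parts, collapse = "")
  if (state$has_ir) {
    # break complementarity at the four junctions so the planted IR is the
    # exact maximal inverted repeat
    L <- nchar(sequence)
    fix <- c(bounds$ira[1], bounds$ira[2] + 1L, bounds$irb[1], 1L)
    for (p in fix) if (p >= 1L && p <= L) substr(sequence, p, p) <- "A"
  }
  genome <- annotated_genome(taxon_id, sequence, "circular", feats,
                            source = "simulated")
  genome <- assign_copy_indices(genome)
  qmap <- if (state$has_ir) {
    L <- nchar(sequence)
    modL <- function(iv) as.integer(iv %% L)
    structure(list(has_ir = TRUE, ir_a = modL(bounds$ira),
                   ir_b = modL(bounds$irb), ssc = modL(bounds$ssc),
                   lsc = modL(bounds$lsc),
                   ir_length = bounds$ira[2] - bounds$ira[1],
                   identity = 1), class = "cp_qmap")
  } else {
    structure(list(has_ir = FALSE, ir_a = NULL, ir_b = NULL, ssc = NULL,
                   lsc = NULL, ir_length = 0L, identity = NA_real_),
              class = "cp_qmap")
  }
  order <- extract_signed_order(genome, qmap = qmap, dedup = "keep-all")
  list(genome = genome, qmap = qmap, order = order)
}

# exon intervals of a gene element placed at `pos` (with introns inserted)
gene_exon_intervals <- function(el, pos, strand) {
  n_exonic <- nchar(el$seq)
  if (is.null(el$introns) || !nrow(el$introns)) {
    ex <- matrix(c(pos, pos + n_exonic), ncol = 2)
  } else {
    ord <- order(el$introns$pos)
    cuts <- el$introns$pos[ord]
    ilen <- nchar(el$introns$seq[ord])
    starts <- integer(0); ends <- integer(0)
    cur <- pos; last <- 0L
    for (i in seq_along(cuts)) {
      starts <- c(starts, cur); ends <- c(ends, cur + (cuts[i] - last))
      cur <- cur + (cuts[i] - last) + ilen[i]
      last <- cuts[i]
    }
    starts <- c(starts, cur); ends <- c(ends, cur + (n_exonic - last))
    ex <- cbind(starts, ends)
  }
  total <- if (is.null(el$introns) || !nrow(el$introns)) n_exonic
           else n_exonic + sum(nchar(el$introns$seq))
  if (strand < 0) {
    # exon order follows transcription (right to left), coordinates fixed
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  }
  colnames(ex) <- c("start", "end")
  ex
}

## ------------------------------------------------------------- events

# apply one logged event to a state (deterministic; used for replay too)
apply_event <- function(state, ev) {
  switch(ev$type,
    reversal = {
      reg <- ev$region
      els <- state[[reg]]
      idx <- ev$from:ev$to
      seg <- rev(els[idx])
      seg <- lapply(seg, function(el) {
        el$strand <- -el$strand
        if (el$kind == "spacer") el$seq <- revcomp(el$seq)
        el
      })
      state[[reg]][idx] <- seg
      state
    },
    gene_loss = {
      for (reg in names(state_regions(state))) {
        hit <- which(vapply(state[[reg]], function(el)
          el$kind == "gene" && el$name == ev$gene, logical(1)))
        if (length(hit)) {
          state[[reg]] <- state[[reg]][-hit[1]]
          return(state)
        }
      }
      if (state$has_ir) {
        hit <- which(vapply(state$ira, function(el)
          el$kind == "gene" && el$name == ev$gene, logical(1)))
        if (length(hit)) state$ira <- state$ira[-hit[1]]
      }
      state
    },
    intron_gain = {
      state <- modify_gene(state, ev$gene, function(el) {
        add <- data.frame(site_label = ev$site_label,
                          intron_class = ev$intron_class,
                          cis_or_trans = ev$cis_or_trans, has_orf = ev$has_orf,
                          pos = ev$pos, seq = ev$seq, stringsAsFactors = FALSE)
        el$introns <- if (is.null(el$introns)) add else rbind(el$introns, add)
        el
      })
      state
    },
    intron_loss = {
      state <- modify_gene(state, ev$gene, function(el) {
        if (!is.null(el$introns)) {
          el$introns <- el$introns[el$introns$site_label != ev$site_label, ,
                                   drop = FALSE]
          if (!nrow(el$introns)) el$introns <- NULL
        }
        el
      })
      state
    },
    ir_loss = {
      if (state$has_ir) {
        state$sc <- c(state$lsc, state$ira, state$ssc)
        state$lsc <- state$ira <- state$ssc <- NULL
        state$has_ir <- FALSE
      }
      state
    },
    ir_boundary_shift = {
      if (!state$has_ir) return(state)
      if (ev$direction == "expand_lsc" && length(state$lsc) > 2L) {
        n <- length(state$lsc)
        state$ira <- c(state$lsc[(n - 1L):n], state$ira)
        state$lsc <- state$lsc[1:(n - 2L)]
      } else if (ev$direction == "expand_ssc" && length(state$ssc) > 2L) {
        state$ira <- c(state$ira, state$ssc[1:2])
        state$ssc <- state$ssc[-(1:2)]
      } else if (ev$direction == "contract_lsc" && length(state$ira) > 2L &&
                 !is_operon_element(state$ira[[1]])) {
        state$lsc <- c(state$lsc, state$ira[1:2])
        state$ira <- state$ira[-(1:2)]
      } else if (ev$direction == "contract_ssc" && length(state$ira) > 2L &&
                 !is_operon_element(state$ira[[length(state$ira) - 1L]])) {
        n <- length(state$ira)
        state$ssc <- c(state$ira[(n - 1L):n], state$ssc)
        state$ira <- state$ira[1:(n - 2L)]
      }
      state
    },
    substitutions = {
      reg <- ev$region
      el <- state[[reg]][[ev$idx]]
      s <- strsplit(el$seq, "")[[1]]
      s[ev$positions] <- ev$bases
      state[[reg]][[ev$idx]]$seq <- paste(s, collapse = "")
      state
    },
    indel = {
      reg <- ev$region
      el <- state[[reg]][[ev$idx]]
      s <- el$seq
      if (ev$op == "del") {
        keep_to <- min(nchar(s), ev$pos + ev$len - 1L)
        state[[reg]][[ev$idx]]$seq <-
          paste0(substr(s, 1L, ev$pos - 1L), substr(s, keep_to + 1L, nchar(s)))
      } else {
        state[[reg]][[ev$idx]]$seq <-
          paste0(substr(s, 1L, ev$pos), ev$seq, substr(s, ev$pos + 1L, nchar(s)))
      }
      state
    },
    stop("unknown event type: ", ev$type)
  )
}

is_operon_element <- function(el) {
  el$kind == "gene" && el$name %in% rdna_operon_genes()
}

modify_gene <- function(state, gene, fn) {
  for (reg in names(state_regions(state))) {
    for (i in seq_along(state[[reg]])) {
      el <- state[[reg]][[i]]
      if (el$kind == "gene" && el$name == gene) {
        state[[reg]][[i]] <- fn(el)
        return(state)
      }
    }
  }
  state
}

# sample a concrete event of a given type on the current state; returns
# NULL (with a log entry) when the event is impossible
sample_event <- function(state, type, cfg) {
  regs <- names(state_regions(state))
  switch(type,
    reversal = {
      cand <- regs[vapply(regs, function(r)
        length(state[[r]]) >= 4L, logical(1))]
      cand <- setdiff(cand, "ira")
      if (!length(cand)) return(NULL)
      reg <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = vapply(cand, function(r)
          length(state[[r]]), numeric(1)))
      n <- length(state[[reg]])
      ij <- sort(sample(2:(n - 1L), 2L))
      list(type = "reversal", region = reg, from = ij[1], to = ij[2])
    },
    gene_loss = {
      genes <- setdiff(state_gene_names(state), rdna_operon_genes())
      if (!length(genes)) return(NULL)
      list(type = "gene_loss", gene = sample(genes, 1L))
    },
    intron_gain = {
      present <- state_intron_sites(state)
      open <- cfg$intron_sites[!(cfg$intron_sites$site_label %in% present), ,
                               drop = FALSE]
      open <- open[open$host_gene %in% state_gene_names(state), , drop = FALSE]
      if (!nrow(open)) return(NULL)
      i <- sample(seq_len(nrow(open)), 1L)
      host_len <- state_gene_length(state, open$host_gene[i])
      list(type = "intron_gain", gene = open$host_gene[i],
           site_label = open$site_label[i],
           intron_class = open$intron_class[i],
           cis_or_trans = open$cis_or_trans[i], has_orf = open$has_orf[i],
           pos = max(1L, as.integer(round(host_len / 2))),
           seq = random_dna(300L, cfg$gc))
    },
    intron_loss = {
      present <- state_intron_sites(state)
      if (!length(present)) return(NULL)
      site <- sample(present, 1L)
      list(type = "intron_loss", gene = state_intron_host(state, site),
           site_label = site)
    },
    ir_loss = if (state$has_ir) list(type = "ir_loss") else NULL,
    ir_boundary_shift = {
      if (!state$has_ir) return(NULL)
      dirs <- c("expand_lsc", "expand_ssc", "contract_lsc", "contract_ssc")
      list(type = "ir_boundary_shift", direction = sample(dirs, 1L))
    },
    stop("unknown event type: ", type)
  )
}

state_gene_names <- function(state) {
  unlist(lapply(state_regions(state), function(els)
    vapply(Filter(function(el) el$kind == "gene", els), `[[`, character(1),
           "name")))
}
state_gene_length <- function(state, gene) {
  for (els in state_regions(state)) for (el in els)
    if (el$kind == "gene" && el$name == gene) return(nchar(el$seq))
  NA_integer_
}
state_intron_sites <- function(state) {
  unlist(lapply(state_regions(state), function(els)
    unlist(lapply(els, function(el)
      if (el$kind == "gene" && !is.null(el$introns)) el$introns$site_label))))
}
state_intron_host <- function(state, site) {
  for (els in state_regions(state)) for (el in els)
    if (el$kind == "gene" && !is.null(el$introns) &&
        site %in% el$introns$site_label) return(el$name)
  NA_character_
}

# sequence-level noise on a branch: substitutions everywhere, indels in
# spacers only (events are logged so replay is exact)
sample_sequence_events <- function(state, cfg) {
  evs <- list()
  for (reg in names(state_regions(state))) {
    for (i in seq_along(state[[reg]])) {
      el <- state[[reg]][[i]]
      n <- nchar(el$seq)
      if (n == 0L) next
      k <- stats::rbinom(1L, n, min(1, cfg$rates["subst"]))
      if (k > 0L) {
        pos <- sort(sample.int(n, k))
        evs[[length(evs) + 1L]] <-
          list(type = "substitutions", region = reg, idx = i, positions = pos,
               bases = sample(c("A", "C", "G", "T"), k, replace = TRUE))
      }
      if (el$kind == "spacer" && n > 10L) {
        ki <- stats::rbinom(1L, n, min(1, cfg$rates["indel"]))
        for (z in seq_len(ki)) {
          len <- 1L + stats::rgeom(1L, 1 / cfg$indel_mean)
          if (stats::runif(1) < 0.5) {
            evs[[length(evs) + 1L]] <-
              list(type = "indel", region = reg, idx = i, op = "del",
                   pos = sample.int(max(1L, n - len), 1L), len = len)
          } else {
            evs[[length(evs) + 1L]] <-
              list(type = "indel", region = reg, idx = i, op = "ins",
                   pos = sample.int(n, 1L), seq = random_dna(len, cfg$gc))
          }
        }
      }
    }
  }
  evs
}

#' Evolve an ancestral genome along a rooted tree
#'
#' Structural events (reversal, gene loss, intron gain/loss, IR loss,
#' IR boundary shifts) are applied in logged order on each branch, followed
#' by sequence-level substitutions and indels. Counts are sampled per
#' branch from \code{cfg$rates} unless \code{cfg$branch_events} plants
#' explicit events on named branches.
#'
#' @param ancestor state from [simulate_ancestor()].
#' @param tree rooted \code{phylo} with tip labels (internal node labels
#'   optional; unlabeled internal nodes are named \code{nodeN}).
#' @param cfg the [simulation_config()].
#' @return object of class \code{cp_sim_truth}: \code{events} (per branch),
#'   \code{leaves} (named list of render_genome() results), \code{tree},
#'   \code{config}.
#' @export
evolve_on_tree <- function(ancestor, tree, cfg) {
  set.seed(cfg$seed + 1L)
  info <- tree_index(tree)
  n <- info$n_tips
  struct_types <- c("reversal", "gene_loss", "intron_gain", "intron_loss",
                    "ir_loss", "ir_boundary_shift")
  states <- vector("list", info$n_nodes)
  states[[info$root]] <- ancestor
  events <- list()
  for (nd in rev(postorder_nodes(info))) {   # preorder
    if (nd == info$root) next
    par <- info$parent[nd]
    st <- states[[par]]
    lab <- info$node_label[nd]
    evs <- list()
    planted <- cfg$branch_events[[lab]]
    if (!is.null(planted)) {
      for (tpl in planted) {
        unspecified <- is.null(tpl$gene) && is.null(tpl$region) &&
          is.null(tpl$direction) && is.null(tpl$site_label)
        ev <- if (unspecified && tpl$type %in% struct_types &&
                  tpl$type != "ir_loss")
          sample_event(st, tpl$type, cfg) else complete_event(st, tpl, cfg)
        if (is.null(ev)) {
          events[[length(events) + 1L]] <-
            list(branch = lab, skipped = TRUE, type = tpl$type)
          next
        }
        evs <- c(evs, list(ev))
        st <- apply_event(st, ev)
      }
    } else {
      for (tp in struct_types) {
        kk <- stats::rpois(1L, cfg$rates[[tp]])
        for (z in seq_len(kk)) {
          ev <- sample_event(st, tp, cfg)
          if (is.null(ev)) {
            events[[length(events) + 1L]] <-
              list(branch = lab, skipped = TRUE, type = tp)
            next
          }
          evs <- c(evs, list(ev))
          st <- apply_event(st, ev)
        }
      }
    }
    sev <- sample_sequence_events(st, cfg)
    for (ev in sev) st <- apply_event(st, ev)
    evs <- c(evs, sev)
    states[[nd]] <- st
    events[[length(events) + 1L]] <- list(branch = lab, events = evs)
  }
  leaves <- list()
  for (tp in seq_len(n)) {
    lab <- tree$tip.label[tp]
    leaves[[lab]] <- render_genome(states[[tp]], taxon_id = lab)
  }
  structure(list(events = events, leaves = leaves, tree = tree, config = cfg,
                 ancestor = ancestor),
            class = "cp_sim_truth")
}

# fill the sampled parts of a planted event template
complete_event <- function(state, tpl, cfg) {
  full <- switch(tpl$type,
    gene_loss = if (tpl$gene %in% state_gene_names(state)) tpl else NULL,
    intron_loss = {
      if (is.null(tpl$site_label)) return(sample_event(state, "intron_loss", cfg))
      if (!(tpl$site_label %in% state_intron_sites(state))) return(NULL)
      list(type = "intron_loss", gene = state_intron_host(state, tpl$site_label),
           site_label = tpl$site_label)
    },
    intron_gain = {
      if (is.null(tpl$site_label)) return(sample_event(state, "intron_gain", cfg))
      sites <- cfg$intron_sites
      i <- match(tpl$site_label, sites$site_label)
      if (is.na(i) || tpl$site_label %in% state_intron_sites(state)) return(NULL)
      if (!(sites$host_gene[i] %in% state_gene_names(state))) return(NULL)
      hl <- state_gene_length(state, sites$host_gene[i])
      list(type = "intron_gain", gene = sites$host_gene[i],
           site_label = sites$site_label[i], intron_class = sites$intron_class[i],
           cis_or_trans = sites$cis_or_trans[i], has_orf = sites$has_orf[i],
           pos = max(1L, as.integer(round(hl / 2))), seq = random_dna(300L, cfg$gc))
    },
    ir_loss = if (state$has_ir) list(type = "ir_loss") else NULL,
    reversal = if (!is.null(tpl$region)) tpl else sample_event(state, "reversal", cfg),
    ir_boundary_shift = if (!is.null(tpl$direction)) tpl
                        else sample_event(state, "ir_boundary_shift", cfg),
    tpl
  )
  full
}

#' Replay a truth log from the ancestor
#'
#' Applies the logged events branch by branch and re-renders the leaves;
#' the result must be identical to the recorded leaf genomes.
#'
#' @param truth a \code{cp_sim_truth}.
#' @return named list of re-rendered leaf genome sequences.
#' @export
replay_truth <- function(truth) {
  info <- tree_index(truth$tree)
  states <- vector("list", info$n_nodes)
  states[[info$root]] <- truth$ancestor
  by_branch <- list()
  for (e in truth$events) {
    if (isTRUE(e$skipped)) next
    by_branch[[e$branch]] <- e$events
  }
  out <- list()
  for (nd in rev(postorder_nodes(info))) {
    if (nd == info$root) next
    lab <- info$node_label[nd]
    st <- states[[info$parent[nd]]]
    for (ev in by_branch[[lab]]) st <- apply_event(st, ev)
    states[[nd]] <- st
    if (nd <= info$n_tips)
      out[[lab]] <- render_genome(st, taxon_id = lab)$genome$sequence
  }
  out
}

#' Write simulated fixtures to disk
#'
#' GenBank and GFF3+FASTA per leaf, the tree as newick and the truth log as
#' JSON; the flat files parse back losslessly through the genome readers.
#'
#' @param truth a \code{cp_sim_truth}.
#' @param out_dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
emit_fixtures <- function(truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (lab in names(truth$leaves)) {
    g <- truth$leaves[[lab]]$genome
    gb <- file.path(out_dir, paste0(lab, ".gbk"))
    gff <- file.path(out_dir, paste0(lab, ".gff3"))
    fa <- file.path(out_dir, paste0(lab, ".fasta"))
    write_genbank(g, gb)
    write_gff_fasta(g, gff, fa)
    paths <- c(paths, gb, gff, fa)
  }
  tw <- file.path(out_dir, "tree.nwk")
  ape::write.tree(truth$tree, tw)
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth$events, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tw, tj))
}
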