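make_tree <- function(txt) ape::read.tree(text = txt)

test_that("gene and intron matrices encode presence, absence and masking", {
  cfg <- small_sim_config(seed = 51)
  tree <- make_tree("((A:1,B:1):1,(C:1,D:1):1);")
  cfg$rates[] <- 0
  cfg$branch_events <- list(
    A = list(list(type = "gene_loss", gene = "atpA")),
    C = list(list(type = "intron_loss", site_label = "rpl16_9")))
  tr <- evolve_on_tree(simulate_ancestor(cfg), tree, cfg)
  genomes <- lapply(tr$leaves, function(x) x$genome)
  gm <- build_gene_matrix(genomes, catalog = cfg$catalog$gene)
  expect_equal(unname(gm$states[, "atpA"]), c(0L, 1L, 1L, 1L))
  expect_true(all(gm$states[, "rbcL"] == 1L))
  im <- build_intron_matrix(genomes)
  expect_equal(unname(im$states[, "rpl16_9"]), c(1L, 1L, 0L, 1L))
  # intron state is missing where the host gene is absent
  cfg2 <- small_sim_config(seed = 52)
  cfg2$rates[] <- 0
  cfg2$branch_events <- list(B = list(list(type = "gene_loss", gene = "rpl16")))
  tr2 <- evolve_on_tree(simulate_ancestor(cfg2), tree, cfg2)
  im2 <- build_intron_matrix(lapply(tr2$leaves, function(x) x$genome))
  expect_true(is.na(im2$states["B", "rpl16_9"]))
  expect_equal(unname(im2$states[c("A", "C", "D"), "rpl16_9"]), rep(1L, 3))
  # empty catalog gives an empty matrix; bad site catalog errors
  expect_equal(ncol(build_gene_matrix(genomes, catalog = character(0))$states), 0L)
  expect_error(build_intron_matrix(genomes,
    data.frame(host_gene = "nonsense", site_label = "nonsense_1")),
    "non-catalog")
})

test_that("Dollo mapping reproduces leaf states and counts minimal losses", {
  tree <- make_tree("((t1,t2),((t3,t4),t5));")
  m <- character_matrix(matrix(c(1L, 1L, 0L, 0L, 1L), 5, 1,
                               dimnames = list(paste0("t", 1:5), "c")),
                        kind = "gene")
  scn <- dollo_map(m, tree, assume_root_presence = TRUE)
  expect_equal(scn$per_character$n_losses, 1L)  # one loss above (t3,t4)
  expect_equal(scn$per_character$classification, "synapomorphic")
  # all-present character: no events
  m2 <- character_matrix(matrix(1L, 5, 1,
                                dimnames = list(paste0("t", 1:5), "c")))
  expect_equal(dollo_map(m2, tree)$losses, 0L)
  # absent character without root assumption warns and maps nothing
  m3 <- character_matrix(matrix(0L, 5, 1,
                                dimnames = list(paste0("t", 1:5), "c")),
                         kind = "intron")
  expect_warning(s3 <- dollo_map(m3, tree), "no presence")
  expect_equal(s3$losses, 0L)
})

test_that("Dollo loss counts equal the exhaustive oracle on random instances", {
  set.seed(202)
  checked <- 0L
  for (rep in 1:150) {
    nl <- sample(4:8, 1)
    tree <- ape::rtree(nl)
    tree$tip.label <- paste0("t", seq_len(nl))
    x <- sample(c(0L, 1L, NA), nl, TRUE, prob = c(0.4, 0.4, 0.2))
    names(x) <- tree$tip.label
    rp <- sample(c(TRUE, FALSE), 1)
    if (!any(!is.na(x) & x == 1) && !rp) next
    m <- character_matrix(matrix(x, ncol = 1,
                                 dimnames = list(names(x), "c")), kind = "gene")
    scn <- suppressWarnings(dollo_map(m, tree, assume_root_presence = rp))
    expect_equal(scn$per_character$n_losses, dollo_oracle(tree, x, rp),
                 info = paste(rp, paste(x, collapse = ",")))
    checked <- checked + 1L
  }
  expect_gte(checked, 100L)
})

test_that("reconstructed states honor observations and ? monotonicity", {
  set.seed(303)
  for (rep in 1:25) {
    nl <- sample(5:8, 1)
    tree <- ape::rtree(nl); tree$tip.label <- paste0("t", seq_len(nl))
    x <- sample(c(0L, 1L), nl, TRUE); names(x) <- tree$tip.label
    if (!any(x == 1)) x[sample(nl, 1)] <- 1L
    m <- character_matrix(matrix(x, ncol = 1, dimnames = list(names(x), "c")))
    n0 <- dollo_map(m, tree, TRUE)$per_character$n_losses
    # flipping an absence to missing can never increase the loss count
    zi <- which(x == 0L)
    if (length(zi)) {
      x2 <- x; x2[zi[1]] <- NA
      m2 <- character_matrix(matrix(x2, ncol = 1,
                                    dimnames = list(names(x2), "c")))
      expect_lte(dollo_map(m2, tree, TRUE)$per_character$n_losses, n0)
    }
    # the reconstruction covers every 0-leaf exactly once and no 1-leaf
    scn <- dollo_map(m, tree, TRUE)
    lb <- strsplit(scn$per_character$loss_branches, ",")[[1]]
    lb <- lb[nzchar(lb)]
    info <- cpevol:::tree_index(tree)
    covered <- as.character(unlist(info$below[match(lb, info$node_label)]))
    expect_setequal(intersect(covered, names(x)[x == 0L]),
                    names(x)[x == 0L])
    expect_false(any(names(x)[x == 1L] %in% covered))
  }
})

test_that("Fitch/Wagner mapping matches phangorn parsimony scores on binary data", {
  set.seed(404)
  for (rep in 1:20) {
    nl <- sample(4:8, 1)
    tree <- ape::rtree(nl); tree$tip.label <- paste0("t", seq_len(nl))
    x <- sample(c(0L, 1L), nl, TRUE); names(x) <- tree$tip.label
    m <- character_matrix(matrix(x, ncol = 1, dimnames = list(names(x), "c")))
    scn <- fitch_wagner_map(m, tree)
    total <- nrow(scn$per_branch)
    pd <- phangorn::phyDat(matrix(as.character(x), ncol = 1,
                                  dimnames = list(names(x), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(total, phangorn::parsimony(tree, pd))
    # Fitch allows repeated gains, so it never exceeds the Dollo total
    dl <- suppressWarnings(dollo_map(m, tree, assume_root_presence = FALSE))
    if (any(x == 1L))
      expect_lte(total, dl$per_character$n_losses + 1L)
  }
  # character present in a single leaf: one gain, no losses
  tree <- make_tree("((t1,t2),(t3,t4));")
  m <- character_matrix(matrix(c(1L, 0L, 0L, 0L), 4, 1,
                               dimnames = list(paste0("t", 1:4), "c")))
  scn <- fitch_wagner_map(m, tree)
  expect_equal(sum(scn$per_branch$event == "gain"), 1L)
  expect_equal(sum(scn$per_branch$event == "loss"), 0L)
})

test_that("two distant presence clades separate Dollo from Fitch", {
  tree <- make_tree("(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));")
  x <- c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L)
  names(x) <- paste0("t", 1:8)
  m <- character_matrix(matrix(x, ncol = 1, dimnames = list(names(x), "c")))
  dollo <- dollo_map(m, tree, assume_root_presence = FALSE)
  fitch <- fitch_wagner_map(m, tree)
  dollo_total <- dollo$per_character$n_losses + 1L  # gain + losses
  fitch_total <- nrow(fitch$per_branch)
  expect_lte(fitch_total, dollo_total)
  expect_equal(fitch_total, 2L)  # two independent gains
  expect_equal(dollo$per_character$n_losses, 2L)
})

test_that("event classification separates synapomorphic from homoplasic changes", {
  tree <- make_tree("((t1,t2),((t3,t4),t5));")
  m <- character_matrix(matrix(c(0L, 1L, 0L, 1L, 0L,
                                 1L, 1L, 0L, 0L, 1L), 5, 2,
                               dimnames = list(paste0("t", 1:5), c("h", "s"))))
  scn <- dollo_map(m, tree, assume_root_presence = TRUE)
  cls <- classify_events(scn)
  expect_equal(cls$per_character$classification[
    cls$per_character$character == "h"], "homoplasic")
  expect_equal(cls$per_character$classification[
    cls$per_character$character == "s"], "synapomorphic")
  expect_equal(cls$total_losses, scn$losses)
  expect_named(cls$loss_histogram)
})

test_that("matrix TSV and NEXUS round trips preserve states including missing", {
  m <- character_matrix(matrix(c(1L, 0L, NA, 1L, NA, 0L), 2, 3,
                               dimnames = list(c("ta", "tb"),
                                               c("c1", "c2", "c3"))),
                        kind = "intron")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_char_matrix(m, p1)
  expect_identical(read_char_matrix(p1, kind = "intron")$states, m$states)
  p2 <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(m, p2)
  expect_identical(unname(read_nexus_matrix(p2)$states), unname(m$states))
})
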