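test_that("simulation is deterministic and the ancestor is well formed", {
  cfg <- small_sim_config(seed = 81)
  r1 <- render_genome(simulate_ancestor(cfg), "anc")
  r2 <- render_genome(simulate_ancestor(cfg), "anc")
  expect_identical(r1$genome$sequence, r2$genome$sequence)
  # rDNA operon order inside the IR
  part <- partition_genes(r1$genome, r1$qmap)
  ir_genes <- part$gene[part$region == "IR"]
  expect_true(all(rdna_operon_genes() %in% ir_genes))
  ira_feats <- Filter(function(f) {
    p <- cpevol:::feature_start(f)
    p >= r1$qmap$ir_a[1] && p < r1$qmap$ir_a[2]
  }, r1$genome$features)
  op <- vapply(ira_feats, `[[`, character(1), "name")
  expect_equal(op[op %in% rdna_operon_genes()], rdna_operon_genes())
  # planted IR recovered exactly by detection
  q <- detect_inverted_repeat(r1$genome)
  expect_equal(q$ir_length, r1$qmap$ir_length)
})

test_that("zero rates leave the leaves identical to the ancestor", {
  cfg <- small_sim_config(seed = 82)
  cfg$rates[] <- 0
  anc <- simulate_ancestor(cfg)
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  tr <- evolve_on_tree(anc, tree, cfg)
  anc_seq <- render_genome(anc, "x")$genome$sequence
  for (lab in c("A", "B", "C"))
    expect_identical(tr$leaves[[lab]]$genome$sequence, anc_seq)
})

test_that("a single planted reversal yields reversal distance one", {
  cfg <- small_sim_config(seed = 83)
  cfg$rates[] <- 0
  cfg$branch_events <- list(A = list(list(type = "reversal")))
  anc <- simulate_ancestor(cfg)
  tree <- ape::read.tree(text = "(A:1,B:1);")
  tr <- evolve_on_tree(anc, tree, cfg)
  oa <- extract_signed_order(tr$leaves$A$genome, qmap = tr$leaves$A$qmap,
                             dedup = "one-ir-copy")
  ob <- extract_signed_order(tr$leaves$B$genome, qmap = tr$leaves$B$qmap,
                             dedup = "one-ir-copy")
  expect_equal(reversal_distance(oa, ob)$distance, 1L)
})

test_that("homoplasy-free planted losses are recovered exactly by Dollo mapping", {
  cfg <- small_sim_config(seed = 84)
  cfg$rates[] <- 0
  tree <- ape::read.tree(text = "((A,B)ab,(C,(D,E)de)cde)r;")
  cfg$branch_events <- list(
    ab = list(list(type = "gene_loss", gene = "petA")),
    C  = list(list(type = "gene_loss", gene = "psbA"),
              list(type = "intron_loss", site_label = "atpF_145")),
    de = list(list(type = "intron_loss", site_label = "rpl16_9")),
    E  = list(list(type = "ir_loss")))
  tr <- evolve_on_tree(simulate_ancestor(cfg), tree, cfg)
  genomes <- lapply(tr$leaves, function(x) x$genome)
  gm <- build_gene_matrix(genomes, catalog = cfg$catalog$gene)
  scn <- dollo_map(gm, tree)
  pg <- scn$per_character
  expect_equal(pg$loss_branches[pg$character == "petA"], "ab")
  expect_equal(pg$loss_branches[pg$character == "psbA"], "C")
  expect_equal(sum(pg$n_losses), 2L)
  im <- build_intron_matrix(genomes)
  scn_i <- dollo_map(im, tree, assume_root_presence = TRUE)
  pi <- scn_i$per_character
  expect_equal(pi$loss_branches[pi$character == "atpF_145"], "C")
  expect_equal(pi$loss_branches[pi$character == "rpl16_9"], "de")
  # planted IR loss recovered from detection + Dollo
  irs <- vapply(names(tr$leaves), function(lab)
    detect_inverted_repeat(tr$leaves[[lab]]$genome)$has_ir, logical(1))
  mir <- character_matrix(matrix(as.integer(irs), ncol = 1,
                                 dimnames = list(names(irs), "IR")),
                          kind = "ir")
  scn_ir <- dollo_map(mir, tree, assume_root_presence = TRUE)
  expect_equal(scn_ir$per_character$loss_branches, "E")
})

test_that("IR events are mirrored and boundary shifts move whole genes", {
  cfg <- small_sim_config(seed = 85)
  cfg$rates[] <- 0
  cfg$branch_events <- list(
    A = list(list(type = "ir_boundary_shift", direction = "expand_lsc")),
    B = list(list(type = "gene_loss", gene = "rrf")))
  # rrf is protected (operon); expect it skipped, leaving B untouched
  cfg$branch_events$B <- list(list(type = "ir_boundary_shift",
                                   direction = "expand_ssc"))
  tree <- ape::read.tree(text = "(A:1,B:1);")
  tr <- evolve_on_tree(simulate_ancestor(cfg), tree, cfg)
  qa <- detect_inverted_repeat(tr$leaves$A$genome)
  qb <- detect_inverted_repeat(tr$leaves$B$genome)
  anc_q <- render_genome(simulate_ancestor(cfg), "anc")$qmap
  expect_gt(qa$ir_length, anc_q$ir_length)
  expect_gt(qb$ir_length, anc_q$ir_length)
  # the duplicated boundary gene now appears twice in the A genome
  dup_a <- table(vapply(tr$leaves$A$genome$features, `[[`, character(1),
                        "name"))
  anc_dup <- table(vapply(render_genome(simulate_ancestor(cfg),
                                        "x")$genome$features, `[[`,
                          character(1), "name"))
  expect_gt(sum(dup_a == 2), sum(anc_dup == 2))
})

test_that("the truth log replays to identical leaf genomes", {
  cfg <- small_sim_config(seed = 86)
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr <- evolve_on_tree(simulate_ancestor(cfg), tree, cfg)
  rp <- replay_truth(tr)
  for (lab in names(rp))
    expect_identical(rp[[lab]], tr$leaves[[lab]]$genome$sequence)
})

test_that("emitted fixtures parse back losslessly", {
  cfg <- small_sim_config(seed = 87)
  tree <- ape::read.tree(text = "(A:1,B:1);")
  tr <- evolve_on_tree(simulate_ancestor(cfg), tree, cfg)
  dir <- withr::local_tempdir()
  emit_fixtures(tr, dir)
  expect_true(file.exists(file.path(dir, "tree.nwk")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  for (lab in c("A", "B")) {
    g0 <- tr$leaves[[lab]]$genome
    g1 <- read_genbank(file.path(dir, paste0(lab, ".gbk")))
    g2 <- read_gff_fasta(file.path(dir, paste0(lab, ".gff3")),
                         file.path(dir, paste0(lab, ".fasta")))
    expect_identical(g1$sequence, g0$sequence)
    expect_identical(g2$sequence, g0$sequence)
    expect_equal(length(g1$features), length(g0$features))
    expect_equal(length(g2$features), length(g0$features))
  }
})

test_that("planted per-branch reversals are usually recovered as the pairwise distance", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    cfg <- small_sim_config(seed = 900 + seed)
    cfg$rates[] <- 0
    k1 <- sample(0:3, 1); k2 <- sample(1:3, 1)
    cfg$branch_events <- list(
      A = replicate(k1, list(type = "reversal"), simplify = FALSE),
      B = replicate(k2, list(type = "reversal"), simplify = FALSE))
    tree <- ape::read.tree(text = "(A:1,B:1);")
    tr <- evolve_on_tree(simulate_ancestor(cfg), tree, cfg)
    oa <- extract_signed_order(tr$leaves$A$genome, qmap = tr$leaves$A$qmap,
                               dedup = "one-ir-copy")
    ob <- extract_signed_order(tr$leaves$B$genome, qmap = tr$leaves$B$qmap,
                               dedup = "one-ir-copy")
    d <- reversal_distance(oa, ob)$distance
    expect_lte(d, k1 + k2)
    total <- total + 1L
    if (d == k1 + k2) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.8)
})
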