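test_that("signed orders follow coordinates, strands and dedup rules", {
  g <- annotated_genome("t", strrep("ACGT", 300), "circular", list(
    gene_feature("a", "protein", c(10, 100), 1L),
    gene_feature("b", "protein", c(150, 300), -1L),
    gene_feature("c", "tRNA", c(400, 470), 1L)))
  o <- extract_signed_order(g)
  expect_equal(o$genes$symbol, c("a", "b", "c"))
  expect_equal(o$genes$sign, c(1L, -1L, 1L))
  # duplicated gene in both IR copies collapses under one-ir-copy
  cfg <- small_sim_config(seed = 41)
  r <- render_genome(simulate_ancestor(cfg), "anc")
  keep_all <- extract_signed_order(r$genome, dedup = "keep-all")
  one <- extract_signed_order(r$genome, qmap = r$qmap, dedup = "one-ir-copy")
  expect_equal(sum(keep_all$genes$symbol == "rrs"), 2L)
  expect_equal(sum(one$genes$symbol == "rrs"), 1L)
  expect_false(anyDuplicated(one$genes$symbol) > 0)
  # truth order from the simulator log equals the extracted order
  expect_equal(keep_all$genes$symbol, r$order$genes$symbol)
})

test_that("signed adjacencies are canonical and invariant to rotation/reflection", {
  o <- signed_order("t", c("a", "b", "c"), c(1, 1, 1))
  adj <- signed_adjacencies(o)
  expect_length(adj, 3L)
  expect_setequal(adj, c(canonical_set <- cpevol:::canonical_pair(
    c("a", "b", "c"), c(1, 1, 1), c("b", "c", "a"), c(1, 1, 1))))
  lin <- signed_order("t", c("a", "b"), c(1, 1), topology = "linear")
  expect_length(signed_adjacencies(lin), 1L)
  set.seed(5)
  for (rep in 1:10) {
    o1 <- random_order(8)
    g <- o1$genes
    rot <- sample(8, 1)
    g2 <- g[((seq_len(8) + rot - 1L) %% 8L) + 1L, ]
    o2 <- structure(list(taxon_id = "t", genes = g2, topology = "circular"),
                    class = "cp_gene_order")
    g3 <- g[rev(seq_len(8)), ]; g3$sign <- -g3$sign
    o3 <- structure(list(taxon_id = "t", genes = g3, topology = "circular"),
                    class = "cp_gene_order")
    expect_setequal(signed_adjacencies(o1), signed_adjacencies(o2))
    expect_setequal(signed_adjacencies(o1), signed_adjacencies(o3))
  }
})

test_that("shared pair matrix applies the min-taxa rule and loss masking", {
  o1 <- signed_order("t1", letters[1:5], rep(1, 5))
  o2 <- signed_order("t2", letters[1:5], rep(1, 5))
  o3 <- signed_order("t3", c("a", "b", "d", "c", "e"), c(1, 1, -1, -1, 1))
  o4 <- signed_order("t4", letters[1:4], rep(1, 4))   # gene e lost
  pm <- shared_pair_matrix(list(o1, o2, o3, o4), min_taxa = 3L)
  m <- pm$states
  # pairs involving the lost gene e are missing, not absent, in t4
  e_pairs <- grepl("e", colnames(m))
  expect_true(all(is.na(m["t4", e_pairs])))
  expect_true(all(m["t4", !e_pairs] %in% c(0L, 1L)))
  # a pair occurring in fewer than min_taxa genomes is excluded
  all_adj <- table(unlist(lapply(list(o1, o2, o3, o4),
                                 signed_adjacencies)))
  rare <- names(all_adj)[all_adj < 3]
  expect_false(any(rare %in% colnames(m)))
  # identical orders give an all-1 matrix
  pm2 <- shared_pair_matrix(list(o1, o2, signed_order("t9", letters[1:5], rep(1, 5))))
  expect_true(all(pm2$states == 1L))
})

test_that("synteny blocks match hand enumeration on toy orders", {
  a <- signed_order("a", letters[1:6], rep(1, 6), topology = "linear")
  b <- signed_order("b", c("a", "b", "e", "d", "c", "f"),
                    c(1, 1, -1, -1, -1, 1), topology = "linear")
  bl <- synteny_blocks(a, b)
  expect_equal(nrow(bl), 3L)
  expect_equal(attr(bl, "breakpoints"), 2L)
  expect_equal(bl$orientation, c("same", "inverted", "same"))
  # identical circular orders, arbitrary rotation: one block, no breakpoints
  a2 <- signed_order("a", letters[1:6], rep(1, 6))
  b2 <- signed_order("b", c(letters[3:6], letters[1:2]), rep(1, 6))
  bl2 <- synteny_blocks(a2, b2)
  expect_equal(nrow(bl2), 1L)
  expect_equal(attr(bl2, "breakpoints"), 0L)
  expect_equal(bl2$n_genes, 6L)
  # symmetry of block count and the breakpoint/reversal-distance bound
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(5:10, 1)
    oa <- random_order(n, "A")
    g <- oa$genes[sample(n), ]; g$sign <- g$sign * sample(c(-1L, 1L), n, TRUE)
    ob <- structure(list(taxon_id = "B", genes = g, topology = "circular"),
                    class = "cp_gene_order")
    nab <- nrow(synteny_blocks(oa, ob))
    nba <- nrow(synteny_blocks(ob, oa))
    expect_equal(nab, nba)
    d <- reversal_distance(oa, ob)$distance
    expect_lte(nab - 1L, 2L * d)
  }
})

test_that("missing genes split into internal excisions and breakpoint-associated losses", {
  a <- signed_order("A", c("a", "b", "x", "c", "d"), rep(1, 5),
                    topology = "linear")
  b <- signed_order("B", c("a", "b", "c", "d"), rep(1, 4), topology = "linear")
  cls <- classify_missing_genes(a, b, synteny_blocks(a, b))
  expect_equal(cls$class[cls$gene == "x"], "internal excision")
  b2 <- signed_order("B", c("c", "d", "a", "b"), rep(1, 4), topology = "linear")
  cls2 <- classify_missing_genes(a, b2, synteny_blocks(a, b2))
  expect_equal(cls2$class[cls2$gene == "x"], "breakpoint-associated")
  # genes absent from both orders are not classified
  expect_false("zz" %in% cls$gene)
})
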