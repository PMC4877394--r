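test_that("a planted IR is recovered at exactly the planted coordinates", {
  g <- planted_ir_genome(seed = 2, lsc = 6000, ir_len = 1500, ssc = 900)
  q <- detect_inverted_repeat(g, min_len = 1000)
  expect_true(q$has_ir)
  expect_equal(q$ir_length, 1500L)
  expect_equal(q$identity, 1)
  L <- nchar(g$sequence)
  expect_equal(q$ir_a, c(6000, 7500))
  expect_equal(q$ir_b, c(8400, 9900))
  # tiling invariant
  len <- function(iv) (iv[2] - iv[1]) %% L
  expect_equal(len(q$ir_a) + len(q$ir_b) + len(q$ssc) + len(q$lsc), L)
  expect_lte(len(q$ssc), len(q$lsc))
})

test_that("simulated quadripartite genomes are mapped exactly as planted", {
  cfg <- small_sim_config(seed = 31)
  r <- render_genome(simulate_ancestor(cfg), "anc")
  q <- detect_inverted_repeat(r$genome)
  expect_true(q$has_ir)
  expect_equal(q$ir_length, r$qmap$ir_length)
  expect_equal(q$ir_a, r$qmap$ir_a)
  expect_equal(q$ir_b, r$qmap$ir_b)
  expect_equal(q$ssc, r$qmap$ssc)
  expect_equal(q$lsc, r$qmap$lsc)
})

test_that("sequences without a long repeat report no IR", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")
  g <- annotated_genome("r", s, "circular")
  q <- detect_inverted_repeat(g, min_len = 1000)
  expect_false(q$has_ir)
  expect_warning(detect_inverted_repeat(
    annotated_genome("s", "ACGTACGT", "circular"), min_len = 1000),
    "shorter")
})

test_that("detection is invariant under rotation and reverse complement", {
  g <- planted_ir_genome(seed = 9, lsc = 4000, ir_len = 1200, ssc = 700)
  q0 <- detect_inverted_repeat(g, min_len = 1000)
  L <- nchar(g$sequence)
  for (shift in c(1234L, 5000L)) {
    s2 <- paste0(substr(g$sequence, shift + 1, L), substr(g$sequence, 1, shift))
    q2 <- detect_inverted_repeat(annotated_genome("rot", s2, "circular"),
                                 min_len = 1000)
    expect_true(q2$has_ir)
    expect_equal(q2$ir_length, q0$ir_length)
    expect_equal((q2$ssc[2] - q2$ssc[1]) %% L, (q0$ssc[2] - q0$ssc[1]) %% L)
  }
  rc <- annotated_genome("rc", cpevol:::revcomp(g$sequence), "circular")
  qr <- detect_inverted_repeat(rc, min_len = 1000)
  expect_equal(qr$ir_length, q0$ir_length)
  expect_equal((qr$lsc[2] - qr$lsc[1]) %% L, (q0$lsc[2] - q0$lsc[1]) %% L)
})

test_that("genes are partitioned by majority region and straddlers flagged", {
  cfg <- small_sim_config(seed = 32)
  r <- render_genome(simulate_ancestor(cfg), "anc")
  part <- partition_genes(r$genome, r$qmap)
  expect_true(all(part$region[part$gene %in% rdna_operon_genes()] == "IR"))
  expect_true(all(part$region %in% c("IR", "SSC", "LSC")))
  # constructed straddler: 60% of the gene inside the SSC
  q <- r$qmap
  straddle <- gene_feature("straddler", "protein",
                           c(q$ssc[1] - 40, q$ssc[1] + 60), 1L)
  g2 <- r$genome
  g2$features <- c(g2$features, list(straddle))
  g2 <- annotated_genome(g2$taxon_id, g2$sequence, g2$topology, g2$features)
  p2 <- partition_genes(g2, q)
  row <- p2[p2$gene == "straddler", ]
  expect_equal(row$region, "SSC")
  expect_true(row$straddles)
  # IR-less genome: single region, no straddling
  noir <- structure(list(has_ir = FALSE, ir_a = NULL, ir_b = NULL,
                         ssc = NULL, lsc = NULL, ir_length = 0L,
                         identity = NA_real_), class = "cp_qmap")
  expect_true(all(partition_genes(r$genome, noir)$region == "SC"))
})

test_that("segregation violations are exact against brute-force removal", {
  # reference pattern scores zero against itself
  cfg <- small_sim_config(seed = 33)
  r <- render_genome(simulate_ancestor(cfg), "anc")
  sides <- ancestral_sides(r$genome, r$qmap)
  ord <- extract_signed_order(r$genome, qmap = r$qmap, dedup = "one-ir-copy")
  expect_equal(classify_partitioning(ord, sides)$segregation_violations, 0L)
  # a single translocated gene costs one removal
  g <- ord$genes
  ssc_idx <- which(sides$ancestral_side[match(g$symbol, sides$gene)] == "ssc-side")
  lsc_idx <- which(sides$ancestral_side[match(g$symbol, sides$gene)] == "lsc-side")
  stopifnot(length(ssc_idx) > 2, length(lsc_idx) > 10)
  mv <- ssc_idx[2]
  g2 <- rbind(g[setdiff(seq_len(nrow(g)), mv)[1:5], ], g[mv, ],
              g[setdiff(seq_len(nrow(g)), mv)[-(1:5)], ])
  o2 <- structure(list(taxon_id = "t", genes = g2, topology = "circular"),
                  class = "cp_gene_order")
  expect_equal(classify_partitioning(o2, sides)$segregation_violations, 1L)
  # random circular binary patterns match the exhaustive oracle
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:11, 1)
    x <- sample(0:1, n, TRUE)
    sdf <- data.frame(gene = paste0("g", 1:n),
                      ancestral_side = ifelse(x == 1, "ssc-side", "lsc-side"))
    oo <- signed_order("t", paste0("g", 1:n), rep(1L, n))
    expect_equal(classify_partitioning(oo, sdf)$segregation_violations,
                 segregation_oracle(x))
  }
  # warning when the reference shares too few genes
  few <- data.frame(gene = "g1", ancestral_side = "ssc-side")
  expect_warning(classify_partitioning(oo, few), "50%")
})
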