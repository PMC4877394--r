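test_that("G+C content handles edge cases and complement symmetry", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ACGTN"), 0.5)   # N excluded from the denominator
  expect_error(gc_content(""), "empty")
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_equal(gc_content(s), gc_content(cpevol:::revcomp(s)))
})

test_that("codon-position G+C recovers planted positionwise composition", {
  expect_equal(gc_by_codon_position("GATGAT"), c(1, 0, 0))
  expect_error(gc_by_codon_position(character(0)), "empty")
  # genes with planted per-position base probabilities
  set.seed(22)
  probs <- list(c(G = 0.8, A = 0.2), c(C = 0.3, T = 0.7), c(G = 0.5, A = 0.5))
  genes <- replicate(30, {
    n <- sample(50:150, 1)
    paste(vapply(seq_len(3 * n), function(i) {
      p <- probs[[(i - 1) %% 3 + 1]]
      sample(names(p), 1, prob = p)
    }, character(1)), collapse = "")
  })
  got <- gc_by_codon_position(genes)
  expect_equal(got, c(0.8, 0.3, 0.5), tolerance = 0.02)
  # weighted-mean consistency with per-gene values
  per_gene <- vapply(genes, gc_by_codon_position, numeric(3))
  w <- vapply(genes, function(g) nchar(g) %/% 3, numeric(1))
  expect_equal(got, as.numeric(per_gene %*% w / sum(w)), tolerance = 1e-12)
  # internal stop codons raise a warning
  expect_warning(gc_by_codon_position(c("ATGTAAGGG")), "stop")
})

test_that("maximal repeat pairs equal the quadratic diagonal oracle", {
  set.seed(31)
  for (rep in 1:4) {
    bg <- paste(sample(c("A", "C", "G", "T"), 1800, TRUE), collapse = "")
    el <- paste(sample(c("A", "C", "G", "T"), sample(32:60, 1), TRUE),
                collapse = "")
    ins <- sort(sample(seq(100, 1500, by = 50), 3))
    s <- paste0(substr(bg, 1, ins[1]), el,
                substr(bg, ins[1] + 1, ins[2]), el,
                substr(bg, ins[2] + 1, ins[3]), cpevol:::revcomp(el),
                substr(bg, ins[3] + 1, 1800))
    got <- as.data.frame(find_repeats(s, min_len = 30))
    got <- got[order(got$type, got$start1, got$start2),
               c("type", "start1", "start2", "length")]
    rownames(got) <- NULL
    want <- repeat_oracle(s, 30)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("planted repeats are found and random sequence is nearly repeat free", {
  set.seed(41)
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  el <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  s <- paste0(substr(bg, 1, 600), el, substr(bg, 601, 2000), el,
              substr(bg, 2001, 3200), el, substr(bg, 3201, 4000))
  rp <- find_repeats(s, 30)
  expect_equal(sum(rp$type == "direct"), 3L)    # all three copy pairs
  expect_gte(sum(IRanges::width(attr(rp, "masked"))), 120L)
  # palindromic construction yields an inverted repeat
  pal <- paste0(substr(bg, 1, 1000), el, substr(bg, 1001, 1400),
                cpevol:::revcomp(el), substr(bg, 1401, 2000))
  rp2 <- find_repeats(pal, 30)
  expect_true(any(rp2$type == "inverted"))
  # 100 kb random sequence: expected 30-mer collisions are negligible
  big <- paste(sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = "")
  rp3 <- find_repeats(big, 30)
  expect_lt(sum(IRanges::width(attr(rp3, "masked"))) / 1e5, 0.001)
})

test_that("repeat summaries separate repeat and unique composition", {
  set.seed(51)
  at_bg <- paste(sample(c("A", "T"), 3000, TRUE, prob = c(.5, .5)), collapse = "")
  gc_el <- paste(sample(c("G", "C"), 60, TRUE), collapse = "")
  s <- paste0(substr(at_bg, 1, 1000), gc_el, substr(at_bg, 1001, 2000),
              gc_el, substr(at_bg, 2001, 3000))
  rp <- find_repeats(s, 30)
  sm <- repeat_summary(s, rp)
  expect_gt(sm$gc_repeat, sm$gc_unique)
  expect_gt(sm$masked_fraction, 0)
  # no repeats: unique G+C is the genome G+C
  set.seed(52)
  r <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  rp0 <- find_repeats(r, 30)
  sm0 <- repeat_summary(r, rp0)
  expect_equal(sm0$masked_fraction, 0)
  expect_equal(sm0$gc_unique, 100 * gc_content(r))
  # soft masking lower-cases exactly the masked positions
  msk <- soft_mask(s, rp)
  expect_equal(sum(grepl("[acgt]", strsplit(msk, "")[[1]])),
               sum(IRanges::width(attr(rp, "masked"))))
})

test_that("colinear divergence counts substitutions and indel events exactly", {
  set.seed(61)
  g <- paste(sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = "")
  dv0 <- colinear_divergence(g, g)
  expect_equal(dv0$total_sites, 0L)
  expect_equal(dv0$aligned_fraction, 1)
  v <- strsplit(g, "")[[1]]
  pos <- seq(5000, 95000, by = 10000)          # 10 well-separated sites
  w <- v
  for (p in pos) w[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  w <- w[-c(20000:20001, 50000:50003)]         # deletions of 2 and 4 bp
  dv <- colinear_divergence(g, paste(w, collapse = ""))
  expect_equal(dv$substitution_sites, 10L)
  expect_equal(dv$indel_events, 2L)
  expect_setequal(dv$indel_lengths, c(2L, 4L))
  expect_equal(dv$total_sites, 12L)
  # substitution count is symmetric under swapping the genomes
  dv_swap <- colinear_divergence(paste(w, collapse = ""), g)
  expect_equal(dv_swap$substitution_sites, dv$substitution_sites)
  # unrelated sequences are declared non-colinear
  set.seed(62)
  u <- paste(sample(c("A", "C", "G", "T"), 5e4, TRUE), collapse = "")
  expect_warning(dvu <- colinear_divergence(g, u), "colinear")
  expect_false(dvu$colinear)
})

test_that("the decoding audit flags codons without a matching tRNA", {
  cfg <- small_sim_config(seed = 71)
  full_cat <- gene_catalog("ancestral")
  cfg$catalog <- full_cat   # all 35 ancestral tRNAs present
  r <- render_genome(simulate_ancestor(cfg), "anc")
  aud <- codon_decoding_audit(r$genome, superwobble = TRUE)
  expect_length(aud$undecodable, 0L)
  # removing every tRNA-Thr leaves all used ACN codons unreadable
  g2 <- r$genome
  g2$features <- Filter(function(f) !grepl("^trnT\\(", f$name), g2$features)
  aud2 <- codon_decoding_audit(g2, superwobble = TRUE)
  acn <- intersect(paste0("AC", c("A", "C", "G", "T")), names(aud2$usage))
  expect_setequal(intersect(aud2$undecodable, acn), acn)
  expect_gt(length(acn), 0L)
  # strict wobble is reported as a subset relation
  aud3 <- codon_decoding_audit(r$genome, superwobble = FALSE)
  expect_true(all(aud$undecodable %in% aud3$undecodable))
  # no CDS: empty audit
  g3 <- r$genome
  g3$features <- Filter(function(f) f$category != "protein", g3$features)
  aud4 <- codon_decoding_audit(g3)
  expect_length(aud4$usage, 0L)
  expect_length(aud4$undecodable, 0L)
})
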