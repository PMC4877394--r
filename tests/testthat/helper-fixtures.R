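# Shared fixtures built in code.

# a reduced simulation configuration for fast tests: 40-gene catalog
# including the rDNA operon, short proteins and spacers
small_sim_config <- function(seed = 1L, ...) {
  cat <- gene_catalog("ancestral")
  must <- c(rdna_operon_genes(), "trnR(acg)", "petA", "psbA", "rbcL",
            "atpA", default_intron_sites()$host_gene)
  keep <- unique(c(must, head(setdiff(cat$gene, must), 40 - length(unique(must)))))
  simulation_config(seed = seed, catalog = cat[cat$gene %in% keep, ],
                    ssc_n = 6L, spacer_range = c(30L, 80L),
                    protein_len_range = c(40L, 120L), ...)
}

# hand-written ~1 kb two-gene GenBank record (plus-strand CDS and a
# minus-strand two-exon tRNA), coordinates checked by eye
two_gene_genbank <- function(path) {
  set.seed(404)
  seqs <- paste(sample(c("a", "c", "g", "t"), 1000, TRUE), collapse = "")
  lines <- c(
    "LOCUS       toy01 1000 bp    DNA     circular   UNA",
    "DEFINITION  toy fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     CDS             101..400",
    "                     /gene=\"rbcL\"",
    "     tRNA            complement(join(501..535,601..637))",
    "                     /gene=\"trnK-UUU\"",
    "ORIGIN"
  )
  pos <- seq(1, 1000, by = 60)
  for (p in pos) {
    chunk <- substr(seqs, p, min(p + 59, 1000))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

# GenBank record with a feature wrapping the origin of a circular sequence
wrapping_genbank <- function(path) {
  set.seed(405)
  seqs <- paste(sample(c("a", "c", "g", "t"), 600, TRUE), collapse = "")
  lines <- c(
    "LOCUS       toy02 600 bp    DNA     circular   UNA",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "     CDS             join(551..600,1..70)",
    "                     /gene=\"psbA\"",
    "ORIGIN"
  )
  pos <- seq(1, 600, by = 60)
  for (p in pos) {
    chunk <- substr(seqs, p, min(p + 59, 600))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

# circular genome with a planted exact IR of ir_len around an SSC
planted_ir_genome <- function(seed = 2, lsc = 6000, ir_len = 1500, ssc = 900) {
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # flanking bases chosen to break complementarity at all four junctions
  ir <- rnd(ir_len)
  s <- paste0(rnd(lsc - 1), "A", ir, "A", rnd(ssc - 2), "A",
              cpevol:::revcomp(ir), "A")
  annotated_genome("planted", s, "circular",
                   list(gene_feature("rrs", "rRNA",
                                     c(lsc + 10, lsc + 110), 1L)))
}

random_order <- function(n, taxon = "t", topology = "circular") {
  signed_order(taxon, paste0("g", sample(n)), sample(c(-1L, 1L), n, TRUE),
               topology = topology)
}
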