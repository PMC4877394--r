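---
title: "Methods: comparative structural analysis of chloroplast genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural analysis of chloroplast genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpevol)
```

# Scope and data model

`cpevol` analyses the structural evolution of chloroplast genomes:
quadripartite (IR/SSC/LSC) architecture, signed gene order, gene / intron /
gene-pair content, and sequence-level statistics, together with a simulator
that generates annotated genomes with a known event history.

All coordinates inside the package are 0-based half-open; GenBank and GFF3
use 1-based inclusive coordinates and are converted only at the I/O
boundary, so interval arithmetic is unambiguous. On circular sequences an
exon whose end is not greater than its start wraps the origin. Features are
spliced in transcription order, so a minus-strand multi-exon gene lists its
rightmost exon first.

The gene nomenclature follows plastid conventions, with tRNA anticodons in
parentheses (`trnK(uuu)`), and a synonym table maps common source spellings
(`trnK-UUU`, `23S ribosomal RNA`, ...) onto that catalog. The ancestral
streptophyte gene complement is fixed at 144 standard genes, of which 90
(63 protein, 24 tRNA, 3 rRNA genes) are retained in every compared genome;
the remaining 54 (42 protein-coding genes, 11 tRNA genes and the tmRNA gene
`ssrA`) were each lost at least once. The retained list is taken verbatim
from the study metadata shipped with the package; for the lost portion, the
genes identified by name in the underlying analyses are used and the
remainder is filled with standard plastid genes commonly reported in basal
streptophytes (e.g. `ftsI`, `ftsW`, `minE`, `ycf20`, `ycf47`,
`trnL(caa)`). Only the 144/90/54 bookkeeping is treated as a fixed
constraint; individual filler identities affect no computed statistic. A
`shared89` variant drops `rrf`, the one rRNA gene whose identification was
contentious in one genome, for rearrangement analyses that were defined on
an 89-gene common set; both the 90- and 89-gene sets are selectable through
`gene_catalog()`.

# Quadripartite architecture

`detect_inverted_repeat()` searches for the longest pair of disjoint,
reverse-complementary segments of at least `min_len` bp (default 1000 bp,
well below any biological plastid IR but above background repeat length).
Matching is exact by default because the two IR copies of assembled
chloroplast genomes are homogenized by concerted evolution and deposited as
identical sequences; `max_mismatch_frac > 0` enables a greedy
seed-and-extend mode for divergent copies. Seeds are 31-mers sampled
sparsely from the doubled sequence (so detection is rotation invariant on
circles) and extended maximally; when several disjoint candidate pairs tie
in length, a pair whose copies contain an annotated rRNA gene wins — the IR
of interest is by definition the one carrying the rDNA operon — and any
remaining tie goes to the smallest start coordinate. The shorter of the two
single-copy gaps is the SSC, purely by length, even where gene content is
unusual.

Genes are assigned to regions by the majority of their coding length, with
junction-straddling genes flagged. Ancestral "sides" (`ssc-side`,
`lsc-side`, `rdna`) are read off a reference genome with an ancestral
partitioning pattern; IR-resident non-operon genes take the side of the
nearer junction. The segregation score of a target genome is the minimum
number of genes whose removal leaves the ssc-side and lsc-side genes in two
contiguous circular arcs. Because the optimal two-arc split can be
enumerated over all (start, length) arcs in O(n²) for the ~100-gene orders
involved, the score is computed exactly for every input; the exhaustive
subset-removal oracle in the test suite checks it on small instances.

# Gene order, adjacencies and synteny

Signed gene orders follow genomic coordinates; the sign is the coding
strand. For analyses that require one copy per gene, `one-ir-copy`
deduplication drops the IR-B copy (the copy inside the second repeat), and
any residual duplicate keeps its lowest-coordinate copy with a logged
message — a deterministic rule where the underlying studies are silent.

Signed adjacencies are canonicalized so a pair and its reverse complement,
(a,b) and (−b,−a), are the same character; adjacency sets are therefore
invariant under genome rotation and reflection. The shared-pair matrix
keeps pairs present in at least `min_taxa` genomes (default 3) and codes a
pair as missing (`?`) rather than absent in any genome that has lost either
member gene, so gene loss is not double-counted as rearrangement.

Synteny blocks are maximal runs of genes consecutive in both genomes with
consistent relative orientation, computed on the common gene set; genes
unique to one genome are invisible to block boundaries and are handled
afterwards by `classify_missing_genes()`, which calls a missing gene an
internal excision when its nearest shared flanks are adjacent inside one
block, and breakpoint-associated otherwise. Blocks may be singletons; a
`min_block_genes` threshold can flag them. On circular orders the block
spanning the arbitrary linearization point is re-merged, making block
counts rotation invariant and symmetric in the two genomes.

# Reversal distance

The signed reversal distance is computed exactly from the breakpoint graph
under the standard capping: d = n + 1 − c + h + f, with c the number of
cycles, h the number of hurdles (unoriented components that are minimal
under span containment, plus the greatest component when it contains all
others), and f the fortress indicator (an odd number of hurdles, all of
them super-hurdles). Circular orders are reduced to a canonical linear
representative by cutting at the lexicographically smallest shared gene,
fixed at +1 (reflecting the whole circle if needed) and removing it — the
anchor plays the role of the linear frame — which makes distances invariant
under rotation and reflection of either genome.

The implementation is validated against an independent breadth-first-search
oracle over the full reversal graph: distance tables are built once per
permutation size (feasible to n = 7, 645,120 signed permutations) and the
suite checks hundreds of random pairs, which exercises cycle counting,
orientation and hurdle handling. Fortresses cannot occur at these sizes;
the fortress code path follows the published case analysis and is exercised
only through the h/f bookkeeping identity.

Branch lengths on a fixed topology are fitted by nonnegative least squares
(`pracma::lsqnonneg`) of additive path sums to the pairwise distance
matrix. This is deliberately a distance-based approximation: median-genome
(ancestral gene order) reconstruction is NP-hard and outside the package's
verifiable surface, so outputs are labelled approximate branch lengths. For
a rooted binary tree the two root-adjacent branches are confounded (only
their sum is identifiable from leaf-to-leaf distances); fitted path sums,
not individual root branches, are the meaningful quantity.

# Character evolution

Characters are binary with missing states (`1`/`0`/`?`). Under Dollo
parsimony a character is gained once — at the root for the ancestral gene
complement (`assume_root_presence = TRUE`, the default for gene
characters), or at the most recent common ancestor of the taxa carrying it
(the default for intron, gene-pair and IR characters) — and lost on a
minimal set of branches such that every observed absence lies below exactly
one loss and no observed presence below any. The minimal set is found by
taking each maximal presence-free subtree containing an absence;
within such a subtree any branch covering its absences is equally
parsimonious, and the package deterministically picks the deepest one (the
branch above the MRCA of the covered absences — the latest possible loss),
reporting the number of alternative placements. Missing states constrain
nothing; they are handled in the subtree logic directly rather than by
pruning taxa, so the topology is not distorted. When presence is assumed at
the root but observed nowhere, losses are placed on root-child branches,
since the root itself has no branch.

`fitch_wagner_map()` implements unit-cost small parsimony (Sankoff dynamic
programming) allowing repeated gains; for binary characters ordered
(Wagner) and unordered (Fitch) costs coincide. Backtrack ties prefer the
parent's state, then absence, for reproducibility. Events are classified
synapomorphic (exactly one event) or homoplasic (more than one).
Correctness is established against exhaustive enumeration over loss-branch
subsets (and all admissible gain placements) on hundreds of random trees of
up to 8 leaves, and against `phangorn::parsimony` for the Fitch score.

The packaged study table encodes IR presence from the IR-size column of the
genome feature table; the partially sequenced *Klebsormidium* sp. SAG 51.86
genome, in which an IR was seen but its junctions could not be delimited,
is coded `?` so it constrains no reconstruction. The species tree is
transcribed from the study's phylogenomic analysis; the successive
divergences of the *Spirogyra* and *Netrium* lineages (rather than a
(*Spirogyra*, *Netrium*) clade) follow that analysis's own description and
are the only reading consistent with its five-loss IR scenario. The
bryophyte branching order differed between the study's own protein and gene
trees; the packaged tree uses one standard arrangement, which affects no
quantity computed here because all land plants share IR presence.

# Sequence statistics

G+C content excludes N from the denominator. Codon-position G+C is computed
over a codon-wise concatenation with incomplete terminal codons trimmed;
internal stops raise a warning but are counted, since annotation errors
should be visible, not silently dropped.

`find_repeats()` reports all maximal exact repeated pairs of at least
`min_len` bp (default 30 bp, the conventional small-repeat threshold),
direct and inverted, by seeding on `min_len`-mers and extending; a pair is
reported only if inextensible on both sides, and overlapping self-repeats
contribute once to the masked union. The large IR would dominate these
summaries, so callers can mask it beforehand (the pipeline does so by
default). The test suite requires exact agreement with a quadratic
diagonal-scan oracle on sequences up to 5 kb. Composition summaries
(masked fraction, G+C of repeat vs unique sequence) and lower-case
soft-masking mirror the conventional repeat-masking workflow.

`colinear_divergence()` anchors the two genomes on unique shared k-mers
(default k = 31, long enough that a random 100–200 kb genome contains
essentially no spurious duplicates), chains them with a longest-increasing
subsequence, greedily enforces non-overlap, and globally aligns the
inter-anchor gaps (unit match/mismatch, affine gaps). Substitutions are
counted per site and each contiguous gap run as one indel event, so a
2-bp deletion is one event of length 2 — the event-wise accounting used
when summarizing nearly identical genome pairs. If the anchor chain covers
less than half of the shorter genome the pair is declared non-colinear and
only the aligned fraction is reported. Gaps too large for dense alignment
(> 25M cells) are scored as a single structural event rather than aligned.

The decoding audit derives anticodons from tRNA gene names and asks which
sense codons in actual use lack a reader. Wobble defaults: strict
Watson–Crick at codon positions 1–2; at position 3, anticodon G reads C/U,
U reads A/G, C reads G, and A is treated as inosine (reads U/C/A), with
`trnI(cau)` reading AUA (lysidine) and the elongator/initiator methionine
tRNAs reading AUG. Four-fold-box superwobble (U reading all four bases),
which plastids are believed to use, is off by default and available as a
toggle, so both the conservative and the permissive audit can be reported.

# The simulator

The simulator is the package's source of ground truth. It represents the
evolving genome as a structured layout — gene and spacer elements in LSC,
IR and SSC lists, with the IR stored once and rendered twice in opposite
orientations — so that rearrangements act on gene order with intergenic
breakpoints and can never split a gene, and any event inside the IR is
automatically mirrored into both copies (concerted evolution). IR boundary
shifts move whole genes (with their spacers) between the IR and the
flanking single-copy region, emulating expansion/contraction; an IR-loss
event deletes copy B and flattens the layout. Substitutions are uniform
(Jukes–Cantor-like) and indels, geometric with mean 2 bp, are confined to
spacers so that gene content stays interpretable. Rendered genomes pin the
four IR junction bases to non-complementary values so the planted IR is
exactly the maximal inverted repeat — without this, chance complementarity
at the junctions would extend the detected repeat by a few bases and
spuriously fail exact-recovery checks.

Defaults describe an ancestral-like streptophyte plastome: the full
144-gene catalog, an IR containing the five-gene rDNA operon
(`rrs, trnI(gau), trnA(ugc), rrl, rrf`) plus `trnR(acg)` (the one extra
tRNA shared by ancestral-type IRs), 18 SSC genes, ~35% G+C, spacers of
60–300 bp and protein genes of 100–500 codons, giving ~130–140 kb genomes
with a ~6 kb IR, comparable to the least-derived genomes in the study. Per
branch, expected event counts default to 2 reversals, 1 gene loss, 0.2
intron gains, 0.7 intron losses, 0.05 IR losses and 0.3 boundary shifts,
with 0.002 substitutions and 0.0002 indels per bp — desk-scale rates chosen
to produce, over a 10-taxon tree, the magnitude of divergence the compared
genomes display (tens of gene losses, extensive shuffling in some clades,
occasional IR loss). Explicit events can be planted on named branches
(`branch_events`), which is how homoplasy-free histories for recovery tests
are constructed. Every event is logged with its concrete parameters;
`replay_truth()` re-applies the log and must reproduce each leaf sequence
byte for byte.

What the simulator does not emulate: selection and codon-usage realism,
intron secondary structure, tRNA evolution, within-IR rearrangement, indels
inside genes, and duplicate gene families outside the IR. Passing the
recovery tests therefore shows that the analysis stack is correct on data
matching its assumptions (clean annotations, exact IR copies, gene-order
rearrangement), not that it is robust to annotation noise or highly
diverged real assemblies; for real data the mismatch-tolerant IR mode and
the synonym normalization are the first knobs to reach for.

# Problem sizes and runtime choices

The shipped tests run the breadth-first-search reversal oracle to n = 7
(645,120 states, built once and cached per session), 200 random
permutation pairs, 500 random Dollo instances of up to 8 leaves against
exhaustive enumeration, 100 seeded reversal-recovery simulations on
40-gene genomes, repeat-oracle comparisons on 5 kb sequences and divergence
recovery on a 100 kb pair. These sizes keep the full suite within a few
minutes on one CPU while still exercising every non-trivial code path; the
same computations are re-run from scratch by `scripts/acceptance.R`.

The planted-reversal recovery property is stochastic by nature: with up to
five reversals per branch on ~40-gene genomes, independently drawn
breakpoints occasionally reuse an endpoint and the minimal distance drops
below the planted count, so recovery is asserted as a rate (≥ 95% over 100
fixed seeds), not as an identity.

# Known limitations

* GenBank parsing covers the flat-file subset produced by standard plastome
  submissions (gene/CDS/tRNA/rRNA/tmRNA keys, join/complement locations);
  exotic qualifiers and multi-record files are out of scope.
* trans-spliced genes are represented as single multi-exon features on
  input, but the simulator only plants cis-spliced introns.
* The fortress case of the reversal distance cannot arise at
  oracle-verifiable sizes; it follows the published case analysis but is
  not independently cross-checked.
* Real-data reproduction of published repeat percentages depends on the
  masking internals of the original tools and is expected to be
  approximate.
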