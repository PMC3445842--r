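---
title: "Methods: comparing homoeologous wheat loci with model grass genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing homoeologous wheat loci with model grass genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeolocus)
```

## The scientific question

Bread wheat is a young allohexaploid: its B and D subgenomes diverged from a
common diploid ancestor only about 2.5-4.5 million years (My) ago, some 30 My
after the wheat lineage split from *Brachypodium distachyon* (about 35 My
ago). Comparing a megabase-scale locus of the wheat 3DS chromosome arm with
its homoeologous region on chromosome 3B — and both with the orthologous
regions of *Brachypodium* (Bd2) and rice (Os1) — lets one ask three linked
questions:

1. How many genes sit at *collinear* (synteny-conserved) positions across
   the four regions, and how many are *non-collinear* insertions?
2. When were the non-collinear genes inserted — before or after the B/D
   progenitor split — and did polyploidization accelerate gene movement?
3. Are non-collinear genes functional (promoters, EST-supported
   expression), or are they mostly pseudogenes?

`homeolocus` implements this comparative pipeline as composable,
data-frame-first functions: homology search, anchor chaining, gene
classification, tandem resolution, pseudogene calling with mechanism
attribution, epoch/rate inference, EST expression scoring, a simplified
core-promoter scan, plus the supporting BAC-pool deconvolution and
scaffold-curation procedures. A locus-evolution simulator and a
deterministic multi-genome fixture make every stage testable without any
external data.

## Homology model

All homology decisions use exact Smith-Waterman local alignment with affine
gaps (match +2, mismatch -3, gap open 5, gap extend 2 by default; all
configurable via `analysis_params()`). The match reward of +2 follows the
original search settings; the remaining penalties are standard
nucleotide-search values, since the original analysis relied on an external
tool's defaults that are not fully specified. Loci at desk scale are small
enough (tens of kb to a few Mb) that exact dynamic programming is
affordable; an optional shared-k-mer prefilter (k = 12) skips sequence pairs
with no exact 12-mer in common. Retained hits at the default cutoff carry
long exact stretches, so the prefilter does not change results above
threshold (a unit test verifies this on the fixture).

Significance uses the Karlin-Altschul form `E = K m n exp(-lambda S)` with
`lambda` solved numerically for the configured scoring under uniform base
composition (the ungapped approximation). The `K` constant is not solved —
its full series expansion is out of proportion to its effect when the
decision is a hard cutoff at `E <= 1e-10` and the planted/biological signals
sit orders of magnitude away from the cliff — so it defaults to 0.1 and is
configurable. What matters downstream is the *cutoff behaviour*: ~95%
identity homoeolog pairs and ~85% identity orthologs score far above it,
unrelated sequences far below.

A *homoeolog pair* is a reciprocal best hit at the cutoff. Reciprocity
matters: an extra tandem copy still hits its template's partner, but is not
that partner's best hit, so tandem copies are correctly left unpaired
rather than double-counted.

## Collinearity

"Found at a collinear position" is asserted by inspection in comparative
figures; here it is operationalized as membership in the maximum-weight
order-preserving chain of best-homolog anchors between two loci
(longest-increasing-subsequence dynamic programming, weight = alignment
score). Chains are computed on gene order regardless of orientation, so a
micro-inversion that preserves order still counts as collinear. Categories:

* `COLLINEAR_ALL` — in-chain homoeolog pair plus in-chain homologs in both
  model genomes;
* `COLLINEAR_RICE_WHEAT` — in-chain pair and in-chain rice homolog, no
  Brachypodium homolog (a Brachypodium-lineage deletion);
* `SHARED_WHEAT_NC` — homoeolog pair, but no model-genome homolog: inserted
  on the shared wheat stem;
* `LOCUS_SPECIFIC_NC` — no homoeolog pair: inserted after the B/D split;
* `TANDEM_DUP_NC` — the less conserved copy of a tandem pair;
* `EXCLUDED` — annotation-flagged genes (e.g. a gene that may fall in an
  assembly gap of the other locus) withheld from pairing but kept in
  denominators.

Tandem pairs are two nearby genes (at most one intervening gene by default)
whose best model-genome homolog is the same gene; the copy with higher
identity to that homolog keeps collinear standing, ties go to the 5'-most
copy, and arrays keep only the single best copy. Because an extra tandem
copy exists at only one locus, the per-locus "locus-specific" count in the
summary includes tandem copies; the category keeps them distinguishable.
One known limitation: if the *worse* copy happened to sit in the anchor
chain, the chain is not re-computed after demotion — in practice the more
conserved copy wins the anchor too, since both chaining weight and tandem
resolution use the same alignment scores.

Percentages are reported round-half-up: collinear fractions to one decimal,
the wheat homoeolog fraction as a whole percent with annotation-excluded
genes kept in the denominator (32 of 38 is reported as 84%, matching the
usual arithmetic for such tables).

## Pseudogene calling

A gene model is assessed against an intact reference — its homoeologous
partner when that has an open reading frame, otherwise its best
model-genome homolog, otherwise only intrinsic checks apply. Defects:

* *premature stop*: first in-frame stop before the final 5% of the
  reference ORF (sparing minor C-terminal truncations);
* *frameshift*: an aligned indel whose length is not a multiple of 3;
* *deletion*: aligned coverage of the reference below 70%
  (`1 - pseudo_deletion_frac`); the stated rule that models missing up to
  30% of their homolog still count as (deletion-type) pseudogenes is read
  as a coverage threshold. Coverage below 50% with no other defect is a
  gene *fragment*.

Coverage and indel evidence come from *multiple* local-alignment blocks
obtained by iterative subject masking: a single optimal local alignment
cannot bridge a multi-kb transposon insertion or a large deletion (the
affine gap cost exceeds any flanking gain), so block gaps are treated as
indel events and the covered reference positions are summed across blocks.

Mechanism attribution compares the intact gene's region (CDS plus 1 kb
flanks) with the pseudogene's region and its repeat annotation, and returns
exactly one mechanism in a fixed priority order that resolves compound
evidence deterministically: `TE_INSERTION` (an insertion of at least 50 bp
interrupting the CDS-aligned part, overlapping an annotated repeat) >
`POINT_FRAMESHIFT` (a single 1-2 bp event) > `INTERNAL_DELETION` (at least
30 bp missing with both flanks anchored) > `TERMINAL_TRUNCATION` (at least
60 bp of a CDS end without homology) > `UNKNOWN`.

In the census, the "pseudogenes among non-collinear genes" tally excludes
`TANDEM_DUP_NC` copies of collinear genes: a broken tandem copy of a gene
that is itself collinear reflects duplication of an already-defective gene,
not pseudogenization of an inserted gene. This is the only accounting
consistent with a defective tandem copy among locus-specific genes and a
zero count of non-collinear pseudogenes at the same locus.

## Insertion epochs and rates

Categories map onto epochs: collinear genes are ancestral (>= 35 My),
wheat-shared non-collinear genes were inserted on the shared stem (35 My to
the B/D split), locus-specific genes and post-split tandem copies are
recent (< the B/D split, taken as 2.5-4.5 My). The rate ratio
`(n_recent / T) / (n_intermediate / t_old)` is evaluated at both endpoints
of the recent-epoch duration and reported as a range; `t_old` defaults to
30 My, the length of the shared-stem epoch in the published framing. The
quoted "three- to five-fold" bracket does not correspond to a single
(t_old, T) pairing of the printed counts, so the full range is reported
rather than a single factor. Pooled counts treat the two post-split
branches as independent lineages (the per-lineage rate divides by `2T`);
per-locus tables are also reported. A zero intermediate count yields an
infinite-ratio flag rather than an error.

## Expression and promoters

EST support uses the stringent published rule: 100% identity over at least
100 bp. Matching is exact by construction — merged k-mer diagonals with
`k = est_min_len` enumerate precisely the maximal exact common substrings of
at least that length (verified against a naive all-substring oracle), on
both EST strands since EST orientation is arbitrary. ESTs hitting both
members of a homoeologous pair cannot be assigned to a copy and are removed
entirely. A gene is "expressed" when at least one retained hit remains.
`est_min_identity` below 100 is rejected rather than silently approximated:
the rule the parameter encodes is exactness.

The promoter scan is a documented, simplified stand-in for proprietary
promoter predictors, preserving the analysis structure (promoter
present/absent, TATA offset window): the TSS is the highest-scoring
pyrimidine-purine initiator context in the final 200 bp of the 1 kb
upstream region (score = pyrimidine count in the preceding 12 bases, +2 for
the canonical CA; ties resolve toward the start codon; minimum score 9),
and the TATA box is the nearest `TATAWAW` match 14-38 bp upstream of the
TSS. A promoter is called when the TATA constraint holds, or when the
initiator alone reaches the TATA-less threshold (14, the maximum score).
These thresholds were chosen once so that random sequence yields calls in
well under 5% of 1 kb regions while the planted consensus always calls.

Per-pair expression contrasts use the exact two-tailed binomial test at
p = 0.5 (point probabilities no larger than the observed one are summed),
via `stats::binom.test`.

## BAC pools and scaffold curation

Three-dimensional pool design places clones in 384-well plates (rows A-P,
columns 1-24), filled plate-major; plate, row and column pools each contain
every clone exactly once. Deconvolution intersects the Cartesian product of
positive pools with occupied wells — exact for single-clone markers and a
superset guarantee for multi-clone markers, with the candidate count
reported as ambiguity. No PCR error model is applied by default (the screens
being modelled were clean); a marker with an empty dimension is a no-call.
Markers hitting clones of two physical-map contigs yield overlap edges,
deduplicated with marker support counts.

Scaffold curation mirrors manual assembly editing: scaffold-end windows
(default 1,000 bp standing in for full-length terminal reads of ~330 bp;
configurable) are aligned to small contigs; matches require 99% identity
over 100 bp and a contig terminus within 10 bp. When two scaffolds match
opposite ends of one contig they are merged with the contig interior
closing the gap; overlapping stretches are kept from the scaffolds, which
have higher consensus depth. Merging iterates to a fixed point; a contig
claimed by more than two scaffold ends is refused and logged. Ends carrying
a repeat-database hit of at least 100 bp above 95% identity are flagged
risky and merge only with a second independent end match. Merging is
same-orientation only: the fragmented-locus reconstruction this models does
not require reverse-complement joins.

## The simulator and what it does (not) show

`simulate_locus_evolution()` evolves one ancestral gene layout into four
loci along the species tree (rice, Brachypodium, then a shared wheat stem
splitting into B and D at a time drawn from 2.5-4.5 My). Each branch
receives Poisson-distributed insertions, deletions, tandem duplications and
pseudogenizations (one of the four mechanisms, literally applied), plus
substitution-only divergence; insertions on the post-split branches are
multiplied by the acceleration factor under study (three- to five-fold in
the motivating hypothesis; default 4). Every event is logged with its time,
lineage and mechanism — the log is the ground truth for parameter-recovery
tests. The B-lineage locus receives ~27% wider intergenic spacing, matching
the relative genome expansion. Simplifications, chosen because only
presence/absence patterns and wheat-side epochs matter downstream: the rice
lineage branches at the ancestral layout rather than earlier; all simulated
genes are single-exon and plus-strand; substitution is uniform across sites
(Jukes-Cantor-like), with codon-safe resampling so intact genes never gain
in-frame stops; transposable elements are random sequence with a repeat
annotation, not real TE models. Consequently, passing recovery tests shows
the *pipeline logic* is correct under clean divergence — it does not show
robustness to real-data artifacts (split gene models, assembly errors,
paralogy networks, alignment-confounding repeats).

The deterministic fixture (`build_paper_fixture()`) plants the published
count structure — 39/38 wheat CDS, 32 pairs, 14 + 1 collinear, 17 shared,
7/5 specific with 3/2 tandem copies, one excluded 3B gene, 22/21 model
genes, 2/6 pseudogenes with the four mechanisms, expression fractions
41.7/53.3/33.3/22.7% and 4 removable shared ESTs — as *sequence facts*, so
the downstream pipeline, not the generator labels, must recover every
count. Homoeolog pairs sit at ~95% identity and orthologs at ~85%, far from
the E-value cliff. Substitutions are stratified (at least one per 45 bp
window) so no 100 bp exact run survives between distinct gene copies except
deliberate 120 bp conserved blocks planted in four pairs to create the
removable shared ESTs. Promoter and expression truths are enforced by
rejection sampling at generation time, making the planted fractions exact
properties of the emitted data rather than tuned thresholds. Counts are
seed-invariant; sequences are not. Problem sizes throughout the test suite
(6-10 ancestral genes in simulations, 300-600 bp CDS, few-hundred-bp
intergenic spacing) were chosen as the smallest layouts that keep every
planted signal comfortably above threshold.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 import/export is the
  only 1-based closed surface and round-trips exactly.
* `N` residues are allowed in locus sequence (assembly gaps) but are an
  error inside extracted CDS unless explicitly permitted.
* Percentages round half-up at the reported precision, so printed-style
  fractions are reproduced exactly (base `round()` would turn 38.46 into
  38.5 but 84.21 into 84 either way; half-up is uniform).
* `gene_distances()` requires two genes; the median of an even count is the
  mean of the central pair.
* Empty inputs return typed empty tibbles, not errors, except where a
  statistic is genuinely undefined (both-zero binomial contrast, distance
  of a single gene) — those are flagged or raised.
* Upstream regions shorter than 50 bp yield a promoter no-call; regions
  clipped at the locus boundary carry a `short` flag.

## Worked example

```{r example, eval = FALSE}
params <- analysis_params()
fx <- build_paper_fixture(seed = 1)
cmp <- compare_loci(fx$loci)
cmp$summary

calls <- call_pseudogenes(cmp, fx$loci)
pseudogene_census(calls, cmp$profiles)$by_locus

ests <- generate_ests(fx, seed = 1)
score_expression(cmp, ests)$summary

insertion_rate_table(cmp$profiles)$pooled
autoplot(cmp)
```

The same pipeline applied to `simulate_locus_evolution()` output, compared
against the event log, is the package's parameter-recovery harness (see
`tests/testthat/test-acceptance.R`).
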