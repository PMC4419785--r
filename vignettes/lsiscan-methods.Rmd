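---
title: "Calling and characterizing lineage-specific insertions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing lineage-specific insertions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsiscan)
```

## The problem and the model

Insertions that arose on the human lineage after the split from chimpanzee
are a natural place to look for sequence underlying human-specific traits:
unlike deletions, an insertion can add regulatory or coding material while
leaving the ancestral function intact, and active transposable-element
families (Alu, LINE1) keep producing them. `lsiscan` implements the full
discovery-and-characterization funnel for such insertions from a
multi-species alignment, together with a planted-truth simulator that makes
every stage testable without any external download.

The calling model is deliberately conservative. Working block-by-block over
a MAF alignment restricted to a focal species (default hg19) and a set of
comparison species (default the five non-human primates panTro4, gorGor3,
ponAbe2, nomLeu3, rheMac3), a column supports an insertion if and only if
the focal character is an explicit base and *every* comparison row carries
an explicit gap character at that column. Two consequences follow:

* **Missing rows veto the block.** If any comparison species has no row in
  a block, nothing is called there. Unaligned or unassembled sequence in a
  lower-quality genome is indistinguishable from absence, and treating it
  as a gap would inflate the call set with false positives.
* **Focal `N` is not evidence** (configurable via `allow_n`): an undefined
  focal base cannot demonstrate an insertion.

Maximal runs of supporting columns become calls; runs touching a block edge
are kept but flagged (`touches_block_edge`), because an insertion may
continue in the neighboring block. Blocks are processed independently — no
stitching is attempted, since any merging rule would be arbitrary at this
layer; the flag preserves the information a downstream merge would need.
Calls identical in (chrom, start, end), which can arise from overlapping
blocks, are deduplicated with a logged count. Minus-strand focal rows are
projected to the plus strand before emission so that every downstream
coordinate lives in one convention: 0-based, half-open, plus strand.

The funnel then applies two filters:

1. **Length**: calls shorter than 10 nt are removed (inclusive boundary —
   a 10 nt call survives). Short indels are hard to position reliably in an
   alignment and unlikely to carry novel regulatory motifs.
2. **Polymorphism**: calls exactly matching a known polymorphic indel —
   identical (chrom, start, length), optionally also sequence — are
   removed; the survivors are taken as fixed in the focal population.
   Partial overlaps and *contained* smaller variants never trigger
   removal: a SNP or small indel inside an insertion indicates a mutation
   that postdates the insertion, not segregation of the insertion itself.
   Exact matching is on placement rather than sequence by default because
   indel representations in variant files differ in normalization.

## Annotation layers

**Genic classification.** Each insertion is classified against every
overlapping gene with one call per gene, resolved by the precedence
`CDS_exon > UTR5 > UTR3 > intron`. A precedence is required because a gene
is reported in exactly one category even when an insertion spans, say, an
exon/intron junction; CDS-first makes coding impact the headline label.
UTR orientation is strand-aware. Non-coding transcripts
(`cds_start == cds_end`) contribute gene-body (intron-level) evidence only,
since the category set has no ncRNA-exon label. An insertion overlapping no
gene receives the sentinel (`gene_id = "."`, `intergenic`).

**Repeat overlap.** An insertion is repeat-overlapping given any ≥1 bp
overlap with a repeat element. Per-insertion coverage uses the union of
overlapping elements, so the summary is invariant to an annotation's
splitting of one element into abutting pieces. Expected class frequencies
use element *counts* (share of annotated elements per class), matching the
convention of comparing how often each class is drawn; a base-pair
weighting would answer a different question and can be derived from the
same inputs. Insertions touching several classes count once per class,
with the multi-class total reported so the column sums remain auditable.

**Regulatory subset.** The strict subset requires all three predicates:
≥1 bp overlap with a DNase-hypersensitivity interval, ≥1 bp overlap with a
TF-ChIP interval, and distance ≤ 5 kb from the nearest gene transcript
span (0 inside). Distance is measured to the span, not the TSS alone —
"within 5 kb of the gene" — with the TSS-anchored alternative available
through the regulatory-domain machinery below.

**Regulatory domains and enrichment.** Gene-level enrichment of a region
set uses basal-plus-extension domains: a basal promoter window around the
canonical TSS (5 kb upstream, 1 kb downstream, strand-aware) extended up
to a distal limit (default 5 kb here, to stay promoter-proximal) in each
direction but never into a neighboring gene's basal domain. The canonical
transcript is the longest-CDS isoform (ties: longest span, then input
order). For each annotation term the test is the upper binomial tail:
with $n$ query regions and a domain set covering fraction $p$ of the
annotatable genome, the p-value for $k$ hits is
$P(X \ge k),\ X \sim \mathrm{Binomial}(n, p)$. The annotatable genome
length is an explicit input rather than hidden data, and the gene→term
table is user-supplied, which keeps the statistic decoupled from any
hosted ontology.

## Selection statistics

Windowed sweep statistics (CLR, Fu's F, both as $-\log_{10} p$) flag an
insertion when the **maximum** value over overlapping windows reaches 2.0
(inclusive ≥). Maximum, not mean, is the conservative choice for "does
this insertion sit in a swept region" when an insertion spans several
windows; mean aggregation is available (`agg = "mean"`). Per-SNP |iHS|
flags strictly above 2.5 (exclusive >). The deliberate asymmetry of the
operators follows the conventional cutoffs for these statistics
($-\log p \ge 2$; $|iHS| > 2.5$). Insertions with no overlapping window or
SNP produce *no call* rather than a negative call: on sparse tracks,
absence of data is not evidence of neutrality. Cross-population logic
(`all_of` / `any_of`) is plain set algebra over flagged ids.

## Site-model LRTs

Positive selection on insertion-containing genes is assessed from
externally computed codon site-model log-likelihoods (M1a/M2a and M7/M8,
e.g. from codeml; running the optimizer is out of scope). The statistic is
$2(\ln L_{alt} - \ln L_{null})$ against $\chi^2_2$ — two extra parameters
in each selection model — clamped at 0 with a warning when the alternative
fits worse, which flags optimizer non-convergence without hiding it.
Bonferroni correction multiplies by an **explicit** test count `m`
(default: rows of the table). It is explicit because gene-level and
transcript-level counting are both defensible when genes carry several
transcripts, and the choice materially changes the corrected results.

## The synthetic generator

`simulate_dataset()` emits every input the pipeline consumes — MAF blocks,
a polymorphic-indel file (TSV and minimal VCF), gene models (extended
genePred), repeat/DNase/TF-ChIP intervals, CLR and Fu's F bedGraph tracks,
per-SNP iHS values, a log-likelihood table — plus `truth.tsv`, the
manifest recording each planted insertion's intended fate. Design points:

* **Gaps are the only signal.** Comparison rows are copies of the block's
  ancestral sequence with independent 1% per-site substitutions; the
  planted insertion appears as focal bases against gaps in every
  comparison row. Substitutions ensure the caller keys on gap structure,
  not sequence identity.
* **One insertion per block**, placed at least 1.2 kb from the block
  edges, keeps truth bookkeeping exact and edge flags clean.
* **Length mixture** (defaults): 90% short component, a discrete power law
  on 1–50 nt with exponent 0.4228 — fixed by solving
  $P(\ell < 10 \mid \text{short}) = 1/3$, so 30% of all planted lengths
  fall below the calling cutoff and ≈86% of retained lengths lie in
  10–50 nt; 8% Alu-like, uniform on 300–350 nt; 2% LINE1-like, normal
  (mean 6000, sd 150) clipped to 5500–6500 nt. This reproduces the
  characteristic shape of the human-specific insertion length spectrum:
  a short-dominated decay with SINE and LINE peaks.
* **Planted fates**: 15% of insertions are emitted into the polymorphic
  file; 10% of blocks drop one comparison row (their insertions are
  marked undetectable — the explicit-evidence rule must lose exactly
  these); 70% get a covering or partial repeat element (93% of those
  fully covering) with classes drawn from a fixed distribution; genic
  context (5% CDS, 2% 5′UTR, 3% 3′UTR, 25% intron, 65% intergenic) is
  realized by *constructing* a transcript around the insertion, so the
  context is planted truth rather than recomputed geometry; sweep status
  (5% per population) drives all three statistics coherently — swept
  windows draw values in [2.2, 4.0], background in [0, 1.5], background
  iHS is truncated at ±2.4 and swept insertions receive one guaranteed
  SNP with |iHS| in [2.6, 3.5], so flag recovery is exact by
  construction; 10% of CDS-context transcripts are simulated under
  positive selection in the log-likelihood table (ΔlnL uniform in
  [15, 40] vs. null draws of $\chi^2_2/2$).
* **Determinism**: one RNG stream seeded from `config$seed`; identical
  configs produce byte-identical files.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: indel evolution in the comparison lineages
(no lineage-specific deletions, no alignment ambiguity), alignment error
and block fragmentation (planted insertions never span block boundaries),
rate heterogeneity, realistic linkage between annotations (repeat class
and genic context are drawn independently), and codeml's actual likelihood
surface. The simulator validates the *logic* of the funnel, not the
field-realism of any particular call set.

## Numerical choices and degenerate inputs

* Binomial tails come from `pbinom(k-1, n, p, lower.tail = FALSE)` —
  accurate far beyond the 10 significant digits the enrichment layer
  needs; `k = 0` returns exactly 1.
* $\chi^2$ p-values use `pchisq(..., lower.tail = FALSE)`; a negative LRT
  statistic is clamped to 0 (p = 1) with a warning.
* Interval algebra (overlap, union coverage, nearest-gene distance) is
  delegated to `GenomicRanges`/`IRanges`; the test suite checks each
  operation against a brute-force double-loop oracle on randomized
  instances.
* Empty inputs propagate as empty results, never errors: an empty MAF is
  an empty block list; filters on empty sets return empty partitions with
  zero counts.
* 1-based conventions (RepeatMasker `.out`, VCF POS) are converted at the
  reader boundary; everything internal is 0-based half-open.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at 500 blocks × 10 kb (the
planted-truth recovery and determinism checks), 5,000 insertions in
coordinate-only mode (sampling-consistency checks at 3 binomial SE and a
χ² goodness-of-fit of the length spectrum at α = 0.01), 20 randomized
1,000 × 1,000 interval instances for oracle equivalence, and 10,000
simulated null LRTs for calibration (Kolmogorov–Smirnov at α = 0.01).
These sizes give the property checks enough power to catch off-by-one and
aggregation errors while keeping a full run on one CPU comfortable.

## Known limitations

* Insertions spanning alignment-block boundaries are flagged, not merged;
  a true long insertion split across blocks appears as two flagged calls.
* The polymorphic match is placement-exact; a polymorphic indel recorded
  with shifted left-alignment in the variant file will not be subtracted.
  Normalizing both sides to a common left-aligned representation is the
  natural extension.
* `expected_fraction` in the repeat summary is count-based (see above);
  base-pair weighting is a one-line change on the same inputs but is not
  what the summary reports.
* The region-binomial test inherits the usual GREAT-style caveats:
  domains of long genes absorb more hits by construction, and the test is
  only as meaningful as the supplied annotatable-genome length.
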