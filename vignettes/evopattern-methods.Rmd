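---
title: "Fixation-pattern analysis of two-condition serial-sampling evolution experiments"
author: "evopattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-pattern analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(evopattern)
  library(SummarizedExperiment)
})
```

## The experimental design this package models

A haploid clonal microbial population is split into two lineages grown
under two constant conditions — here called *cold* (stress) and *hot*
(control) — and propagated by iterative re-plating for on the order of a
hundred generations. Single clones are archived at ordered time points
(by default six cold samples and four hot samples) and whole-genome
re-sequenced. After read alignment and haploid variant calling
(upstream of this package), every called site carries one binary
genotype per sample: 0 when the sample matches the reference assembly,
1 when it carries any variant haplotype. Optical density is recorded at
every re-plating step, giving a coarse growth series per condition.

Given the multi-sample VCF, the genome, a gene annotation with GO
assignments, and those growth tables, the package answers:

1. which variants show condition-exclusive fixation (candidate adaptive
   mutations) rather than random gain/loss or reference error;
2. which genes are variant *hotspots*;
3. which gene functions (GO terms) and which intergenic sequence motifs
   (k-mers, e.g. CpG dinucleotides) attract significantly many variants;
4. whether variant-bearing genes coincide with differential expression;
5. how fast each lineage grows, and whether growth changes over time.

## Trajectory encoding and classification

Every record's calls are ordered cold-block-first and rendered as a
pattern string such as `"110011|0000"`. Classification is a total rule
over `{0, 1, missing}` vectors:

* **Background** — all samples 1. Every lineage disagrees with the
  reference at this site from the first sample on, which indicates an
  error in the reference assembly rather than a new mutation; these are
  removed from evolutionary interpretation.
* **ColdFixed** — the cold block is `0^a 1^b` with `b >= 1` and the hot
  block is all 0: the variant was gained once and retained in every
  subsequent cold sample, exclusively in the cold lineage. **HotFixed**
  symmetrically. When `a = 0` (e.g. `"111111|0000"`) the gain predates
  the first sampling point, so the condition under which it arose cannot
  be determined; the class is kept but flagged `gainAmbiguous`.
* **NoVariant** — all 0 (only possible for records that enter the set by
  construction, e.g. simulations).
* **Unresolved** — any missing call. At the coverage typical of such
  experiments (hundreds-fold) missingness is negligible, and silently
  imputing a 0 or 1 would bias fixation calls, so these records are set
  aside and excluded from all percentage denominators.
* **Random** — everything else, including repeated gain/loss
  (`"110011|0000"`) and mixed-condition patterns (`"011111|0011"`):
  fixation must be *exclusive* to one condition to count.

```{r classify}
classifyPatterns(c("111111|1111", "111111|0000", "000000|0111",
                   "110011|0000", "011010|0101"))
```

The rule is vectorised over a calls matrix and is validated in the test
suite against an independent regular-expression reference over every
pattern of every layout up to 12 samples (the 6|4 layout has 1024
patterns: 6 ColdFixed, 4 HotFixed, 1 Background, 1 NoVariant,
1012 Random).

Summaries report two denominators explicitly, because they answer
different questions: the Background share is given over *all* classified
records (how much of the filtered call set is reference error), while
the ColdFixed/HotFixed/Random shares are given over the non-background
records (how trajectories distribute among interpretable variants).
Percentages over an empty denominator are `NA`, never 0.

## Hard filtering and region assignment

Records are filtered per variant type with OR-combined exclusion
clauses; the defaults in `gatkFilterSpec()` are the conventional
hard-filter thresholds for haploid short-read calls (SNPs:
`QD < 1.0 || FS > 30.0 || MQ < 45.0 || SOR > 9 || MQRankSum < -4.0 ||
ReadPosRankSum < -10.0`; InDels: `QD < 1.0 || FS > 200.0 || MQ < 45.0
|| MQRankSum < -6.5 || ReadPosRankSum < -10.0`). A clause whose
annotation is absent on a record is skipped; a record on which every
clause was skipped is `UNEVALUATED` rather than silently passed.

A variant is *genic* iff its VCF position overlaps at least one full
gene span — UTRs and introns count as genic; for InDels only the
anchor position is used, not the deleted span, which keeps the
assignment deterministic. All overlapped gene ids are recorded, so a
variant inside two overlapping genes counts for both. Internally all
ranges are held as `GRanges` (1-based, closed); GFF3 and BED inputs are
normalised on read by `rtracklayer`, and VCF positions are 1-based
natively, so no manual coordinate shifting occurs anywhere.

## Hotspots

Per-gene variant counts are standardised, `z = (n - mean) / sd`, and
genes with `z > 2.575` — the upper 0.5% of a standard normal, i.e. the
99th-percentile band — are flagged. Two choices are deliberately
configurable because the underlying convention is ambiguous in the
field: the background population (genes with at least one variant, the
default, versus all annotated genes) and the standard-deviation
denominator (sample `n - 1`, the default, versus population `n`). A
tie at exactly 2.575 is not a hotspot (strict inequality), and a
zero-variance count table yields no hotspots with a warning rather than
dividing by zero.

## Enrichment machinery

`fisherExactTest()` computes the exact conditional (hypergeometric)
p value; the two-sided p sums the point masses of all outcomes no more
probable than the observed table (relative tolerance `1e-7`), matching
the convention of `stats::fisher.test`, against which it is
cross-checked in the tests (and against a full binomial-coefficient
enumeration for *every* 2x2 table with total at most 40).
`bhAdjust()` is the Benjamini–Hochberg step-up procedure.

**GO terms.** For each term annotated to at least one variant-bearing
gene, the table compares the term's affected versus unaffected genes
against the background of all *other* gene–GO associations, split the
same way. Terms seen fewer than twice among variant genes are excluded
before testing (singletons cannot be distinguished from noise and only
dilute the BH family). Genes count once per term by default; weighting
by per-gene variant count is available. No GO-DAG ancestor closure is
performed — terms are taken exactly as annotated.

**Intergenic k-mers.** `kmerScan()` slides every window of length
k = 1..10 across the forward strand of the intergenic sequences; an
occurrence is variant-overlapping iff the window contains at least one
variant position, and windows containing non-ACGT characters are
skipped. Each k-mer is then tested against the summed counts of all
other k-mers of the same length, with BH applied within each length
separately (each k forms its own hypothesis family; a global family is
available behind a flag). Scanning only the forward strand is a
deliberate simplification: the headline CpG signal ("CG") is its own
reverse complement, so the choice does not affect it, and the
palindrome invariance is asserted in the tests. Enriched k-mers are
annotated against a user-supplied cis-regulatory motif table by IUPAC
substring matching; hits from k-mers shorter than 6 are flagged
low-confidence, since such partial matches carry little specificity.

**Differential expression.** `deOverlapTest()` builds the 2x2 of
variant-bearing x differentially-expressed over the DE universe and
returns the two-sided Fisher p. The DE flags are consumed as input;
fitting the expression model that produced them is out of scope.

## Growth statistics

Each re-plating event closes one interval: about 1,000 cells are
streaked, grown to harvest, and the harvest OD is converted to a cell
count through the `cellsPerOd` calibration. The interval doubling time
is `Td = dt * ln 2 / ln(N_end / N_start)`; intervals without net growth
are flagged and excluded rather than producing negative times. Because
pairing a mean doubling time with a single "growth rate per day" is
convention-dependent (doublings per day `1/Td` versus exponential rate
`ln 2 / Td`), both are reported and labelled — the package takes no
position on which convention a given published pairing used.

Condition differences use the Wilcoxon rank-sum test (exact enumeration
up to combined n = 20 without ties, otherwise the tie-corrected normal
approximation). Temporal trends use the Jonckheere–Terpstra test,
implemented in the package because no installed package provides it:
`J` sums, over ordered group pairs, the number of increasing
cross-pairs plus half the ties. The p value is computed by exhaustive
enumeration of group-label assignments up to pooled n = 12, by
tie-corrected normal approximation above that, or by seeded Monte-Carlo
permutation (default 10,000 draws). The nonparametric tests are applied
unconditionally; no normality pre-test gates them, since the sample
sizes involved make such gating uninformative.

## The synthetic-data generator

`simulateExperiment()` produces a genome, annotation, multi-sample
variant table and growth series with a ground-truth ledger, so every
pipeline stage can be validated against planted truth. Its defaults are
a deliberately desk-scale rendition of the study design:

* **Genome**: 100 kb over two contigs with 64 genes of ~1 kb — the same
  ~64% genic fraction as the real 14 Mb / 6,800-gene genome, at 1/140
  scale. CpG-dense islands (dinucleotide sampler emitting "CG" with
  probability 0.35) cover 20% of intergenic space; background GC is
  0.40. Each gene carries 2–8 GO ids from a 150-term pool.
* **Samples**: 6 cold + 4 hot, 102 / 181 generations — the study
  layout.
* **Variants**: planted class counts default to
  `Background = 100, ColdFixed = 23, HotFixed = 18, Random = 1000`,
  the magnitudes of the real experiment's non-background classes (the
  background count is scaled down; reference errors are cheap to test).
  Fixed variants draw their gain time uniformly; Random patterns are
  drawn uniformly from the 1,012 eligible patterns, which maximises
  classifier coverage rather than imitating any particular gain/loss
  process. The SNP share is 0.48, matching the filtered call set's
  composition; InDels are 1–10 bp. Alternatively, counts can be drawn
  from per-base per-generation rates (defaults 2.17e-6 cold, 1.10e-6
  hot — the published estimates).
* **Placement**: uniform by default; `cgBias` multiplies the sampling
  weight of intergenic CG-dinucleotide bases (10x in the recovery
  suite), and `per_gene` placement puts each variant into a distinct
  gene — the planted design under which a 9-variant hotspot gene is
  provably the unique Z-score outlier. Under uniform placement with a
  per-gene mean near one, Poisson tails routinely push 3–4-variant
  genes over z = 2.575, so uniqueness would not be a fair assertion.
* **Growth**: mean doubling times 2.70 d (cold) and 1.32 d (hot); the
  cold series drifts −30% linearly across its six re-platings, centred
  so the series mean stays at the configured value — reproducing both
  the published averages and the published adaptation trend in one
  series. OD noise is multiplicative lognormal (sd 0.1); with zero
  noise `doublingTime()` inverts the generator exactly.

One master seed drives three derived streams (genome, variants, growth)
so each stage is reproducible in isolation. What the generator does
*not* emulate: read-level error, coverage fluctuation and missing
genotypes (calls are clean 0/1), linkage between variants, selection
dynamics within a lineage, and real motif content of intergenic DNA.
Passing recovery tests therefore demonstrates that the *analysis* is
correct and internally consistent — not that the upstream caller or the
biological assumptions hold on real data.

## Validation problem sizes

The shipped test and acceptance runs use: exhaustive classifier
enumeration over all layouts up to 12 samples (~90,000 patterns);
every 2x2 table with total <= 40 (135,751 tables) against a
binomial-coefficient oracle; a 300 kb recovery genome carrying 1,141
planted variants; a 150 kb CpG-bias genome with >200 intergenic
variants; 500 null replicates (800 bp, k <= 3) for the k-mer type-I
check; and 500 growth replicates for trend power. These sizes were
chosen so the full validation completes in a few minutes on one core
while keeping every binomial standard error small relative to the
asserted margins.

## Known limitations

* InDel region/window overlap uses the anchor position only; a long
  deletion spanning a gene boundary is attributed to its start.
* Multi-allelic sites collapse to presence/absence, as the binary
  trajectory code requires; allele identity is not tracked over time.
* The GO background counts associations, not a DAG-aware universe.
* `Unresolved` handling is conservative: one missing call removes a
  record from classification entirely.
* The k-mer scan treats intergenic sequences as independent strings;
  windows do not span region boundaries.

## Session info

```{r session}
sessionInfo()
```
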