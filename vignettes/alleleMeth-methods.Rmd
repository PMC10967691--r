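---
title: "Methods: allele-resolved methylome and expression analysis for hybrid genomes"
author: "alleleMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-resolved methylome and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`alleleMeth` analyses DNA methylation and gene expression at allele
resolution in an inter-specific hybrid whose genome consists of two
subgenomes, one per parent. The motivating system is a developmental time
course (de novo shoot organogenesis from leaf explants) with six
bisulfite-sequenced phases (`LE`, `DP1`, `DP2`, `IP1`, `IP2`, `IP3`) and
eight RNA-seq phases (the same plus `IP0.5` and `IP1.5`), three biological
replicates each. All analysis stages operate on standard objects
(`GRanges`, count matrices, `DNAStringSet`) and every stage can be fed by
the bundled synthetic generator, which emits complete ground truth.

## Methylation levels and profiles

A cytosine's level is the fraction of methylated read calls,
`mC / (mC + uC)`, defined only at coverage of at least 5 reads. Region
levels are coverage-weighted: pooled `sum(mC) / sum(mC + uC)` over
qualifying sites, so the level of a union of disjoint intervals equals the
count-pooled level of its parts. A region with no qualifying site is
*undefined* (`NA`), never zero.

Metagene profiles use an 80-bin scheme: 20 fixed 100-bp bins over the 2-kb
upstream flank, 40 proportional bins over the feature body, and 20 fixed
bins over the downstream flank, ordered along the direction of
transcription (for `-` strand features the upstream bins come from higher
coordinates and the order is reversed). The 20/40/20 split is the only
reading of "40 flank bins plus 40 body bins" that totals 80 with equal
flanks; flank bins are fixed-width, body bins proportional. Features
shorter than 40 bp are excluded with a warning, since each body bin must
cover at least one base.

For genome-wide summaries a site is *called* methylated by a one-sided
binomial test of its methylated count against the bisulfite non-conversion
rate (default 0.005), BH-adjusted within context, at adjusted p < 0.01.
Level histograms use the bands `[0, 0.2)`, `[0.2, 0.8]`, `(0.8, 1]`.
Non-conversion is simulated by the generator but never corrected in the
analysis; the observed level of a site with true probability `p` has
expectation `p(1 - e) + (1 - p)e`.

## DMR calling

The genome is tiled with 200-bp windows sliding by 100 bp; a trailing
partial window is kept only when it is at least 100 bp and covers otherwise
uncovered chromosome tail. Only windows containing at least five cytosines
of the tested context in every sample enter the test.

Each window is tested with a binomial-logistic likelihood-ratio test:
replicate counts are binomial observations with a common within-group
proportion, and the two-group model is compared to an intercept-only model
(1 df). With a single group covariate the group MLEs are the pooled
proportions, so the statistic has closed form and is vectorized over
windows. Multiple testing uses Benjamini-Hochberg; this deliberately
replaces the SLIM q-value of the delegated DMR caller with the standard,
dependency-free procedure. A window is a DMR when `q < 0.05` *and* the
pooled methylation difference exceeds the per-context threshold: 0.25
(CG), 0.25 (CHG), 0.15 (CHH). An optional beta-binomial variance-inflation
correction (method of moments over replicate heterogeneity) is available
and off by default.

Differentially methylated genes (DMGs) carry at least one DMR in the gene
body or the 2-kb flanks; each DMR's primary feature follows the precedence
promoter > gene body > downstream > intergenic with 1-bp overlap.
Enrichment of gene sets is a one-sided hypergeometric test with BH
correction, database-agnostic. Group-count comparisons (the >= 3-ASMR
category, below) use a chi-square test with continuity correction,
switching to Fisher's exact test when any expected cell is below 5.

Time-course patterns are clustered in the style of short time-series
expression mining: candidate profiles are integer-step trajectories
starting at 0 with per-step changes in -2..2, greedily reduced to 50 by
maximizing the minimum pairwise distance; each series joins its
highest-correlation profile (constant series join the flat profile by the
zero-distance rule), and profile significance comes from permuting every
series' time order (default 1000 permutations in the standalone function;
the pipeline uses a smaller default suited to its window counts, stated in
its argument).

## Expression, classes, and correlation

TPM is `(count/length) / sum(count/length) * 1e6` per sample with
exon-union lengths; columns sum to 1e6 exactly. Differential expression is
a per-gene negative-binomial GLM Wald test: median-of-ratios size factors,
gene-wise method-of-moments dispersion floored at 1e-4 (no shrinkage
toward a fitted trend — a documented deviation from the delegated tool),
and the `|log2FC| > 1 & FDR < 0.05` flag. Expression classes are I:
TPM = 0, II: (0,1], III: (1,10], IV: (10,100], V: > 100; class-wise
methylation comparisons use Wilcoxon-Mann-Whitney tests (exact when both
classes have at most 8 members, otherwise normal approximation with tie
correction) and a compact letter display at p < 0.05.

Bin-level methylation-expression correlation uses one expression value per
phase (replicate means; the replicate-resolved alternative is supported)
against replicate-pooled bin levels over the six WGBS phases. Significance
requires both `|r| > 0.6` and two-sided `p < 0.05` from the t-transform of
r — with six phases the p criterion dominates, and no genome-wide
correction is applied to this scan by design. A gene's sign is that of its
strongest significant bin.

## Allele pairing

Candidate homology between the two subgenomes' CDS sets is seeded by
shared 8-mers (at least 3), capped to the best candidates per gene by
shared-k-mer count; near-best partners always rank at the top of that
list, so the cap is an efficiency device that cannot displace a
reciprocal-best partner. Scores come from a banded Smith-Waterman local
alignment (match 2, mismatch -2, gap -3, band half-width 20 — substitution
divergence needs no wide band). A c-score filter keeps hits scoring at
least 0.99 of the best score of either gene, interpreting the synteny
tool's `-0.99` setting as a c-score cutoff. Collinear chains are extracted
per chromosome pair by dynamic programming (strictly monotone in both gene
ranks, gap at most 20 ranks, both orientations, greedy extraction of
successive longest chains, blocks of at least 4 anchors); genes unique
within a block become synteny pairs. Remaining genes go through
bidirectional best hits (deterministic lexicographic tie-break, ties
logged) and then a single-copy tier (BBH restricted to residual genes with
exactly one hit each). Precedence synteny > BBH > single-copy on disjoint
residual sets guarantees a partial matching: no gene in two pairs.

## Allele-specific expression

Size factors are computed across all alleles jointly per sample — the two
alleles share a library, and per-allele normalization would distort the
allelic ratio. Per-phase tests fit `count ~ allele` per pair (NB GLM,
method-of-moments dispersion floored at 1e-4) and Wald-test the allele
coefficient; bias requires `|log2FC| > 1 & FDR < 0.05` (BH within phase).
Phase-dependent tests fit `count ~ phase + allele + phase:allele` on the
baseline (LE) plus one phase and compare against the no-interaction model
by likelihood ratio; the interaction effect is the allelic log2 fold
change in the phase minus that at baseline, flagged by the same
`|effect| > 1 & FDR < 0.05` rule. Wald for marginal tests and LRT for the
interaction keeps the interaction's single degree of freedom explicit.
Consistency classes over per-phase calls: `consistent_*` (same bias every
phase), `shifting` (both directions observed), `phase_specific` (biased in
some but not all phases, one direction), `unbiased`. "Different parental
bias at different phases" has no formal rule in the source literature; the
shifting class is this package's operationalization. PCA uses centred
`log2(TPM + 1)` with alleles as observations.

## Allele-specific methylation

ASMRs compare allele pairs over the shared 80-bin scheme, bin i against
bin i by ordinal index (allele bodies differ in length, so coordinate
matching is not possible), using exactly the DMR test and significance
rule (shared code path, per-context thresholds inherited — the most
conservative reading of the source's "similarly"). An ASMG is a pair with
at least one ASMR in a context. For the bias-shift statistic, a region is
*matched* when significant in at least two phases and *shifted* when those
calls disagree in direction; regions significant once are stable by
default (the stricter of the two possible readings).

## Promoter TFBS analysis

Promoters are the strand-aware 2-kb upstream sequences. PWMs (MEME
minimal format) are scored as log2 odds against a 0-order background
estimated from the scanned promoter set and symmetrized between
complementary bases, with pseudocount 0.1 per cell. Scores are integerized
at a scale of 1000 and the exact distribution of the total score under the
background is built by dynamic-programming convolution over columns, so
every achievable score has an exact p-value; hits are positions (both
strands) with p < 1e-4, with no further correction. Presence vectors are
binary over the library; allele promoters are compared by cosine
similarity, with the both-zero case defined as similarity 1 (identical
absence) and flagged. CS classes are I-V in 0.2 steps. Within each class,
the Pearson correlation between maternal and paternal expression (mean
`log2(TPM+1)` across phases — the per-phase alternative is available) is
compared between all pairs and a designated group (e.g. phase-dependent
ASEGs) by Fisher's r-to-z two-sample test. TFBS methylation reuses the
weighted-region-level pooling on each hit footprint.

# The synthetic generator

The generator emulates the study system at desk scale and is the basis of
all validation. Defaults: two subgenomes of 2 chromosomes (not the real
19 — runtime is the only reason) carrying 500 allele pairs; gene bodies
lognormal around 1.5 kb; every gene flanked by 2 kb on both sides so
promoters never overlap neighbours; intergenic gaps of 0.6-1.4 kb, 30% of
them carrying a TE (LTR/LINE/DNA/SINE mix); 1% SNP divergence between
alleles; 10% of pairs relocated by a cyclic order permutation within their
chromosome to exercise the non-synteny pairing tiers.

Methylomes: each cytosine site is methylated-class with probability
`f(context)` (0.50/0.35/0.12 for CG/CHG/CHH, elevated on TEs with SINE
highest) and draws its true probability from a Beta component (high:
Beta(8,2)/Beta(5,3)/Beta(2,5); low: Beta(0.3,30)). These defaults were
chosen so genome summaries land near the magnitudes typical of a poplar
leaf methylome (mean mCG around 0.4, mCHH low); they are defaults, not
assertions. The two alleles share the underlying random draws
position-by-position through the slot map, so allele methylomes are
exchangeable unless an offset is configured — the property that makes the
ASMR null testable. Phase effects multiply the true probability: global
hypomethylation at the first induction phases (factors 0.833 and 0.909,
taken from the reported 16.67% and 9.14% decreases as default settings)
and a CHH decrease-then-increase trajectory. True DMR windows receive an
additive offset (default 0.4) from the induction phases onward; the
per-window offset is calibrated by bisection so the realized pooled
difference equals the nominal offset despite clipping to [0,1], and
windows that cannot express the offset in either direction are skipped —
truth windows are detectable by construction, which is what a recall
criterion requires. ASMG genes (30% of pairs) receive a constant allelic
offset over a 5-bin run of promoter-proximal bins (bins 8-20, where
cytosine density passes the per-bin filters in every context). Observed
data: replicate-level Beta jitter (concentration 200, i.e. between-replicate
standard deviation of roughly 0.03 at mid levels), Poisson coverage (mean
30), binomial methylated counts after the non-conversion adjustment
(rate 0.005).

Expression: pair means lognormal (median 150, log-sd 1.5) with 10% silent
pairs (near-zero mean) so all five TPM classes are populated at desk
scale; NB dispersion 0.05; 15% ASEGs with |log2FC| uniform in 1.5-3 split
symmetrically across alleles; 5% phase-dependent pairs that either acquire
bias at a random onset phase or flip its direction there; per-sample
library factors uniform in 0.8-1.25. Promoter motifs: a bundled synthetic
library of 24 sharp PWMs (widths 7-12; constructed for this package, not
derived from any database); each motif present in a pair with probability
0.4, embedded as its consensus word at a common non-overlapping position
in both promoters; presence flips to exactly one allele with probability
0.03, elevated to 0.25 for designated pairs (the phase-dependent ASEGs),
which couples promoter divergence to allelic expression divergence.

What the generator does not emulate: read-level errors and mapping bias,
TE sequence families, linked methylation between neighbouring sites,
trans-acting expression structure, and real promoter composition. Passing
tests therefore demonstrate the correctness and calibration of the
statistics under a faithful null and controlled effects — not performance
on real bisulfite libraries.

# Numerical choices and edge cases

* Internal coordinates are 1-based closed `GRanges` everywhere, the
  Bioconductor convention; BED I/O converts at the boundary via
  rtracklayer. This intentionally replaces a 0-based internal convention:
  in this ecosystem the container defines the convention, and a second
  internal convention would invite off-by-one drift.
* Likelihoods at fitted proportions 0 or 1 use the saturated value 0;
  LRT statistics are floored at 0.
* NB IRLS: coefficient-change tolerance 1e-8, at most 100 iterations,
  means capped at 1e12; the two-group fit uses per-group Newton steps on
  the log mean (the groups are orthogonal), clamped to +-5 per step.
* Dispersion: method of moments per design cell, shot-noise corrected by
  the mean inverse size factor, averaged over cells, floored at 1e-4 and
  capped at 10. The floor, not a trend fit, is the fallback.
* Cosine similarity snaps values within 1e-12 of 1 to exactly 1; the
  both-zero case is 1 with a flag.
* PWM integerization at scale 1000 makes the DP tail and brute-force word
  enumeration agree exactly (the acceptance oracle checks widths <= 6).
* The STEM-style permutation p-value uses the add-one estimator
  `(1 + #{perm >= obs}) / (B + 1)` and a fixed seed.
* Compact letter display: classes ordered by median; maximal consecutive
  runs whose internal pairs are all non-significant share a letter.

# Problem sizes

The default pipeline (500 pairs, 2+2 chromosomes, ~6.5 Mb, 18 methylome
samples at 30x, 24 expression samples) runs in a few minutes on one CPU.
The test suite uses the same generator at 2-40x smaller gene counts per
property; the error-control checks run at ~380 pairs over 2 chromosomes
per subgenome (about 50k sliding windows per context) and 2000 simulated
null allele pairs. These sizes are the package's chosen validation scale:
large enough for stable rates, small enough to iterate quickly.

# Known limitations

* The banded aligner assumes substitution-dominated divergence; large
  indels would need a wider band or an external aligner (12-column
  tabular hits are accepted as input for that case).
* The binomial LRT ignores residual overdispersion unless the optional
  inflation correction is enabled; under strong replicate heterogeneity
  q-values can be anticonservative (the simulated conditions keep the
  realized null well inside the acceptance bound).
* The STEM-style clustering is a simplification: profile reduction is
  greedy and significance is per-profile, without the original's
  multiple-testing layer.
* Single-exon gene models are assumed by the simulator (the GFF3 reader
  handles multi-exon models and exon-union lengths).
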