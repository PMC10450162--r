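---
title: "Cataloging sense/antisense pairs and correlating their fold-changes"
author: "antisensePairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloging sense/antisense pairs and correlating their fold-changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisensePairs)
```

## The question and the procedure

Antisense long non-coding RNAs overlap protein-coding genes from the
opposite strand, and for individual loci (the yeast *PHO84* locus is the
canonical example) antisense transcription has been proposed to repress the
sense gene. If antisense RNA were broadly repressive, a perturbation that
raises antisense levels should lower sense levels: across all overlapping
pairs, the log fold-changes of sense and antisense transcripts between two
conditions should correlate *negatively*. The pipeline in this package
measures that correlation:

1. build the catalog of gene/antisense-ncRNA pairs from coordinate overlap;
2. compute differential expression (treatment vs. control) for genes and
   ncRNAs separately, from count matrices;
3. among pairs whose gene is significant at an FDR threshold (default
   0.25), compute the Pearson correlation of the two log2 fold-change
   vectors and its significance.

The package deliberately consumes *count matrices*, not reads: alignment
and read counting are upstream concerns with mature tools of their own, and
keeping them out makes every stage here exactly reproducible.

## Pair catalog

Features are single stranded intervals, 1-based inclusive internally; BED
input is converted on read (start + 1) and back on write. Three rules define
the catalog:

* **Overlap** means at least one shared base on the same chromosome
  (`[max(starts), min(ends)]` non-empty); abutting intervals do not overlap.
  This is the standard inner-join semantics of genomic ranges.
* **Opposite strands only.** Unstranded records are rejected at input
  validation rather than silently dropped, because an unstranded record
  cannot participate in an antisense analysis at all.
* **One ncRNA per gene:** the ncRNA with the greatest full annotated length
  wins. Length of the *transcript*, not of the overlap, is the criterion —
  "longest ncRNA" is a property of the partner, and overlap length would
  make the choice depend on the gene. Ties (possible in coordinate sets that
  quantize boundaries) are broken deterministically: smaller ncRNA start,
  then lexicographically smaller id.

A ncRNA may still appear under several genes; the resolution is per gene.
The join itself runs on GenomicRanges interval trees; the test suite holds
an independent naive all-pairs implementation of the same three rules and
requires exact agreement on random genomes, so the fast path is never the
only witness to its own correctness.

Chromosome names are compared as exact strings. Silent "chr" aliasing hides
real input errors (mixed annotation releases); users with mismatched naming
should fix the inputs, not the comparator.

## Differential expression model

The two-condition DE test is authored here rather than delegated, so that
every constant in the pipeline is specified and the whole analysis is
reproducible from this document alone. It is a deliberately transparent
DESeq-style NB Wald test:

* **Normalization** — median-of-ratios size factors over features with
  all-positive counts. Factors are not rescaled to unit geometric mean
  afterward; only ratios of factors matter downstream.
* **Dispersion** — per-feature method-of-moments in the
  `Var = μ + αμ²` parameterization: `α̂ = max(α_floor, (v − m)/m²)` with
  `m` the grand mean of normalized counts, `v` the pooled within-condition
  variance (df = n − 2), and `α_floor = 1e-8`. There is no shrinkage toward
  a mean-dispersion trend: at the replicate numbers this pipeline targets
  (≥ 6 per group for recovery, ≥ 10 for calibration) the per-feature
  estimate is adequate, and the estimator stays a two-line formula. This is
  a known deviation from shrinkage-based estimators and costs power at 2–3
  replicates.
* **Wald test** — with condition means `μ̂_T`, `μ̂_C` of normalized counts
  and pseudocount `c₀ = 0.5`, `log2FC = log2((μ̂_T + c₀)/(μ̂_C + c₀))`;
  the delta method gives
  `se = (1/ln 2)·sqrt(Var(μ̂_T)/(μ̂_T+c₀)² + Var(μ̂_C)/(μ̂_C+c₀)²)` with
  `Var(μ̂_c) = (μ̂_c + α̂μ̂_c²)/n_c`, and `z = log2FC/se` is referred to the
  standard normal. Features with zero counts everywhere are flagged
  untestable and given p = 1 rather than dropped, so output rows always
  align with input features. Benjamini–Hochberg adjustment (via
  `p.adjust`) yields q-values.

Two numerical consequences are worth knowing. First, the pseudocount
shrinks extreme fold-changes of barely-expressed features toward 0; `c₀` is
an exposed argument. Second, the normal reference for `z` ignores the
degrees of freedom spent estimating the variance: at 10 vs 10 replicates
the statistic behaves approximately like a t with ~18 df, so the realized
type-I error at the nominal 0.05 level sits slightly above nominal
(typically 0.05–0.08 across simulation seeds, ≈ 0.068 on average). This is
an inherent property of a plug-in Wald test at small n, shared by the
standard tools; the acceptance checks measure it rather than hide it.

One identifiability point that the test suite makes explicit: a fold-change
shared by *every* feature is absorbed into the size factors by
median-of-ratios normalization. The DE test measures fold-changes relative
to the bulk of the transcriptome, which is the intended behaviour for this
analysis; simulations that plant a global shift must therefore supply the
true size factors to recover it.

## Correlation of fold-changes

"Log fold-change" is taken as log2; the base rescales both axes identically
and cannot change `r`. Selection uses the *gene* (sense) q-value only, with
strict inequality `q < threshold`; an option additionally requires ncRNA
significance for sensitivity analyses, but the default follows the
gene-level reading because the sense gene is the regulatory target under
test. The correlation is undefined (NA, with a warning status rather than
an error) below 3 retained pairs or when a fold-change vector is constant.

## What the generator emulates — and what it does not

The synthetic module builds a yeast-like genome: non-overlapping genes
(lengths U[500, 3000] bp, gaps U[200, 1000] bp, ≤ 500 genes per chromosome,
strands alternating), and for a configurable fraction of genes one
opposite-strand ncRNA of target length U[200, 1500] bp overlapping the
gene's 3′ half by ≥ 100 bases — the geometry typical of yeast antisense
transcripts, which initiate near the sense 3′ end. The ncRNA starts inside
its gene and its extension is clipped at the neighbouring gap, so each
planted ncRNA overlaps exactly its own gene and the planted truth *is* the
expected catalog. Decoys exercise the filters: intergenic ncRNAs (overlap
nothing) and same-strand ncRNAs contained in genes (removed by the strand
filter), each 5% of the gene count by default.

Counts follow the same NB convention as the estimator
(`Var = μ + αμ²`, Poisson at α = 0). True gene effects are
`g ~ N(0, effect_sd²)`; each paired ncRNA gets
`a = ρ·g + sqrt(1 − ρ²)·ε`, `ε ~ N(0, effect_sd²)`, so the planted
correlation is exactly ρ in expectation and is imposed on *true effects*,
not on counts — the observed pipeline estimate is mildly attenuated by
estimation noise in both coordinates, which the recovery tolerances
accommodate and a dedicated test confirms is attenuation, never inflation.

Defaults are the study conditions used throughout the tests: 1500 genes,
all with partners, `effect_sd = 1`, dispersion 0.01, 6 vs 6 replicates,
library-size factors U(0.7, 1.3), baselines LogNormal(log 1500, 0.4) —
median 1500 and ~99.7% of baseline means above 500 counts, i.e. deeply
covered features where fold-changes are well estimated. Real TT-seq or
RNA-seq data differ in ways the generator does not model: baseline means
span several orders of magnitude with many low-count features, dispersion
trends with the mean, ncRNA quantification inherits strand-specific
counting artifacts, and sense/antisense counts at one locus can be
correlated through shared sequencing noise. Passing recovery tests
therefore validate the *pipeline's estimators and plumbing*, not the claim
that any particular real dataset has a given ρ.

All randomness flows from one master seed through per-stage derived seeds,
so annotations and counts can be regenerated independently and any one
stage can be re-run in isolation.

## Problem sizes and determinism

The validation suite uses 50 random genomes (≤ 500 genes × ≤ 1000 ncRNAs)
for the pairing oracle, 1500-pair datasets at 6 vs 6 replicates for
recovery of ρ ∈ {0, 0.5, 0.9}, and a 2000-feature 10 vs 10 null for test
calibration — sizes at which the quantities being checked have small enough
sampling error to be meaningful while the whole suite stays quick. The
pipeline itself is deterministic: identical inputs give byte-identical
outputs, and the run summary (versioned JSON schema) records every stage
count and every dropped-record count so that `kept + dropped` can always be
reconciled with the input sizes.

## Known limitations

* Two groups only; no GLM designs, likelihood-ratio tests, or shrunken
  fold-change estimators.
* Features are single intervals; transcript isoform structure (exons,
  alternative 3′ ends) is out of scope, matching how published CUT/SUT/XUT
  coordinate tables are distributed.
* The Wald p-values are mildly anti-conservative at small replicate
  numbers (see above); at 2–3 replicates per group, treat marginal
  q-values with caution.
* Reproducing published pair-catalog counts for a real genome requires the
  corresponding published coordinate sets as inputs; the run summary
  exposes the candidate-pair, distinct-gene and distinct-ncRNA counts
  needed for such comparisons.
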