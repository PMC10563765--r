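---
title: "Methods: integrated RNA/ATAC analysis of somite maturation"
author: "somiteMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated RNA/ATAC analysis of somite maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somiteMap)
library(SummarizedExperiment)
```

# Scope and data model

somiteMap analyses matched bulk RNA-seq and ATAC-seq profiles of
individual somites collected as stage-by-somite-age cohorts: embryos at
six developmental stages (8, 18, 21, 25, 27 and 35 somite pairs), and
from each embryo the three most recently segmented somites (SI is the
youngest). One somite of each bilateral pair provides the transcriptome,
the other the open-chromatin map, so samples are paired one-to-one
between the two modalities.

All interval annotation lives in a `GenomeModel` (S4, validity-checked):
chromosome lengths, gene bodies with strand (the TSS is the most 5'
coordinate of the gene on its strand), exons, a unified non-overlapping
peak set and a blacklist. Counts travel as `RangedSummarizedExperiment`
objects; fragments as `GRanges`. Coordinates are 1-based closed
internally (the `GRanges` native convention); BED input/output is
converted at the boundary, and documentation of insertion arithmetic is
phrased in the 0-based half-open convention BED users expect.

# ATAC library quality control

Three measures feed a gate:

* **Insert-size distribution score (0-4)** — the number of nucleosomal
  modes in the fragment-length histogram. Published analyses scored
  this by eye; here detection is automated: the per-bp log-count
  histogram is smoothed with a Gaussian kernel (sigma = 10 bp) and a
  mode is counted in each of the bands (120, 280], (280, 470],
  (470, 660] and (660, 900] bp whose smoothed maximum exceeds the
  preceding local minimum by a prominence factor (default 1.15) and
  which holds at least 10 fragments. The band boundaries sit at the
  antinodes of the ~200 bp nucleosomal ladder, so each band can contain
  exactly one ladder mode.
* **TSS enrichment** — Tn5 insertion points (fragment ends shifted
  +5/-4 bp) are profiled over 2 kb windows centered at the TSS of
  expressed genes (mean normalized CPM > 10, supplied by the RNA side),
  strand-oriented and averaged across genes. The mean of the first and
  last 100 bp estimates the background rate; the score is the maximum
  of the smoothed fold-enrichment curve (the ENCODE-style scalar).
  Whether "the" TSS score should be the curve maximum or the value at
  the TSS itself is a convention choice; the maximum is used because
  the mononucleosomal shoulders otherwise penalise sharp profiles. A
  101 bp running mean stabilises the maximum against per-bp sampling
  noise.
* **FRiP** — the fraction of fragments overlapping the unified peak
  set.

A library passes when at least three of four criteria hold: score >= 2,
FRiP >= 3%, >= 15,000 called peaks, TSS enrichment >= 5. Per-sample
peak counts are an input: per-sample peak calling happens upstream of
this package.

# Normalization and removal of unwanted variation

**Expression filter.** Genes with >= 10 counts in >= 3 samples are
kept.

**TMM.** Composition-robust size factors via the weighted trimmed mean
of M-values (edgeR's implementation; 30% M-trim, 5% A-trim, precision
weights), rescaled to geometric mean 1. Normalized expression is
log2(CPM + 0.5).

**Loess offsets for windowed ATAC counts.** ATAC efficiency biases are
abundance-dependent: MA curves between samples bend with mean
abundance, so a single size factor cannot normalize them. For each
sample a loess curve (span 0.4, degree 1, evaluated on a 200-point
abundance grid and interpolated) of that sample's log2-count deviation
from the cross-sample mean log2 abundance is fitted against abundance;
the fitted values are centered across samples within each window and
subtracted as offsets (equivalently, passed to the GLM as per-window
effective library sizes). The span was chosen for stability at a few
thousand windows; degree 1 avoids edge oscillation in the extreme
abundance deciles.

**Residual-PCA covariates.** Collection-date batch effects are partly
confounded with stage (early and late stages were collected on disjoint
dates), so the batch label cannot enter the model. Instead a per-feature
least-squares fit of the stage-by-somite group means is removed, PCA is
run on the residuals, and the number of components kept is chosen by
parallel analysis: each feature's residuals are permuted independently
across samples, re-residualized against the design (so the permuted
spectrum lives in the same residual subspace — omitting this step
systematically over-selects), and the retained components are the
leading run whose variance share beats the permutation distribution at
alpha = 0.05. The covariates are the corresponding residual PC scores,
unit-normalized; they are orthogonal to the design by construction. The
permutation spectrum is computed from residuals rather than from the
normalized counts; a residual source keeps the observed and null
spectra comparable, which is the property the selection rule needs.

Two properties of this correction are worth stating plainly. A batch
direction orthogonal to the design is recovered essentially exactly
(correlation with truth ~1) and restoring it to the model returns
type-I error to nominal; without the covariate, the batch variance is
absorbed into the per-feature dispersion and the quasi-likelihood tests
become conservative. Conversely, a batch component lying inside the
design span is invisible to residual PCA *by construction* — no
covariate can repair a fully confounded contrast, which is exactly the
caveat the partially confounded collection design carries.

# Differential testing

Per-feature negative-binomial GLMs are fitted on the group-mean design
(one coefficient per stage-by-somite group) plus the covariates, with
robust empirical-Bayes trended dispersion and quasi-likelihood F-tests
(edgeR's estimateDisp/glmQLFit/glmQLFTest). Four contrast families are
generated:

1. each somite-age pair averaged over all stages (weights +/- 1/6 with
   six stages);
2. the three somite-age pairs within each stage, tested jointly (one
   p-value per stage: "does the feature differ between at least one
   pair of somite ages here?");
3. all stage pairs averaged over somite ages (weights +/- 1/3), tested
   jointly;
4. all stage pairs within each somite age, tested jointly.

Significance requires FDR < 0.05 (BH within family) *and*
|fold-change| > 1.5. For joint families the member fold-change of
largest magnitude feeds the gate and is reported, so the rule can be
audited per member.

# Window-level differential accessibility

Fragments are counted in 150 bp windows sliding by 50 bp (fragments
overlapping the blacklist are excluded entirely; windows with summed
count < 75 are dropped), then filtered to windows overlapping the
unified peak set with mean count >= 4. After testing, windows no more
than 150 bp apart are merged transitively; merged spans wider than
1.5 kb are split into ceil(span/1500) overlapping sub-regions of
near-equal width (within about 100 bp of span/k, never wider than
1.5 kb, start positions spread evenly with ties toward the 5' end), and
each window joins every sub-region it overlaps. The region p-value is
the Simes combination min_i(n p_(i) / i) of its member windows
(ties in the sort broken by original window order), correction is at
the region level, and the region fold-change is that of the member
window with the smallest p-value. Region-level correction is what keeps
the FDR honest in the face of correlated adjacent windows.

# Peak classification

Each peak receives exactly one class with precedence promoter > exonic
> proximal > distal > intergenic: promoter when within 200 bp of a TSS
(peak edge to TSS point), exonic when overlapping an exon, proximal
within 25 kb and distal within 100 kb of a gene body (edge-to-edge,
strand-independent), intergenic beyond. Edge-based distances are the
permissive, conventional reading; gene body (not TSS) anchors the
25/100 kb bands.

# Motif accessibility deviations and enrichment

For motif m and sample j the observed count over member peaks is
compared with the expectation under a depth-only model,
e = (sum of member-peak count fractions) x (sample total); the raw
deviation (o - e)/e is bias-corrected by subtracting the mean deviation
of GC/accessibility-matched background peak sets and standardized by
their SD to a z-score (z is reported missing when the background SD is
zero, never as 0). Backgrounds are drawn with replacement from
equal-frequency 2-D bins of (GC fraction, mean accessibility); 50
iterations by default. Overlapping windows are pruned first (the most
abundant window per overlap run is kept). Motif enrichment between a
differential and a non-differential peak set subsamples the background
to the foreground's length-decile profile and applies one-sided Fisher
tests with BH correction.

# Peak-gene linkage and regulation scores

For every candidate gene and each peak whose midpoint lies within
100 kb of its TSS, the Spearman correlation of (corrected) expression
and accessibility across the paired samples is compared against the
correlations of the same gene with 100 background peaks matched for GC
and mean accessibility; the p-value is a one-sided z-test against the
background mean/SD (100 draws limit the resolution of an empirical
rank, hence the parametric null). When the background set contains
fewer than 50 *different* peaks the null is degenerate and the p-value
is set to missing, excluding the pair. Kept links satisfy p < 0.05 and
correlation > 0.3. The number of attribute bins adapts to the peak
universe (about 100 peaks per bin, between 2 and 10 bins per axis);
with fewer than ~50 distinct candidates per bin every pair would be
guarded out, which is the correct behaviour for a peak set too small to
furnish a null.

Genes with more than 5 kept peaks are flagged highly regulated; their
DORC score per sample is the sum of linked-peak accessibility. For each
(TF, flagged gene) pair the TF's motif enrichment in the gene's kept
peaks (against matched background peaks) and the rank correlation
between TF expression and the gene's DORC score combine into
score = sign(rho) x sqrt(-log10 p_enrich x -log10 p_corr), capped at
10; |score| > 1.25 flags a putative interaction. The combination is
monotone in both significances and signed by the expression-
accessibility direction, so repressors (motif enriched, expression
anti-correlated with accessibility) receive negative scores. The exact
combination function used elsewhere in the field is not uniquely
fixed; this g is recorded in the output and configurable, and the
1.25 gate should be re-examined if g is changed.

# The synthetic-data generator

The generator exists so every stage can be verified against planted
truth at desk scale. It emulates:

* NB counts with stage-by-somite group means; planted differential
  features carry a centered log2 gradient along the somite or stage
  axis whose extreme-group contrast equals the configured magnitude
  (default 2-fold);
* multiplicative per-gene log-normal batch factors (default SD 0.4
  log2) with early and late stages on disjoint collection dates — the
  partially confounded design; alternative schemes (round-robin,
  imbalanced) exist for calibration studies;
* a smooth abundance-dependent efficiency bias in ATAC counts
  (amplitude x tanh of standardized log abundance, varying across
  samples; default amplitude 0.3);
* fragment-length mixtures of truncated normals at 75/200/400/600/800
  bp with decaying weights — the sub-nucleosomal to tetra-nucleosome
  ladder — with good libraries placing elevated insertion rates in
  peaks and around TSSs and bad libraries uniform and sub-nucleosomal
  only;
* peaks with GC content drawn Beta(5, 5) and a stored mean-accessibility
  attribute (matched-background sampling needs the attributes, not
  sequence);
* planted peak-gene links: a latent factor per regulator is shared
  between target-gene expression and linked-peak accessibility, with
  the loading chosen so the realized correlation approximates the
  configured target (default 0.9) given the NB noise at the feature's
  abundance; planted TF regulators track the latent positively
  (activators) or negatively (repressors), and their motifs are set in
  the linked peaks of their targets.

Genes occupy the first 60% of each chromosome; the remaining desert
guarantees distal and intergenic peaks. RNA and ATAC samples are
generated as fully matched pairs by default, emulating the paired
design.

What the generator does *not* emulate — and hence what green tests do
not certify about real data: sequence-level artifacts (mappability, GC
amplification curves beyond the stored attribute), cell-composition
drift within somites, correlated gene programs beyond the planted
latents, per-sample peak calling and duplicate structure. Calibration
on this generator shows the machinery is correct, not that real somite
data meet its assumptions.

# Problem sizes and numerical choices

Tests and the acceptance script run cohorts of 24-72 samples with
500-5,000 genes and up to ~6,500 windows, 20-seed replication for null
calibration — sizes at which decile means, KS statistics and recovery
rates are estimable while the whole suite stays interactive. Degenerate
inputs are handled explicitly: empty fragment sets yield failing QC,
empty peak sets yield warnings and empty results, motifs without member
peaks and z-scores with zero background SD are reported missing,
non-estimable linkage nulls are guarded out, and Simes of a single
window is that window's p-value. Seeds fully determine all generator
output; pipeline reruns with the same seed are byte-identical.

# Known limitations

* A fully confounded batch component (inside the design span) cannot
  be corrected, only acknowledged; stage-axis contrasts under the
  stage-split batch scheme carry that risk, exactly as the underlying
  collection design does.
* The insert-size score automates a visual call; prominence 1.15 and
  sigma 10 bp reproduce the intended banding on the generator's
  mixtures, but real libraries with unusual ladder spacing may need the
  prominence knob.
* The regulation-score combination g is one reasonable monotone choice;
  comparability of the 1.25 threshold across different g's is not
  guaranteed.
* Window counts tested as NB GLMs treat overlapping sliding windows as
  features; region-level Simes correction addresses the resulting
  dependence at the call level, not at the estimation level.

# A short end-to-end example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1)
report <- runPipeline(cfg, quiet = TRUE)
report$qc                       # per-library QC gate
report$classes                  # peak genomic-context table
head(report$linkage$links)      # peak-gene linkage table
report$linkage$regulation       # signed TF-gene regulation scores
```
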