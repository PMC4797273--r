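---
title: "Modeling TF–TF co-occupancy from chromatin features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TF-TF co-occupancy from chromatin features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccupy)
```

## The problem

Transcription factors (TFs) often bind regulatory DNA together. Given
ChIP-seq peak sets for two TFs in one cell type, every binding site falls
into one of three event categories: bound by the first TF only, bound by
the second only, or co-occupied by both. `cooccupy` asks whether the local
chromatin context — DNase I accessibility, histone modifications (HMs), GC
content, CpG methylation, chromatin state — distinguishes co-occupied sites
from solo sites, and whether a classifier trained on those features in one
cell type predicts co-occupancy in another.

## Event classification

Two peaks form a co-occupied event when each covers at least a fraction
`min_frac` of the other (reciprocal overlap; default 0.30, the conventional
criterion for ChIP-seq co-localization). Overlap is computed on the full
peak intervals in BED half-open coordinates; peak summits are used only
downstream, as the representative binding positions around which feature
windows are centered.

A co-occupied region contributes two records — one per source TF — because
the two TFs' summits generally differ, so the two sides of the same region
see (slightly) different chromatin windows and are analysed as separate
contrasts.

Design choices that the overlap rule itself does not determine:

* **Single best partner.** A peak with several qualifying partners is
  assigned the one maximising the smaller of the two overlap fractions,
  with ties broken by leftmost partner start, then end, then input order.
  Multi-partner bookkeeping would complicate the event table without
  changing the class labels; a deterministic rule is required for
  reproducibility.
* **Threshold exposure.** `min_frac` is a parameter; classifications at
  stricter thresholds are monotonically contained in looser ones, which the
  test suite asserts.

The interval-tree implementation is validated against an all-pairs
brute-force classifier (identical categories *and* partners) on hundreds of
random instances.

## Feature quantification

For each event record, signal features are measured in the 100-bp window
centered at the summit: the read count of each track is converted to RPKM
(`count / (window/1000) / (library_size/1e6)`) and transformed as
`log2(RPKM + 1)`. Choices the measurement convention leaves open:

* **Read-to-window rule**: a read counts when it overlaps the window by at
  least 1 bp. (A 5'-end rule would undercount reads straddling the window
  edge; either is defensible, the overlap rule is the package default.)
* **Pseudocount 1.0** inside the log2 keeps zero-count windows at exactly 0
  and is configurable.
* **GC content** is computed on the same 100-bp window from the genome
  sequence, `(G+C)/(A+C+G+T)` with `N` excluded from the denominator.
* **Methylation** is the mean beta over CpG sites inside the window. Most
  binding sites carry no covered CpG; when methylation is part of the
  feature set, CpG-free rows are dropped rather than imputed, restricting
  that analysis to the CpG-bearing subset (in the bundled synthetic cell,
  166 of 1000 sites).
* **Chromatin state** is the label of the segmentation interval containing
  the summit (half-open convention; gaps give a missing value), one-hot
  encoded over the 15-state alphabet.
* **Strand is ignored** throughout; windows are never orientation-flipped.

Profiles for visual comparison use the same RPKM unit per 100-bp bin across
a 6-kb span centered at summits (60 bins, centers −2950…+2950). Bins
clipped at a chromosome edge are excluded from that site's contribution
rather than zero-filled.

## Statistical contrasts

Each feature is compared between co-occupied and solo events with a
two-sample t-test. The default is Welch's unequal-variance form — group
sizes and variances differ substantially in practice — with the pooled
Student form available (`equal_variance = TRUE`). Raw p-values are the
primary readout (conventional practice for these enrichment contrasts);
a Benjamini–Hochberg column is emitted for users who prefer adjusted
values. Degenerate zero-variance inputs use the convention t = 0, p = 1
for equal means and p = 0 otherwise.

## Classifiers and evaluation

Four classifier kinds discriminate co-occupied (label 1) from solo
(label 0) events:

* `rbf_margin` — RBF-kernel SVM (via e1071/LIBSVM), cost 1 and kernel
  width 1/n_features on standardized data; no tuning by default since the
  evaluation compares feature sets, not hyperparameter schedules.
* `tree_ensemble` — random forest (via randomForest), 500 trees.
* `gaussian_nb` — Gaussian naive Bayes, implemented from its closed form
  (per-class feature means/variances, log-odds scores).
* `linear_discriminant` — Fisher LDA, implemented from its closed form
  (pooled covariance, weights `solve(S, mu1 - mu0)`, ridge fallback when
  the pooled covariance is singular).

The two linear kinds are written from their closed forms so that the
linear-versus-nonlinear comparison — the question of whether HM channels
relate to co-occupancy nonlinearly — does not depend on an opaque
third-party implementation; both are verified against their analytic
solutions in the test suite.

All kinds see z-scored features, with means and SDs taken from the
training rows only (the RBF kernel requires a common scale; it is harmless
for the others). Constant features are kept with an SD floor. Scores are
oriented and centered so 0 is the decision threshold for every kind
(log-odds, SVM decision value, forest vote fraction − 1/2); accuracy is
reported at that threshold, and the threshold is a parameter. No class
rebalancing is applied: AUC is insensitive to imbalance and ACC is
reported as-is.

Evaluation repeats a stratified split — 2/3 of each class to training,
the rest to testing — ten times by default, reporting per-repetition and
mean AUC/ACC. AUC is computed as the rank statistic
P(score_pos > score_neg) + ½P(tie), which the tests verify against
brute-force pair counting to 1e-12. A master seed fans out
deterministically to per-repetition splits and fits, so identical inputs,
configuration and seed give bitwise-identical outputs.

Cross-cell transfer applies a trained model — including its training-cell
standardization — to the full feature matrix of another cell, with no
refitting and no split. (Using the other cell's test third instead would
only shrink the evaluation set; the full set is the package's choice.)
Conservation of the feature/co-occupancy relationship is summarised by
|ΔAUC|, the absolute difference between within-cell and cross-cell mean
AUC.

## The synthetic-data generator

The generator emulates the complete input bundle so the pipeline can be
exercised and calibrated end to end without external data. Its defaults
are the package's study conditions: 500 events per category, 300-bp peaks,
12 feature channels (DNase + 11 HMs), negative-binomial counts with
dispersion 10 around 20 reads per 100-bp window, library size 10^6, 36-bp
reads, +1.5 log2 enrichment at co-occupied sites on the six active
channels (DNase, H3K27ac, H3K4me2, H3K4me3, H3K9ac, H2A.Z), 0 on five, and
−0.5 on H3K27me3 — the direction and rough magnitude of the enrichment
contrasts seen at real co-occupied sites.

Construction guarantees worth knowing:

* **Exact truth labels.** Solo peaks occupy disjoint slots, so they share
  no qualifying overlap; co-occupied partners share a slot with a
  normally-jittered summit offset (sd 40 bp) clamped so reciprocal overlap
  always exceeds the 30% criterion. Truth labels are therefore exact, and
  the suite asserts that re-classifying the written files reproduces them
  for 100% of sites.
* **Exact effect sizes.** Reads for a site are scattered uniformly over a
  600-bp signal region centered on the site (the solo summit, or the co
  pair's summit midpoint), with the region count scaled by the analytic
  window capture probability. Binomial thinning of a negative binomial
  preserves its dispersion, so the count landing in any 100-bp summit
  window is negative binomial with exactly the configured mean — the
  configured log2 effects are recoverable from extracted features
  regardless of summit jitter, and the two windows of a co pair share
  reads the way a broad histone-mark domain would.
* **Class-linked covariates.** Sequence inside event windows is i.i.d.
  with class-dependent G+C probability (0.55 co vs 0.45 solo over a 0.40
  background); CpGs are Poisson-placed (2/kb) with Beta-distributed betas
  hypomethylated at co-occupied windows (mean 0.3 vs 0.6 solo, 0.8
  background); segmentation bins holding a co-occupied summit are assigned
  a low-index "active" state with probability 0.8 (0.3 for solo).
* **Poisson limit.** Dispersion `Inf` dispatches to a Poisson draw, which
  is unit-tested.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: mappability and copy-number artifacts, fragment
-size distributions and strand asymmetry, motif-bearing sequence,
correlated feature channels beyond the shared class structure, peak-width
and signal heterogeneity, and biological confounding between GC, CpG
density and methylation. Results on the generator certify the machinery
(classification, quantification, statistics, evaluation), not biological
effect sizes.

## Problem sizes and numerical choices

The bundled analyses and tests run at 500 events per category (the
calibration experiments use 20 seeds for null calibration, 10 for signal
recovery), sizes at which the null mean AUC of every classifier sits in
[0.45, 0.55] and planted +1.5 log2 effects saturate the RBF model's AUC.
SD floors (1e-8) keep constant features harmless; the LDA ridge fallback
activates only on singular pooled covariance; window clipping at
chromosome edges is logged and clipped bins are excluded from profiles.
Ties in AUC are counted half; ties in partner selection break
deterministically leftmost.

## Known limitations

* Only two-TF classification is supported; multi-TF hotspot detection is
  out of scope.
* Coverage (bedGraph) tracks are accepted as an alternative to read
  intervals, but the windowed statistic is then the base-pair-weighted
  mean coverage, not RPKM (no read count exists in that mode); the two
  modes are not numerically interchangeable.
* The margin and ensemble model kinds serialize as R objects, not JSON;
  only the closed-form kinds have a portable JSON representation.
* No peak calling, IDR filtering, duplicate removal or blacklist
  filtering: the pipeline starts from called, filtered peaks, as its
  inputs are defined.
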