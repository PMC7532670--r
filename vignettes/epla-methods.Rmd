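---
title: "Ensemble patch-likelihood aggregation for microsatellite status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble patch-likelihood aggregation for microsatellite status: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Microsatellite instability (MSI) arises from mismatch-repair deficiency and
predicts benefit from immune checkpoint blockade, yet most patients never
receive a dedicated MSI assay. A haematoxylin–eosin whole-slide image (WSI)
exists for essentially every cancer patient, and MSI leaves visible traces
in it — poor differentiation, lymphocytic infiltration. `pathomsi`
implements a two-stage predictor of slide-level microsatellite status from
such images.

**Stage 1 — patch likelihoods under MIL.** A WSI is far too large to
classify whole, and only some regions carry signal. The slide is reduced to
the pathologist-annotated carcinoma region (ROI), tiled into 512×512
patches on a non-overlapping grid anchored at the slide origin, and a patch
is kept only when its area overlap with the ROI polygon union is *strictly*
greater than 0.8. Under the multiple-instance shortcut each patch inherits
its slide's label; a convolutional discriminator is trained on these noisy
targets with binary cross-entropy and mini-batch SGD (momentum 0.9), and
its sigmoid output is the patch's MSI likelihood. The MIL premise is that a
minority of "key" patches carries most of the class information, so many
inherited patch labels are wrong individually while the bag statistics
remain informative.

**Stage 2 — bag aggregation.** Each slide's bag of likelihoods is
summarised twice:

* *PALHI*: the occurrence histogram over 100 equal-width bins on $[0,1]$
  (bin $i$ is $[(i-1)/100, i/100)$, the last bin closed, frequencies
  normalised to sum to 1), classified with gradient-boosted trees.
* *BoW*: likelihood $p$ maps to word $\lceil 100p \rceil$ (clamped to
  $[1,100]$, so $p=0$ is word 1); the slide becomes a TF–IDF vector with
  smoothed IDF $\ln\frac{1+N}{1+\mathrm{df}(w)} + 1$, L2-normalised, and is
  classified with Gaussian naive Bayes.

The concatenated histogram and TF–IDF coordinates are the slide's 200
pathological signatures `FEA#001`–`FEA#200`. The final score is the convex
ensemble $\alpha\,s_{\text{PALHI}} + (1-\alpha)\,s_{\text{BoW}}$; a slide is
called MSI when the score is at or above the fitted cutoff.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| patch size / crop | 512 px → centre 224 px | tile geometry at 20× (≈0.5 µm/px); the 224 crop starts at pixel (144,144) |
| ROI overlap filter | > 0.8, strict | excludes patches dominated by stroma or background |
| histogram bins / vocabulary | 100 / 100 | resolution of the bag summary; 200 signatures total |
| xgboost grid | depth {2,3,4} × trees {50,100,200} × η {0.05,0.1,0.3} | chosen by stratified 5-fold CV maximising slide-level AUC |
| NB variance smoothing | 1e-9 × max feature variance | keeps constant TF–IDF coordinates finite and uninformative |
| ensemble α | grid 0…1 step 0.01 | fitted on *out-of-fold* training scores only; ties break toward 0.5 |
| cutoff | Youden optimum of out-of-fold ensemble scores | `score ≥ cutoff` ⇒ MSI |
| labelling rules | MSIsensor ≥ 10; ≥ 2 of 5 unstable loci | sequencing- and PCR-panel-based gold labels; MSI-L pools with MSS |
| split | 7:3 stratified, per-class rounding with ties toward train | preserves prevalence in both sets |
| SGD | lr 0.05, momentum 0.9, batch 16 | training hyperparameters were not externally constrained; these are conventional small-scale values, exposed in `patch_model_config()` |

## The convolutional backbone

No deep-learning framework is assumed: the discriminator is a compact CNN
written directly in R — conv 5×5 (3→8) + ReLU + 4×4 mean-pool, conv 3×3
(8→16) + ReLU + global mean-pool, dense 16→1 — with im2col/BLAS forward and
backward passes. At 64-px tiles it trains to convergence on the synthetic
cohorts in seconds to minutes on one CPU, which is the scale this package
targets; the aggregation stages are agnostic to how the likelihoods were
produced, so likelihood tables from any external patch model (e.g. a
GPU-trained residual network at 224 px) can be fed directly into
`epla_train()`. Class imbalance is handled by per-epoch sampling of up to a
configured number of patches per slide and inverse-class-frequency loss
weights, so large slides and the majority class do not dominate.

## Transfer across cohorts

Cohorts differ in population and in slide preparation (frozen vs FFPE), and
a model trained on one cohort degrades on another. `fine_tune()` draws a
stratified fraction of the new cohort, reuses the source weights in the
patch discriminator (all layers, 0.1× learning rate) when images are
available, and refits the WSI-level aggregators — vocabulary, PALHI, BoW,
ensemble weight, cutoff — from scratch on the tuning subset's bags.
Refits reuse the xgboost grid point selected on the source cohort: the
tuning subsets are small, and re-running the hyperparameter search on a
handful of slides would mostly fit noise. Evaluation always uses the
complement of the tuning subset, so numbers at different fractions refer to
different (overlapping) evaluation sets but share the seed policy.

## Signature importance and omics association

The contribution of signature $k$ to the slide-level prediction is measured
by permutation importance: the mean decrease in ensemble AUC over repeated
random shuffles of column $k$ of the signature matrix, negatives clipped to
zero. This treats the fitted ensemble as a black box and puts histogram
bins and TF–IDF words on one scale, which per-classifier native importances
(tree gain, NB effect sizes) would not; native gain is exposed behind a
flag for comparison. Group differences are tested per signature with
two-sided Wilcoxon rank-sum tests (exact for small tie-free samples, normal
approximation with tie and continuity correction otherwise) under
Benjamini–Hochberg adjustment.

The omics quantities follow their standard clinical definitions: TMB =
nonsynonymous variant count / exome megabases (default 38 Mb, a
configuration parameter); INDEL load = count of insertion and deletion
rows; a pathway (e.g. MMR: MLH1, MSH2, MSH6, PMS2) is *deficient* as soon
as one member gene carries any nonsynonymous variant; CYT =
$\sqrt{(\mathrm{GZMA}+1)(\mathrm{PRF1}+1)} - 1$ (the pseudocount tolerates
zero expression); the CD8 T-effector score is the mean $\log_2(x+1)$ over
the eight-gene set. "Nonsynonymous" means every controlled variant class
except `synonymous`, so insertions and deletions count.

## What the synthetic cohorts emulate

The likelihood-space generator embodies the key-patch premise directly: MSS
bags draw every likelihood from Beta(2,8) (mean 0.2); MSI bags mix in a
fraction π = 0.3 of key patches from Beta(8,2) (mean 0.8). Defaults —
prevalence 0.17, 20–400 patches per slide — echo a realistic colorectal
cohort's class balance and per-slide tile counts. Domain shift of strength
$s$ moves both Beta means toward 0.5 by $0.15s$ with concentration
preserved, imitating the likelihood-space effect of a preparation change;
in image mode the same $s$ adds a colour cast. The image generator renders
the premise in pixels: noisy eosin-toned tiles whose key tiles carry dense
dark blobs (Poisson(25) vs Poisson(5)), a rectangular ROI, and
ImageScope-dialect XML. The omics generator plants lognormal TMB (log-mean
3.5 vs 1.5), binomial INDEL fractions (0.25 vs 0.08), MMR hits (0.8 vs
0.05) and a +2 log2-fold immune-gene shift.

For the planted-signal interpretability experiment the key Beta is
Beta(200, 1) with π = 0.15 and small bags (10–30 patches), so that
essentially all key mass lands in the top histogram bin and *only*
top-bin/top-word mass separates the classes; with the default Beta(8,2) the
signal spreads over many correlated bins and single-column permutation
cannot isolate it (AUC saturates at 1 under redundancy).

Passing tests on these cohorts demonstrate that the pipeline's mechanics —
binning, quantisation, leak-free ensembling, thresholding, transfer,
importance — behave as specified under a controlled generative model. They
do **not** demonstrate histological realism: synthetic tiles contain no
nuclei, stain variation, or scanner noise, the likelihood mixture is far
cleaner than a real discriminator's output, and real-cohort AUCs will be
lower than the near-perfect values reached here.

## Numerical choices and degenerate inputs

* Label boundaries are inclusive exactly as the clinical rules state
  (score ≥ 10; ≥ 2 loci); the overlap filter is strict (> 0.8); an ensemble
  score equal to the cutoff is an MSI call; majority voting needs a strict
  majority (vote fraction 0.5 ⇒ MSS).
* Patch geometry is 0-based with half-open pixel intervals, y down.
  ROI–patch overlap is computed exactly: signed fan triangulation of each
  (possibly concave) ring with Sutherland–Hodgman clipping of the convex
  triangles, so no rasterisation error enters the filter. Annotation rings
  are treated as disjoint regions, the usual convention for pathologist
  outlines; overlapping rings would be double-counted (the fraction is
  clamped at 1).
* Youden-cutoff candidates are the midpoints between adjacent distinct
  scores plus ±∞; ties take the smallest cutoff. All-tied scores therefore
  return −∞ with J = 0.
* Zero DeLong variance (perfect separation) yields the degenerate point
  interval with a warning; a percentile bootstrap is available as a
  cross-check. The paired Wald statistic is 0 (p = 1) when both score
  vectors are identical.
* Empty bags, single-class cohorts, unlabelled slides, out-of-range loci,
  and constant inputs to normalisation/correlation raise typed errors or
  warnings rather than propagating silently.
* Word quantisation evaluates $\lceil 100p \rceil$ in floating point; a
  likelihood lying exactly on a bin boundary can land on either side of it
  (e.g. 0.07 × 100 is slightly above 7 in IEEE arithmetic). Boundary
  values of the continuous likelihoods occur with probability zero, so
  this only affects hand-constructed inputs.

## Open design points, as resolved here

The feature layout (100 bins then 100 words), the word map, the smoothed
IDF dialect, the Gaussian NB variant (TF–IDF entries are continuous), and
the grid-scan convex combiner are all choices this package fixes and
documents, since 200 total signatures with a highest index of 200 admits
exactly this interpretation but the aggregation details are otherwise
underdetermined. The tiling grid is non-overlapping and anchored at the
origin — the simplest reproducible grid consistent with per-slide patch
counts in the hundreds. Centre crops are used in both training and
inference; the augmentation affine ranges (rotation ±10°, shear ±5°, scale
0.9–1.1, centre fixed) are deliberately mild. The majority-vote baseline
uses the vote fraction as its continuous ROC score, since an AUC requires
one.

## Problem sizes

The shipped experiments are sized for a single CPU: end-to-end evaluation
uses 300 training and 150 test slides; transfer uses a 160-slide source
cohort and 300-slide shifted cohorts averaged over five seeds; calibration
uses 2000 simulation replicates at 100+100 scores; CNN experiments use
64-px tiles on cohorts of a few dozen slides. All of these are
configuration values, not limits — the same code runs at larger sizes
unchanged.

## Known limitations

Slide-level accuracy here is an upper bound produced by a clean generative
model, not a clinical estimate. The CNN backbone is intentionally small;
reproducing published WSI-scale results requires a deeper backbone, 224-px
inputs and far more data than the package's test harness uses. WGCNA
network construction, GO enrichment, and stain normalisation are out of
scope — module eigengene matrices, if available, can be correlated against
signatures with `spearman_corr()` like any other sample-level covariate.
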