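---
title: "Quantifying immune cell milieus in breast tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune cell milieus in breast tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Immune cell densities in pathologically normal breast tissue change with age:
T and B cell densities in epithelium-enriched regions decline, while
CD163+ (M2-polarized) macrophages dominate the intralobular stroma. mammilieu
re-implements the quantitative pipeline behind such measurements as a tested,
reusable package: multiplex brightfield IHC images are unmixed into chromogen
channels, tissue is segmented into compartments, stained cells are detected,
filtered and classified, and densities are expressed as cells per mm² of each
compartment. Because the original measurements come from human donors, the
package's accuracy claims rest on *parameter recovery*: a synthetic scene
generator plants cells at known densities, and the pipeline must read those
densities back.

## Synthetic scenes

`generate_scene()` renders an RGB brightfield image by Beer-Lambert
composition: each stain contributes `concentration × unit OD vector` to the
per-pixel optical density, and the image is `I = 256 · 10^(−OD) − 1`,
quantized to 8 bits. The geometry has three nested compartments:

* **FSR** (fat/stroma): light background with faint texture.
* **EER** (epithelium-enriched regions): smooth blobs thresholded from a
  low-frequency random field at the exact quantile giving the requested area
  fraction.
* **PE / ILS** within EER: the peri-epithelial band is a quantile band of a
  finer "duct" field, giving ring/band morphology around duct cores;
  the remainder of EER is intralobular stroma.

Quantile thresholding makes realized area fractions exact up to pixel
rounding, which keeps density denominators honest. Cells are rendered as a
hematoxylin nucleus disk (8 ± 1.5 µm) under a chromogen halo (18 ± 1.5 µm,
truncated at ≥ 16 µm so genuine cells survive the 15 µm detection floor).
Placement is Poisson in expectation — counts are drawn per class ×
compartment as Poisson(density × area), positions uniform over the
compartment — with hard-core repulsion. The hard-core separation is the halo
mean plus four standard deviations (24 µm): with the separation at one mean
halo diameter, halos in the upper diameter tail fuse into single binary
objects below the watershed-split scale and detection loses ~10% of cells;
the wider separation restores the intended property that planted cells are
individually resolvable. This is a documented simplification — real
lymphocytes do touch.

Two optional populations exercise specific filters: nucleus-free CD68
"speckles" (sliced macrophage fragments that must be excluded by nucleus
association) and sub-15 µm chromogen debris (removed by the size filter).

What the generator does *not* emulate: tissue folds, out-of-focus regions,
fat vacuole texture, stain intensity gradients across a slide, touching
cells, or chromogen co-localization other than the double-positive
teal+yellow mixture. Passing recovery tests therefore demonstrates that the
algorithmic chain is unbiased under its stated assumptions, not that it is
robust to every real-world artifact.

## Stain separation

Stains mix linearly in optical density, so concentrations are the inverse
stain matrix applied per pixel. The OD transform is
`OD = −log10((I + 1)/256)`. Stain vectors are fixed configuration shared by
the renderer and the deconvolver (`default_stain_vectors()`, overridable
from YAML); the purple/teal/yellow chromogens of the triple panel and the
hematoxylin counterstain were chosen well-conditioned (condition numbers
≤ 3.8 per pass).

The triple panel has four stains but OD space is three-dimensional, so exact
four-stain unmixing is impossible. Each chromogen is instead unmixed in its
own pass `[hematoxylin, chromogen, residual ⊥ both]`. Within such a pass the
counterstain contributes *exactly zero* to the chromogen channel (it is in
the basis), and the chromogen contributes exactly zero to the hematoxylin
channel — the property the CD68 nucleus-association rule relies on.
Cross-chromogen leakage exists (e.g. yellow leaks ≈ 0.28 per unit into the
purple channel) but stays below the binarization threshold at the rendered
amplitudes; negative leakages clip harmlessly. The double panel
(CD68/CD163 + hematoxylin) fits one three-stain pass.

The "positive below intensity 50" rule is applied on a 0–255 intensity map
of the deconvolved channel, `I = 255 · 10^(−c/scale)` with 0 = strongest
stain — the standard convention in which positive objects are dark. The
threshold is evaluated on the per-object *mean* intensity; the alternative
per-pixel reading would conflate the binarization and positivity steps.

## Tissue segmentation

Both stages use a small encoder-decoder convolutional network with skip
connections and ReLU activations, written in plain R (im2col convolutions,
2×2 max pooling, nearest-neighbor upsampling, Adam): depth 2, 8 base
channels, 64-px tiles at desk scale, all configurable. Training minimizes
pixel-wise cross-entropy with flip/rotation/intensity augmentation, holds
out a validation tile fraction, and stops early once validation pixel error
drops below the 10% target (the epoch budget — default 60 — is a ceiling;
non-convergence returns the model with a warning, never silently).
"Validation error" is defined as the fraction of misclassified labeled
validation pixels. Inference tiles the image with 50% overlap and averages
softmax scores.

The two-stage design mirrors the measurement protocol: stage A separates
EER from FSR on the whole image; stage B runs *only inside* the stage-A
mask, classifying PE vs ILS, with non-EER pixels excluded from its loss and
output. `oracle_segmenter()` returns the generator's true mask, decoupling
detection accuracy from model quality in tests; on synthetic scenes the
trained models reach Dice ≥ 0.99, so oracle and trained paths give nearly
identical densities.

## Cell detection and classification

Per marker channel: mean-filter smoothing → dark-object binarization →
connected components → watershed split → size filter → positivity filter.
Numerical choices that matter:

* **Smoothing space.** The mean filter runs on the *concentration* map, not
  the 0–255 intensity map. Intensity is convex in concentration, so
  smoothing intensities erodes dark objects: a 16 µm halo measures ≈ 14.9 µm
  and a borderline object's mean intensity drifts above 50. Smoothing
  concentrations (then mapping to intensity) preserves object scale. The
  filter is a square box mean (side 2r+1, r = 2 µm default), computed by
  integral images.
* **Blob scale.** The proprietary single-cell blob filter is re-implemented
  as: components whose equivalent diameter exceeds the 33 µm characteristic
  scale are split by watershed on the distance transform. Touching pairs
  below that scale are counted as one — the hard-core generator makes this
  rare by construction.
* **Size floor.** "Less than 15 µm" is read as equivalent-circle diameter of
  the binary object, exclusive: 15.0 µm is kept. (Whether the original
  software meant diameter, width or area is not determinable; diameter is
  flagged as the interpretation.)
* **Positivity.** Mean object intensity < 50, exclusive: exactly 50 is not
  positive.
* **Nucleus association.** CD68 objects must overlap a nucleus object
  (hematoxylin channel of the same pass, own binarization threshold of 32 ≈
  concentration 0.9, chosen above the PE epithelial background ≈ 0.65 and
  below the rendered nuclei ≈ 1.3) by any positive fraction
  (`nucleus_overlap_min`, default 1%).
* **Classification.** Objects from different markers sharing ≥ 30% of the
  smaller object's area merge into one cell. Triple panel: exactly one
  positive marker classifies T/B/Mac; multi-positive collisions are
  `unclassified` and excluded, consistent with eliminating ambiguous
  positives. Double panel: CD163⁺ is M2 regardless of CD68; CD68⁺/CD163⁻ is
  M1.

## Densities and statistics

Density is count over compartment area (mm²), never an average of per-tile
densities; `EER_total` pools PE and ILS counts and areas. The statistics
layer wraps base R: `lm` for age regressions (Pearson r, two-sided slope p),
`aov` + `TukeyHSD`, classic equal-variance t-tests (Welch behind a flag),
paired t-tests for PE vs ILS, and type-7 (linear interpolation) quartiles
with 1.5·IQR whiskers for Tukey boxplots. Significance symbols: `*` ≤ 0.05
through `****` ≤ 1e-4.

The cohort generator draws donor densities from a linear age model
(`default_age_model()`) anchored to the published compartment means
(ILS T ≈ 259, PE T ≈ 849→477 across age, ILS B ≈ 75→9, PE B ≈ 11,
PE Mac ≈ 313, ILS Mac ≈ 101 cells/mm², M2 skewed high in ILS), with normal
between-donor scatter, truncation at zero (counted, not an error), and
steeper high-risk slopes for T and B. Default group sizes are 67 average-
risk and 36 high-risk donors aged 24–74 (the published per-group counts;
their sum, 103, is used as the total since the group sizes must add up).

## Flow cytometry and signatures

Flow gating uses rectangular per-channel gates with a multiplicative
ambiguity band (default threshold 700, band ×/÷1.6 on the log scale) as a
stand-in for manual 2-D gating, which is described only by its outcome.
7-AAD⁺ events are excluded first; samples with < 10,000 viable events error
out (the inclusion rule); CD45⁺ is gated before subsets; events inside any
subset band are dropped, so T + B + monocyte percentages sum below 100.
Compensation is not modeled — the generator emits compensated intensities.

Signature scoring: probes collapse to the single probe with maximum mean
expression across samples (ties by probe identifier); genes are z-scored
("mean center scaled" is read as center + unit variance, with plain
centering available); a signature score is the mean of member-gene scaled
values — the simplest formula consistent with the described preprocessing,
documented as an interpretation. Young (≤ 35) vs older (≥ 50) groups are
compared by two-sided Wilcoxon rank-sum tests with Holm-Bonferroni
correction across signatures; intermediate ages are excluded. Reproducing
the published adjusted p-values would require the real expression accession
and exact published gene lists, so validation uses synthetic universes:
planted shifts must be detected with the right direction, and the global
null must control family-wise error.

## Problem sizes and reproducibility

Desk-scale defaults keep full runs on one CPU in minutes: recovery
experiments accumulate 10–24 mm² of EER from 3072² scenes (≈ 2 mm² each) at
the scanner resolution of 0.465 µm/px; the segmenter trains on ≈ 40 tiles of
64² for ≤ 60 epochs; cohort-level checks use the full 103-donor structure,
which is cheap because it needs no images. Total EER area per synthetic
donor defaults to 10 mm² (a free choice; per-donor EER area is not published).
All generators take a single integer seed and are bit-reproducible;
`run_pipeline()` writes a manifest with the seed, a configuration checksum
and per-stage output checksums, and its detection stage never sees donor
metadata (permuting ages leaves detection outputs byte-identical).

## Known limitations

* Hard-core placement and non-touching halos idealize real tissue; the
  detector's merge behavior under genuinely confluent infiltrates is
  untested.
* Stain vectors are configuration, not estimated from images; slides with
  different chromogen batches would need re-calibration.
* The watershed split activates only above the 33 µm scale; two touching
  cells summing below it are counted once.
* Per-class accuracy at densities far above ~1,000 cells/mm² in one
  compartment degrades as placement approaches the hard-core packing limit.
* The flow model has two log-normal populations per channel and no spillover.
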