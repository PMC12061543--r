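---
title: "Quantifying periarterial and perivenous capillary-free zones in en-face OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periarterial and perivenous capillary-free zones in en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfzquant)
```

## The measurement problem

Capillary-free zones (CFZs) are the physiologically avascular bands that
flank large retinal arteries and veins. In en-face optical coherence
tomography angiography (OCTA) they appear as dark ribbons hugging the
bright large-vessel signal. In diabetic retinopathy (DR) and other
microvascular disease these zones enlarge and coalesce as the capillaries
nearest the large vessels drop out, which makes their geometry a candidate
early biomarker: changes appear before clinically visible retinopathy.

`cfzquant` implements the full measurement chain for 6 mm x 6 mm en-face
OCTA scans:

1. a semi-automated **candidate pipeline** that proposes periarterial and
   perivenous CFZ regions from a grayscale image plus artery/vein masks;
2. a five-class **label map** representation (background, artery, vein,
   periarterial CFZ, perivenous CFZ) with PNG round-trip I/O;
3. nine **biomarkers** computed from a label map, with whole-image,
   nasal-half and temporal-half variants;
4. a **segmentation training harness** (multiclass Jaccard loss,
   subject-grouped five-fold cross-validation, IoU/Dice/accuracy metrics)
   with a small built-in encoder–decoder network;
5. **group statistics** comparing control, NoDR (diabetic without
   retinopathy) and mild-NPDR cohorts;
6. a **synthetic generator** producing OCTA-like images with exactly known
   ground truth, so that every stage is testable without clinical data
   (clinical OCTA datasets of this kind are not redistributable).

## The nine biomarkers

With $A_k$ the pixel area of class $k$ in the label map, the three ratio
features are

$$R_a = \frac{A_{paCFZ}}{A_{artery}}, \qquad
  R_v = \frac{A_{pvCFZ}}{A_{vein}}, \qquad
  R_t = \frac{A_{paCFZ}+A_{pvCFZ}}{A_{artery}+A_{vein}}.$$

Ratios use raw class areas. A zero denominator yields a missing value
(`NA`), which is distinct from a true zero ratio and is excluded from
group statistics rather than imputed as 0.

Connected-component analysis of the CFZ classes yields counts
$N_a, N_v, N_t$ and mean component sizes $M_a, M_v, M_t$ (mean pixel area
of the retained components). Two conventions matter:

* **Two-pixel exclusion.** Components of two pixels or fewer are removed
  before counting: at en-face OCTA resolution such specks are
  indistinguishable from segmentation noise. The exclusion applies to the
  component analysis only, not to the ratio numerators, because the two
  analyses answer different questions (total avascular burden vs. spatial
  fragmentation).
* **Union components for the totals.** $N_t$ and $M_t$ are computed on the
  union mask (periarterial together with perivenous), so a periarterial
  and a perivenous component that touch merge into one total-CFZ
  component. Consequently $N_t \le N_a + N_v$, with equality only when no
  cross-class contact exists.

Components use 8-connectivity by default (thin diagonal slivers along
vessel walls are common); 4-connectivity is available everywhere.

### Regional splits

Nasal and temporal halves are obtained by splitting the image columns at
`floor(width/2)` (left half gets the floor for odd widths) and re-running
the whole analysis inside each half: components are re-derived inside the
crop and the two-pixel rule applies post-crop. A component straddling the
split is therefore counted in both halves; class *areas* still sum exactly
to the whole-image areas. Which half is nasal depends on eye laterality;
`nasal_side_for_OD` defaults to `"right"` (standard fundus display
orientation) and is a logged, configurable convention because exports
differ between devices.

## The candidate pipeline

`run_cfz_pipeline()` composes four deterministic steps:

1. **Gaussian denoising** (`gaussian_sigma`, default 1 px), separable
   convolution with reflective borders;
2. **adaptive thresholding**: a pixel is avascular iff its intensity is
   below the local `threshold_window` x `threshold_window` mean (default
   31 px) minus `threshold_offset` (default 0.10 on the [0, 1] intensity
   scale). Before thresholding, vessel pixels are replaced by the median
   extravascular intensity: mean-based local thresholds are otherwise
   biased upward in a halo around every bright vessel, flagging normally
   perfused tissue. The default offset sits in the middle of a broad
   plateau (roughly 0.06–0.14) over which candidate recovery on synthetic
   cohorts is stable; it is about a quarter of the contrast between the
   avascular signal floor and the capillary texture.
3. **connected components** of the avascular mask (8-connectivity,
   `min_candidate_area` 1 px — the downstream two-pixel rule already
   guards the counts);
4. **adjacency assignment**: each candidate component is compared with the
   artery and vein masks dilated by a Euclidean disk of
   `adjacency_radius` (default 3 px) and assigned to the class with the
   larger pixel overlap. Components touching neither are rejected; equal
   nonzero overlaps go to the periarterial class, deterministically, with
   a logged warning. Components are never split: a single avascular
   region lying between an artery and a vein is assigned wholly to the
   majority side. This is the main known error mode of the pipeline (see
   Limitations).

All parameter values are exposed in `pipeline_params()` and recorded in
the per-component assignment log, because none of them is standardised;
they are implementation choices that a downstream study must report.

## The segmentation harness

The five-class segmentation task is trained with the multiclass Jaccard
(IoU) loss

$$L = 1 - \frac{\sum_{c=1}^{C}\sum_{i=1}^{N} g_{ic}\, s_{ic}}
               {\sum_{c=1}^{C}\sum_{i=1}^{N} \left(g_{ic} + s_{ic} - g_{ic}\, s_{ic}\right)},$$

with $s_{ic}$ the softmax probability of class $c$ at pixel $i$, $g_{ic}$
the one-hot truth, and a smoothing epsilon of $10^{-7}$ in numerator and
denominator. The default (`loss_reduction = "pooled"`) evaluates this as a
single global ratio pooled over classes and pixels, exactly as written; a
`"per_class"` variant averages the per-class Jaccard terms instead.

The pooled form is faithful but ill-conditioned for training *from random
initialisation*: the global ratio is dominated by the majority background
class, and once the softmax saturates toward confident background
predictions the gradient reaching minority classes (veins in particular)
vanishes — the loss gradient is multiplied by $s_c$, which is then
numerically zero. Two harness choices mitigate this without touching the
loss definition:

* network inputs are centred (`x - 0.5`), keeping initial logits small and
  the early softmax near-uniform;
* activations are leaky (slope 0.1), so no unit can die completely.

For desk-scale smoke training the harness uses the `"per_class"`
reduction, which equalises the per-class gradient scale and trains
reliably at small model and data sizes; large pretrained encoders at
clinical scale do not need this crutch. The shipped network
(`"tinyunet"`) is a deliberately small two-level encoder–decoder
(~13k parameters: 8/16/24 encoder channels, skip concatenations, 2x
average pooling / nearest upsampling) intended for testing the harness,
not for clinical performance.

Optimisation follows the study protocol defaults: Adam
(lr $5\times10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$), learning rate multiplied by 0.8 every 150 epochs,
mini-batch 15, up to 1000 epochs, with on-the-fly augmentation (random
horizontal flip, zoom 0.9–1.1, rotation ±15°, shift ±5%, shear ±5°,
brightness ±0.1; the magnitudes are package conventions, configurable, as
only the transform list is standard). Geometric transforms are shared
between image and label map, labels resampled nearest-neighbour. The
mini-batch loss is the mean of per-image losses (each image's loss is the
formula above over its own pixels), so memory stays bounded and gradients
are accumulated image by image.

Cross-validation is grouped by subject: subjects are shuffled under a
seed and dealt round-robin into five folds, so both eyes of a subject
always share a fold and no subject appears in both train and validation.
Fold models are selected at the best validation mean-IoU epoch. All
randomness flows from explicit seeds; two runs with the same seed, data
and configuration produce bit-identical traces on one CPU thread.

## Group statistics

Each eye is one observation. For every biomarker, region and group pair
the package runs a two-sided Mann-Whitney U test (exact null distribution
for tie-free groups of at most 8; otherwise normal approximation with
continuity correction) and reports the U statistic, p value and a
significance tier at 0.05, 0.017 (Bonferroni 0.05/3 for three pairwise
comparisons) and 0.001. Summaries report median, mean and IQR with
type-7 (linear interpolation) quantiles. Covariate balance checks use
chi-squared homogeneity tests for categorical covariates and
Shapiro-Wilk (per group, skipped below n = 3) plus one-way ANOVA for
continuous ones. No correction for inter-eye correlation within subject
is attempted; that is a documented limitation of the eye-as-observation
convention.

## The synthetic generator

`generate_sample()` renders what the measurement chain actually relies
on, not retinal physiology:

* **vessel trees**: alternating artery/vein trunks enter from the border
  and branch inward as biased random walks with decreasing calibre
  (simplest mechanism giving tree-like masks with controllable width);
* **CFZ bands**: each vessel class dilated by a per-class half-width,
  minus the vasculature, with overlap resolved periarterial-first;
* **fragmentation**: a smooth random field cut at the `cfz_fragmentation`
  quantile interrupts the bands, emulating capillary encroachment; the
  removed pixels revert to background texture;
* **rendering**: capillary texture 0.55–0.77 (smoothed Bernoulli
  speckle), veins 0.85, arteries 0.97, CFZ 0.10, additive Gaussian noise
  (sd 0.03) clipped to [0, 1]. The levels keep the physical intensity
  hierarchy — large-vessel flow signal above the capillary mesh, both far
  above avascular tissue.

Disease stage maps onto band geometry: control 3/3 px half-widths with
fragmentation 0.55; NoDR 4/4 px, 0.40; mild 6/5 px, 0.22. Wider, less
interrupted bands raise $R$ and $M$ features and lower $N$ features, the
qualitative ordering reported for real cohorts. The presets are the
generator's own: no published effect sizes exist for these biomarkers, so
magnitudes are chosen to be plausible, and only the orderings should be
read as meaningful.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about clinical data: projection and motion
artifacts, signal-quality gradients, the foveal avascular zone, true A/V
intensity ambiguity (real arteries and veins are separated by morphology,
not brightness; the generator intensity-codes them as a deliberate
simplification so that a small network can learn the five-class task),
inter-eye correlation, and grader behaviour in the manual-editing step of
ground-truth preparation (the package replaces it with label-map file
round-trips).

## Numerical conventions and degenerate inputs

* Coordinates are row-major with origin top-left; the layer-indicator
  exclusion region ("bottom-left corner") defaults to 12% height x 25%
  width and must be configured per device.
* Label maps are stored as 8-bit grayscale PNGs whose pixel values are
  the class indices; round trips are bit-identical and any value above 4
  is a format error naming the value.
* Empty component sets give `NA` means and zero counts; empty ROIs are
  identity operations; `sigma = 0` denoising is the identity.
* Adaptive thresholding and denoising use half-sample symmetric
  (reflective) borders.
* Argmax prediction breaks probability ties toward the lowest class
  index.
* Component ids are assigned in raster order of each component's first
  pixel, making candidate logs reproducible.

## Problem sizes used by the test suite

The shipped tests exercise the chain at sizes chosen for a single CPU:
biomarker oracles on 200 random 64 px maps; pipeline recovery on 100
synthetic 256 px samples (pass floor: both CFZ classes at Jaccard ≥ 0.5
in at least 95% of samples); training smoke run on 40 synthetic 128 px
images (32 train / 8 validation, 30 epochs, per-class reduction, lr
3e-3, batch 5, no augmentation — floor 0.60 validation mean IoU);
trend and significance checks on truth-map cohorts of 40 eyes per group;
null calibration (stage effects disabled) over 200 replicate cohorts of
12 eyes per group at 96 px, where the fraction of comparisons below
p = 0.05 should sit near the nominal 5% (the exact and
continuity-corrected tests are slightly conservative at these group
sizes, so values modestly below 5% are expected). `scripts/acceptance.R`
re-runs the same computations from scratch under a caller-supplied seed.

## Limitations

* Whole-component adjacency assignment flips an entire avascular region
  to one class when periarterial and perivenous bands merge; on synthetic
  cohorts this is the dominant cause of per-class Jaccard dips.
* The pooled Jaccard loss, used verbatim, is not a practical objective
  for training small networks from scratch; use the per-class reduction
  (or a pretrained encoder) in that regime.
* Biomarker magnitudes from the generator are not calibrated to clinical
  populations; only orderings and machinery are validated.
* The statistics module treats eyes as independent observations.
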