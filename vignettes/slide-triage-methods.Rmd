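---
title: "Slide triage from gland segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slide triage from gland segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsitriage)
```

## The screening problem

Colorectal biopsies dominate the workload of many histopathology
laboratories, and most of them are benign. A slide-level triage system
that flags slides likely to contain dysplasia or malignancy lets
pathologists prioritize their attention while keeping the final
diagnosis human. `wsitriage` implements such a system as a *composite*
algorithm: an instance-segmentation stage delineates individual glands
on an H&E whole-slide image (WSI) and assigns each a category and a
prediction certainty; a classical machine-learning stage then
aggregates those objects into four slide-level features and classifies
the slide as high or low risk.

Gland categories follow a 7-way scheme: benign glands,
adenocarcinoma/high-grade dysplasia, low-grade dysplasia, blood
vessels, necrosis, mucin, and inflammation. The first two of
`r paste(high_risk_categories(), collapse = ", ")` constitute the
high-risk subset — any slide whose tissue truly contains such a region
is a high-risk slide.

The deep segmentation network itself is deliberately **out of scope**.
Training a Faster-RCNN requires cohorts and annotation effort that
cannot travel with a package, and its weights are not what makes the
composite design interesting. Instead the package pins down the
*contract* such a network must satisfy (`segment_slide()` returning a
`slide_segmentation`) and ships an **oracle backend** that converts
ground-truth annotations into predictions under configurable
corruption — label flips drawn from a row-stochastic confusion matrix,
dropped detections, spurious objects, and Beta-distributed prediction
certainties per (category, correctness). Every downstream stage is
therefore testable end to end, and a real trained model can be dropped
in later by implementing one S3 method.

## Tissue masking and tiling

WSIs are mostly glass. Tissue is detected per pixel in HSV space: a
pixel is tissue when its saturation exceeds an Otsu-derived threshold
*or* its brightness (value) falls below 0.92 — i.e. anything not
near-white. Otsu's criterion is degenerate when the saturation channel
is essentially unimodal (a blank or a uniformly stained frame), so the
threshold is capped at 0.2; fully saturated frames are then still
flagged as tissue. Connected components below `min_object_px`
(default 64 px) are removed as specks.

Slides are divided into non-overlapping 775 × 522 px tiles on a grid
anchored at the image origin; partial tiles at the right and bottom
edges are dropped, and tiles whose tissue fraction is exactly zero are
discarded (the "any tissue" retention rule; a stricter fraction is
configurable). Tile extents are half-open pixel intervals, 0-based,
x = column, y = row, origin top-left.

For neural-network training bookkeeping, `split_dataset()` partitions
a tile set 90/5/5 into train / model-selection / final-evaluation
subsets. The rounding rule is fixed: `n_train = floor(0.9 N)`, and the
remainder is split ceil-half / floor-half. This is the unique simple
rule under which a 73,546-tile cohort yields 66,191 / 3,678 / 3,677 —
the arithmetic the test suite pins.

A tile inherits a risk label from overlapping geometry: it is
high-risk if *any amount* of a high-risk-category polygon intersects
its extent with positive area, whether the polygons are ground truth
or model output. Intersection is computed exactly by
Sutherland–Hodgman clipping of the polygon against the tile rectangle.

## The augmentation suite

Seven augmentations are applied jointly, in a fixed order, one sampled
parameter each, to every training tile:

| Augmentation | Law |
|---|---|
| rotation | 0°, 90°, 180°, 270°, equiprobable |
| mirroring | horizontal / vertical / none, equiprobable |
| contrast | factor ~ U(0.7, 1.3) about the image mean |
| brightness | factor ~ U(0.7, 1.3) |
| H&E color | channel shifts ~ U(−0.05, 0.05) |
| Gaussian noise | additive, σ = 0.1 (normalized intensity) |
| Gaussian blur | kernel SD = 0.1 px |

Design notes, where the conventions were genuinely open:

* **Stain space.** No slide-specific stain matrix is available, so the
  RGB↔H&E transform uses the Ruifrok–Johnston optical-density vectors
  for hematoxylin and eosin, normalized, completed by an orthogonal
  residual vector, with background intensity 1.0 on the normalized
  scale. Optical density is `−log10((p + 1e-6)/I0)`; the 1e-6 guards
  `log 0`. The pair `rgb_to_he()` / `he_to_rgb()` are mutual inverses
  to within 1/255 on the non-clipped domain.
* **Channel-wise shifts.** The stain modulation reads "to each
  channel" as one scalar per image per channel, not per pixel.
  Negative concentrations after the shift are clipped at zero — so the
  operation is identity-preserving only on stain-plausible colors,
  which is the domain it is meant for.
* **Blur radius.** "Radius" is interpreted as the Gaussian standard
  deviation in pixels. At 0.1 px the kernel is a near-identity
  softening, consistent with "slightly out of focus". The convolution
  is separable with half-sample-symmetric (reflective) boundaries and
  a normalized kernel, so total intensity is conserved to ~1e-6
  relative.
* **Joint application.** Whether the augmentations were alternatives
  or a joint pipeline is not determinable from their published
  description; here they are applied jointly (rotation and mirroring
  may sample the identity), which subsumes the alternative reading.

All photometric outputs are clipped to [0, 1]; geometric operations
are exact pixel permutations.

## The four slide features

Let *H* be the segmented objects of high-risk category on a slide, *a*
their areas in mm² (pixel areas converted through microns-per-pixel:
`mm² = px · mpp_x · mpp_y · 1e-6`), *c* their certainties, and *T* the
slide's tissue area in mm². The feature vector is:

1. **`f_area_pct`** — `100 · Σ{a_i : c_i > 0.70} / T`, the high-risk
   area at certainty strictly above 70%, as a percentage of tissue;
2. **`f_wmean`** — `Σ c_i a_i / Σ a_i` over all of *H*, the
   area-weighted mean certainty;
3. **`f_flag`** — 1 iff `Σ{a_i : c_i > 0.85} ≥ 0.1 mm²`, a Boolean
   "confident and substantial" flag;
4. **`f_wpctl1`** — the area-weighted bottom 1-percentile of
   certainties over *H*.

All four are zero when *H* is empty. Three readings of the published
feature definitions were ambiguous; the defaults (all exposed in
`feature_config()`) are:

* the 70% certainty filter applies to feature 1 only — features 2 and
  4 aggregate over all high-risk objects
  (`filter_mean_percentile = TRUE` selects the other reading);
* the flag's 0.1 mm² is *cumulative* over qualifying objects, not a
  single object's area;
* the tissue denominator is the tissue-mask area, not the sum of
  object areas.

The weighted percentile is the left-continuous inverse CDF without
interpolation: sort values ascending and return the smallest value
whose cumulative normalized weight reaches *p*/100. The convention is
parameter-free and reproducible; the test suite checks it against a
replicate-expansion oracle.

## The slide classifier

A gradient-boosted decision-tree ensemble (via `xgboost`, logistic
objective, single-threaded for determinism) maps the four features to
a probability of high risk. Hyperparameters are selected by seeded,
stratified fivefold cross-validation over a small grid — trees
{50, 200}, depth {2, 3}, learning rate {0.1, 0.3}, minimum leaf
{1, 5} — by mean held-out accuracy (probability cut 0.5); ties break
toward fewer trees, then shallower depth. A four-feature input space
does not reward a larger grid. The winning configuration is refitted
on the full training cohort.

Prediction thresholds the probability at a configurable operating
point, default **0.7**, with `≥` semantics (a slide exactly at the
threshold is called high risk). A high default threshold is the
screening choice: it trades specificity for sensitivity so that
false negatives are rare. The predicted-high-risk set is monotone
(non-increasing) in the threshold, which the tests verify. Fold
stratification by class is used because small cohorts with imbalance
would otherwise produce degenerate folds; the CV selection cut of 0.5
is the natural argmax rule and is independent of the deployment
threshold.

Models persist as versioned JSON (the booster in xgboost's portable
JSON representation) so predictions reproduce across platforms.

## Evaluation

High risk is the positive class throughout. From exact confusion
counts the package reports sensitivity, specificity, accuracy and F1;
a rate whose denominator is empty is reported as missing (`NA`), never
as zero. The ROC curve sweeps every distinct score as a threshold and
the AUC is the trapezoid area, which equals the pairwise concordance
statistic with ties counted ½ — an identity the tests enforce to
1e-12 against an enumeration oracle on random instances, and
cross-check against pROC. AUC is always reported on the [0, 1] scale.

## The synthetic generator

`synthetic_config()` / `generate_slide()` emulate the *structure* of
an annotated WSI cohort, not its appearance: a near-white frame with
an elliptical "tissue" blob in a flat pink, gland-like non-overlapping
ellipses in fixed per-category colors (rejection-sampled placement,
at most 100 attempts each), per-category polygon annotations, a true
slide label, and oracle segmentation output. Default study conditions:

* frame 2325 × 1566 px (a 3 × 3 grid of 775 × 522 tiles) at
  mpp = 4.0, so 0.1 mm² = 6250 px; validation-style "biopsy" cohorts
  in the pipeline default to a smaller 2 × 2 frame;
* high-risk prevalence 0.5; object counts Poisson (mean 12 high-risk /
  10 low-risk slides); object areas log-normal on the mm² scale
  (meanlog log 0.05, sdlog 0.5 — glands of a few hundredths of a mm²);
* certainty laws: Beta(16, 2) (mean ≈ 0.89) for correct detections,
  Beta(2, 8) (mean 0.2) for spurious ones; spurious high-risk
  detections arrive at Poisson rate 2 per slide.

These settings produce clear but imperfect separability: low-risk
slides carry a few low-certainty false detections, occasionally above
the 70% cut, so the learned classifier faces a realistic (if easy)
decision problem. Category rendering colors are arbitrary constants —
they exist so the tissue mask and tiling stages see realistic colored
structure.

What the generator does **not** emulate: nuclei-level texture, stain
variation (that is the augmentation suite's job), scanner artifacts,
pyramid/multi-resolution formats, or the failure modes of a real
segmentation network beyond the oracle's corruption model. A green
test suite on synthetic cohorts therefore demonstrates the
correctness of the aggregation, training and evaluation machinery —
not clinical performance on real slides.

## Determinism and problem sizes

Every stochastic stage takes a seed; per-slide and per-stage seeds are
derived deterministically from one global seed so any stage can be
re-run in isolation. Two `run_all()` invocations with the same config
produce byte-identical reports; PNG and JSON writers are pinned to
deterministic settings.

The test suite exercises the full pipeline at deliberate desk scale:
cohorts of tens of slides for integration tests, 300 training / 150
validation slides (the default generator laws) for the
parameter-recovery check, 200 slides for the prevalence calibration,
~1.2 million pixels for the noise-moment bounds, 500 random cases for
the weighted-percentile oracle and 1,000 for the AUC/concordance
identity. The end-to-end default (`pipeline_config()`: 105 training,
150 validation slides) mirrors the resection-trained,
biopsy-validated cohort shape without claiming its data; by default
`run_all()` works at the object level (polygons + mpp) and renders no
pixel rasters — `render_images = TRUE` switches on rendering plus the
mask/tile stages.

## Known limitations

* The oracle backend corrupts labels and certainties but keeps
  ground-truth geometry; boundary-quality failure modes of real
  segmentation models are not represented.
* The tissue heuristic is tuned for H&E-like color statistics; other
  stains would need a different rule.
* Probabilities from the boosted ensemble are not calibrated; the
  operating threshold is a rank cut, not a calibrated risk.
* Weighted-percentile and flag conventions follow the defaults above;
  alternative readings are one `feature_config()` change but change
  feature values.
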