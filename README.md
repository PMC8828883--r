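# wsitriage

Slide-level triage of colorectal whole-slide images (WSIs) from gland
instance-segmentation output.

## What problem this solves

Most colorectal biopsies are benign, yet each one consumes pathologist
time. A screening algorithm that sorts slides into **high risk**
(dysplasia or malignancy) and **low risk** (benign / inflammatory)
lets a laboratory prioritize review without removing the pathologist
from the diagnosis. `wsitriage` implements the classical half of a
composite screening design for people building or validating such
systems: everything *around* the deep gland-segmentation network —
which is abstracted behind a pluggable backend contract — is
implemented, seeded, and testable at desk scale:

* **Tissue masking and tiling** — HSV-based background removal, a
  775 × 522 px tile grid with empty-tile discard, and the exact
  90/5/5 train/selection/final split arithmetic
  (`floor` / `ceil`-half / `floor`-half: 73,546 tiles →
  66,191 / 3,678 / 3,677).
* **An H&E augmentation suite** — right-angle rotation, mirroring,
  contrast and brightness (factors U(0.7, 1.3)), stain-space color
  modulation via the RGB ↔ H&E optical-density round trip (shifts
  U(−0.05, 0.05)), Gaussian noise (σ = 0.1) and Gaussian blur
  (radius 0.1 px).
* **A segmentation-backend contract plus corrupting oracle** — the
  oracle turns ground-truth polygon annotations into "predictions"
  with configurable label flips, drops, spurious objects and
  Beta-distributed certainties, standing in for a trained network.
* **Slide features** — the four aggregation features computed per
  slide from segmented objects of high-risk category (area fraction
  above 70% certainty; area-weighted mean certainty; a cumulative
  ≥ 0.1 mm² above-85%-certainty flag; the area-weighted bottom
  1-percentile of certainty).
* **A gradient-boosted slide classifier** — stratified fivefold
  cross-validated hyperparameter selection, final fit on all slides,
  and thresholded prediction (default operating point 0.7, `≥`
  semantics, chosen to favour sensitivity).
* **Evaluation** — exact confusion counts (high risk = positive),
  sensitivity / specificity / accuracy / F1, and a threshold-sweep
  ROC whose trapezoid AUC equals the concordance statistic.
* **A synthetic cohort generator** — seeded slides with a tissue blob
  and gland-like colored ellipses, per-category GeoJSON annotations,
  and oracle segmentation output with controllable separability, so
  the whole pipeline runs without any external data.

In notation: with high-risk objects *H* on a slide (areas *aᵢ* mm²,
certainties *cᵢ*, tissue area *T*),

```
f_area_pct = 100 · Σ{aᵢ : cᵢ > 0.70} / T         f_flag  = 1[Σ{aᵢ : cᵢ > 0.85} ≥ 0.1]
f_wmean    = Σ cᵢaᵢ / Σ aᵢ                        f_wpctl1 = wpctl₁(c, a)
```

and the classifier maps `(f_area_pct, f_wmean, f_flag, f_wpctl1)` to
`P(high risk)`, thresholded at 0.7.

## Worked example

```r
library(wsitriage)
library(purrr)

# a seeded synthetic cohort: annotations + oracle segmentation output
cfg    <- synthetic_config(n_slides = 60, seed = 42)
cohort <- generate_dataset(cfg)

feats <- features_table(map(cohort$slides, "seg")) |>
  dplyr::left_join(dplyr::select(cohort$manifest, slide_id, label = true_label),
                   by = "slide_id")
head(feats, 3)
#> # A tibble: 3 × 6
#>   slide_id   f_area_pct f_wmean f_flag f_wpctl1 label
#>   <chr>           <dbl>   <dbl>  <int>    <dbl> <chr>
#> 1 slide_0001      0       0.270      0    0.177 low_risk
#> 2 slide_0002      0.317   0.707      0    0.217 high_risk
#> 3 slide_0003      0       0.256      0    0.256 low_risk

clf <- train_slide_classifier(feats, classifier_config(seed = 1))
#> <slide_classifier> 50 trees, depth 2, lr 0.10, min leaf 1;
#>   trained on 60 slides (accuracy 1.000)

# score a fresh validation cohort at the 0.7 operating point
val   <- generate_dataset(synthetic_config(n_slides = 40, seed = 99))
vfeat <- features_table(map(val$slides, "seg")) |>
  dplyr::left_join(dplyr::select(val$manifest, slide_id, truth = true_label),
                   by = "slide_id")
preds  <- predict_risk(clf, vfeat, threshold = 0.7)
report <- evaluate_predictions(
  dplyr::left_join(preds, dplyr::select(vfeat, slide_id, truth), by = "slide_id")
)
report
#> <triage_eval> n=40  TP=13 TN=24 FP=0 FN=3
#>   sensitivity 0.812  specificity 1.000  accuracy 0.925  F1 0.897  AUC 0.906
```

Reading the output: on 40 held-out synthetic slides the 0.7 threshold
calls 13 of 16 truly high-risk slides high risk (sensitivity 0.81)
with no false positives; `autoplot(report)` draws the ROC curve behind
the 0.906 AUC, and lowering `threshold` trades specificity for
sensitivity (the high-risk set is monotone in the threshold).
`tidy(clf)` and `glance(report)` give broom-style summaries. The
one-shot equivalent, from simulation through `report.json`, is

```r
run_all(pipeline_config(seed = 1), out_dir = "runs/demo")
```

A thin CLI wrapper over the same functions lives at
`inst/cli/wsitriage.R` (subcommands `simulate`, `mask`, `tile`,
`augment`, `features`, `train`, `predict`, `evaluate`, `run-all`).

## Scope

The Faster-RCNN gland-segmentation network itself (architecture,
training schedule, weights) is out of scope by design; the
`segment_slide()` contract is the seam where a trained model plugs
in. See `vignettes/slide-triage-methods.Rmd` for the model,
parameter conventions, generator design and known limitations.
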