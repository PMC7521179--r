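---
title: "Scoring and selecting reporter-positive organoids in well plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and selecting reporter-positive organoids in well plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidscreen)
```

## The measurement problem

Three-dimensional differentiation of pluripotent stem cells into organoids
is stochastic: within one plate, some aggregates develop the tissue of
interest and others do not. When the target tissue is marked by a
fluorescent reporter, a single fluorescence image per well carries the
relevant information — how much reporter-positive area the organoid shows.
`organoidscreen` turns those images into per-well scores, scores into
positive/negative calls, and calls into plate- and batch-level statistics.

## The scoring model

The score of a well image is a count of "positive" pixels after three
steps, all in floating point:

1. **Background estimation.** The background is the mean intensity over a
   centered, axis-aligned rectangle whose height and width are a fraction
   `rect_fraction` (default 0.8) of the image's. The rectangle dimension is
   `max(1, round(rect_fraction * dim))` with round-half-away-from-zero, and
   when the leftover margin is odd the extra row/column sits at the
   bottom/right — conventions fixed so that the rectangle, and hence every
   score, is bit-reproducible. Because the rectangle covers most of the
   frame, the estimate is dominated by dark background plus the dim organoid
   body, and adapts to per-well illumination differences: adding a constant
   to every pixel leaves the score unchanged (the background absorbs it).
2. **Subtraction and contrast.** Residuals `pixel - background` are clipped
   below at 0, then linearly mapped with gain `alpha` (> 0, default 1) and
   offset `beta` (default 0), then clipped to [0, 255]. The clipping
   conventions are the natural 8-bit saturation semantics; they matter only
   when `alpha`/`beta` push values outside the display range.
3. **Thresholding.** A pixel is positive when its value reaches
   `pixel_threshold` (default 50 on the 8-bit scale). The score is the
   count of positive pixels; `score_to_area_fraction()` converts it to a
   fraction of a caller-supplied organoid projected area (the pipeline
   itself does not segment the organoid — deliberately: the score is a
   whole-image pixel count, not an object-level measure).

16-bit images are divided by 257 before the pipeline so that one threshold
value means the same brightness at either bit depth. The defaults are
neutral rather than estimated: the gain, offset and pixel threshold that a
given microscope/reporter combination needs depend on its intensity
statistics, and all three are exposed in the configuration and CLI flags.

```{r score-demo}
img <- matrix(0, 100, 100)
img[40:49, 40:49] <- 200          # a 10x10 bright patch
compute_score(well_image(img), scoring_params())
```

## Threshold calibration from labeled negatives

Given scores for organoids a human has graded positive/negative,
`fit_threshold()` sets the cutoff at the inverse-ECDF quantile of the
*negative* scores: the `ceiling(q * n)`-th order statistic, `q = 0.95` by
default. Classification is strict (`score > threshold` is positive; ties
are negative). Two properties drove this pair of choices:

* **Exact contamination control.** For any negative sample of size `n`, the
  number of negatives strictly above the `ceiling(q*n)`-th order statistic
  is at most `floor((1-q)*n)`, so at most a `1-q` fraction of calibration
  negatives can ever be called positive — for every `n`, not just
  asymptotically. An interpolated quantile estimator would not give this
  guarantee.
* **One-sided design.** Only negatives define the cutoff; labeled positives
  are used to *report* sensitivity (`sensitivity_on_labeled()`), never to
  move the threshold. The selected population is then interpretable as
  "contains at most 5% of organoids that look like labeled negatives",
  whatever the positive distribution looks like.

A fitted `threshold_model` prints, summarises, plots (negative ECDF with
the quantile and cutoff, positives overlaid on request), exposes
`coef()`, serialises to JSON, and classifies via `predict()`. The model
carries a free-text `source` (reporter line, day, batch); the CLI refuses
to apply a model whose source disagrees with the data's tag unless forced,
because a cutoff calibrated for one reporter line and stage does not
transfer to another.

```{r calib-demo, fig.width = 5, fig.height = 4}
cal <- sample_scores(n_pos = 150, n_neg = 350, seed = 7,
                     source = "demo line day 10")
model <- fit_threshold(cal)
summary(model)
plot(model, labeled = cal)
```

Pooling labeled organoids across batches is left to the caller: pooling
widens the negative distribution (raising the threshold, lowering
sensitivity), per-batch calibration tracks batch effects but needs enough
negatives per batch.

## Plate and batch analytics

`build_plate_result()` assembles the 8×12 grid of calls; wells without an
image are `missing` and excluded from the denominator of the positive
fraction. `half_plate_counts()` splits the plate by columns 1–6 vs 7–12 by
default — the physical axis that corresponds to an environmental gradient
(incubator door, stack position) varies between labs, so the axis and
boundary are arguments, not constants.

Group comparisons use the two-sided Mann-Whitney test with the **plate as
the unit of analysis** (each plate contributes its positive fraction): wells
within a plate share handling and position effects, so organoid-level
pooling would overstate the effective sample size. An organoid-level mode
(`unit = "organoid"`, pooling per-well scores) exists for questions about
score distributions rather than rates. The test uses the exact null
distribution when both groups have ≤ 8 observations and the pooled sample
has no ties, otherwise the normal approximation with tie and continuity
corrections; a pooled sample with zero variance returns p = 1. Welch's
t-test is offered as a clearly labeled secondary output (`welch = TRUE`),
since small-sample rate comparisons are conventionally reported both ways.
Sample SDs use the n−1 denominator. No multiple-testing correction is
applied — the package reports single planned comparisons.

## What the synthetic generator emulates

`render_well()` composites, on a `background_level` of 10 (8-bit scale): an
optional linear illumination ramp, +30 inside a centered organoid disk
(default radius 150 px in a 512×512 frame, projected area ≈ 70,700 px), the
patch intensities (default +120) inside circular reporter patches, then
Gaussian noise, clipping to the bit range and rounding. Disk membership is
center-in-circle (`dx² + dy² ≤ r²` on the integer lattice), so ground-truth
areas are exact integer pixel counts independent of any implementation
detail. Positive wells drawn by `generate_plate()` get 1–3 patches
totalling 1–10% of the organoid area — reporter-positive regions are a
small fraction of the projected area at the selection stage — and negatives
get none. Each well's random stream derives from `(plate seed, well
index)`, so any single well is reproducible without regenerating the plate.
`sample_scores()` draws labeled score sets directly (lognormal or gamma);
the default negative lognormal(meanlog 4, sdlog 1) and positive
lognormal(7.6, 0.7) give right-skewed distributions on the scale observed
for real reporter-area scores, with the negative 95% quantile near 283.
These intensity and distribution defaults are conventions, not estimates
fit to any dataset.

What the generator does **not** emulate: organoid texture, out-of-focus
blur and PSF effects, vignetting beyond a linear ramp, debris and
autofluorescence, multi-organoid wells, or misregistered frames. Passing
the recovery tests therefore shows the pipeline is *internally correct*
(it counts what is there), not that the default `pixel_threshold` is right
for any particular microscope — that is what `fit_threshold()` on labeled
real data is for. A threshold calibrated for one reporter line, day and
instrument (typically landing at a small percent of the organoid's
projected area) depends on that instrument's gain and contrast settings
and cannot be regenerated from synthetic data; the package instead
validates the procedure that produces such thresholds.

## Numerical choices and degenerate inputs

* All pixel arithmetic is double precision; only the mask and score are
  integer. The scoring tests require *exact* equality with an
  independently written per-pixel loop, which pins the clipping order and
  comparison direction (`>=` at the pixel threshold, `>` at the score
  threshold).
* Well ids accept padded ("A01") and bare ("A1") forms, canonicalized to
  bare; two files resolving to the same well abort plate discovery with
  both paths named.
* Zero-sized images, empty score sets, calibration without negatives,
  empty comparison groups, and patch centers outside the organoid disk all
  raise classed validation errors (CLI exit code 1); unreadable files raise
  I/O errors (exit code 2).
* Scores above a supplied organoid area yield fractions > 1, reported
  as-is with a warning rather than silently clamped.

## Problem sizes used in the validation suite

The checked-in validation uses 200 random 64×64 images for the oracle
equivalence, negative calibration sets of 20–1,000, 100 noisy wells at the
default 512×512 geometry for area recovery, a 4-plate rendered batch for
rate recovery, 2,000 null replicates for the Mann-Whitney size check, and
100 simulated 10-plate batches for edge-effect power — sizes chosen to make
Monte-Carlo noise small relative to the tolerances they check while keeping
a full run in the order of a minute.

## Known limitations

* One image per well is assumed; multi-field tiling and stitching are out
  of scope, as is microscope control.
* The score conflates several bright objects with one large one; per-vesicle
  object statistics would need segmentation this package deliberately
  avoids.
* PNG input is treated as 8-bit; use TIFF for 16-bit data.
* The half-plate comparison tests a two-level spatial split only; it will
  miss gradients orthogonal to the chosen axis (choose the axis) and finer
  spatial autocorrelation structure.
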