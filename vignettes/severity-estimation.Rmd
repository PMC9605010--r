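---
title: "Follicle classification and scalp severity estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Follicle classification and scalp severity estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichoscan)
```

## The problem and the model

Pattern hair loss progresses follicle by follicle: a miniaturizing
follicle shrinks, its hair count drops toward one, and the remaining
shaft thins. At roughly 200× magnification these three quantities are
measurable in pixels, which motivates a three-band classification of
follicle state:

* **severe** — radius ≤ 10 px, one hair, thickness ≤ 3 px;
* **normal** — radius in (10, 20) px, one hair, thickness in (3, 6) px;
* **healthy** — radius ≥ 20 px, two or more hairs, thickness ≥ 6 px.

All thresholds are in pixels of a 640 × 480 image; no physical px↔mm
scale is assumed anywhere, so images from another magnification must be
resized (with annotation rescaling, `resize_with_annotations()`) before
classification.

The per-patch **local severity index** is a weighted follicle count,

$$P_k = \min\!\Big(1,\; \frac{\sum_i n_{ki}\,(\alpha_i + \beta)}
{n_{\max}\,(\alpha_\mathrm{healthy} + \beta)}\Big),$$

with $\alpha = (32, 22, 12)$ for (healthy, normal, severe), $\beta \ge 0$,
and $n_{\max} = 45$. Twelve patches on a 3 × 4 scalp grid average into
$P_{avg}$, the scalp-level estimate, rendered as an ellipse heatmap.
High $P$ means *healthy*: the index rewards both follicle density and
follicle condition.

### Assumptions

* Follicles are adequately represented by circles; overlapping or merged
  follicles are a known failure mode of every stage downstream.
* Hair is darker than both skin and the follicle opening, and strands are
  locally straight enough that a medial-axis width is meaningful.
* Patches are sampled at comparable magnification so the pixel thresholds
  mean the same thing in every image.

## Design choices in the scoring

Several parts of the scoring rule admit more than one reasonable reading;
the package fixes each one explicitly and keeps it configurable.

**Normalization of P.** A per-dataset min–max scaling would make $P$
incomparable across subjects and visits, so the package normalizes
against the fixed ceiling $S_{\max} = n_{\max}(\alpha_\mathrm{healthy} +
\beta)$ — the score of a patch holding `n_max` all-healthy follicles —
and clamps at 1. `n_max` defaults to 45, the upper end of the per-image
follicle regime; both it and $\beta$ (default 0, no published value
exists) are `severity_params()` arguments.

**The α weights.** The printed weights are (32, 22, 12); a plausible
alternative reading is the squares $(3^2, 2^2, 1^2) = (9, 4, 1)$. The
default follows the printed values; `severity_params(alpha = "squares")`
selects the alternative. Both are strictly decreasing from healthy to
severe, so every monotonicity property of $P$ holds under either.

**PLS.** In the printed per-image label score the bounding-box area
multiplies *and* divides each term, so the formula reduces algebraically
to the plain sum of class codes. `pls_score()` implements that `"literal"`
variant alongside the `"area_weighted"` reading
$\sum \hat y_{ij} A_{ij} / \sum A_{ij}$ (the default), which matches the
verbal description of an area-weighted sum. PLS and $P$ are kept as
independent operations; neither feeds the other.

**Band edges.** The three class definitions use strict inequalities and
leave the boundary values (r = 10, 20; t = 3, 6) formally unassigned. The
classifier closes each band on the severe-ward side (≤ 10 severe, ≥ 20
healthy, and likewise for thickness), so the rule is total and boundary
cases flag the *more* severe class — the clinically conservative choice.

**Conflicting features.** The three criteria are conjunctive as stated
and say nothing about follicles whose features disagree. The default
resolution is majority voting: radius and thickness vote for their band's
class; a hair count below 2 splits half a vote between severe and normal
(whose count criterion is identical) and a count ≥ 2 votes healthy. Ties
break severe-ward. A follicle with no visible hair is classified severe —
absent hair is at least as severe as one thin hair. `mode = "strict"`
instead labels only unanimous follicles and returns `"indeterminate"`
otherwise.

## Feature measurement

`extract_features()` works from any follicle circle (detected or ground
truth):

* **radius** — the circle radius itself;
* **hair count** — connected components of the dark-strand mask
  (gray < 0.30) restricted to a ±2 px annulus at the circle boundary,
  after a 3 px closing that bridges single-pixel aliasing gaps in very
  thin strands;
* **thickness** — the median, over skeleton pixels of the attached
  strands, of a sub-pixel width: the ink coverage integrated along a
  profile perpendicular to the local skeleton orientation (orientation
  from a PCA of nearby skeleton points, sampling step 0.5 px). The
  background under each profile is modeled in two regions — skin tone
  outside the follicle disk, darkened tone inside, blended linearly
  across the disk's soft edge — with a per-profile scale factor that
  absorbs low-frequency skin mottle. Skeleton pixels are sampled between
  0.45 r and 1.35 r from the center, clear of the strand merge zone at
  the follicle mouth and of stroke tips.

Whether a clinical "thickness" is the maximum, mean, or median strand
width is not specified anywhere; the median was chosen for robustness to
tips and crossings. The skeleton is a hand-implemented Zhang–Suen
thinning; the width integral deliberately avoids the distance transform,
whose 2×d−1 estimate quantizes to odd integers and cannot separate the
3 px and 6 px band edges reliably.

## The reference detector

The deep detector is *not* part of the package: training one requires
GPU-scale resources and clinical images, and every downstream computation
is detector-agnostic. External detectors plug in through a JSON
interchange (`read_detections()` / `write_detections()`): a list of
`{image_id, cx, cy, r, score, label?}`. The bundled
`detect_follicles_reference()` is a deterministic classical pipeline
(background flattening by large-kernel Gaussian subtraction → dark
thresholding split into hair ink vs follicle disk → closing + hole fill +
opening → connected components → area/circularity filter → centroid +
equivalent-area-radius circle fit) whose scores are the component
circularity. It exists so the full pipeline, and every test of it, runs
without any trained model.

The mask loss (`mask_loss()`) is the standard average per-cell binary
cross-entropy over an m × m mask pair; the printed equation has
unbalanced parentheses but the accompanying text fixes the intended
form. Predictions are clipped to `[1e-7, 1 - 1e-7]` because the loss is
undefined at exactly 0 or 1.

## What the simulator emulates — and what it does not

`simulate_scalp_image()` generates the data regime the pipeline was
designed for: 640 × 480 px rasters, 10–45 follicles per image, class
mixture proportional to the labeled-dataset totals (severe 3836 :
normal 11,262 : healthy 8914), a skin-tone background (RGB 210, 180, 160)
with ±10 % low-frequency multiplicative mottle, one darkened disk per
follicle (amplitude 0.45, 1.5 px linear soft edge), and near-black
(RGB 30, 25, 20) anti-aliased hair strokes drawn as slightly curved
quadratic arcs. Unspecified quantities were fixed once at realistic
values: hair length uniform in [1.15, 1.4] · r, so every strand crosses
its circle boundary but — under the placement policy — can never reach a
neighboring follicle; hair directions separated by ≥ 50°; stroke
curvature within ±0.12.

Placement is dart-throwing, largest follicles first, under the pairwise
policy *center distance ≥ 2.5 × max(r_i, r_j)*; overlapping follicles are
thus excluded by default, isolating feature-measurement behavior from
occlusion. With `strict_bands = TRUE` (the default) attributes are drawn
strictly inside their class band, keeping a 0.3 px interior margin from
any edge shared with the adjacent class — the natural reading of
"strictly inside" once measurements carry sub-pixel error.

The simulator does **not** attempt photorealism: no red spots, oiliness,
dead skin cells, non-black hair, slanted acquisition, or occluding
follicle pairs. Consequently, passing recovery tests demonstrates that
the measurement and classification chain is correct *given* clean,
circle-like follicles with dark hairs — not that it is robust to real
clinical artifacts. Detector and feature thresholds (`strand_threshold =
0.30`, `dark_delta = 0.10`, `bg_sigma = 25`) are calibrated to this
rendering model and are exposed as parameters precisely because real
images will need recalibration.

## Numerical choices

* Coordinates are 0-based continuous pixels, x rightward, y downward
  (the VIA convention); pixel centers sit at integer + 0.5.
* Under anisotropic resize a circle cannot stay a circle; radii scale by
  the geometric mean $\sqrt{s_x s_y}$ and the event is reported.
* Resize interpolation is bilinear; Gaussian blur uses a separable kernel
  truncated at 3σ with mirror-reflected borders.
* Split sizes use half-up rounding (`floor(x + 0.5)`), not banker's
  rounding, so a 0.75 fraction of 600 images is exactly 450.
* AP uses all-point interpolation (the precision envelope integrated over
  recall), not 11-point sampling; the headline mAP averages IoU
  thresholds 0.50–0.95 in steps of 0.05, and an AP over zero ground-truth
  instances is an error, not 0.
* Circle IoU is the closed-form lens area; a rasterized estimate is kept
  as an independent cross-check and agrees within 0.01 at radii ≥ 5 px.
* Region centers of the 12-region layout sit at u ∈ {−0.45, 0, 0.45},
  v ∈ {−0.6, −0.2, 0.2, 0.6} on the unit ellipse (only the 3 × 4 scheme
  itself is prescribed); heatmap smoothing is a normalized Gaussian RBF
  average between the 12 centers (bandwidth 0.35), with a nearest-region
  block mode available. The severity colormap runs red (P = 0) through
  yellow to green (P = 1).
* The heatmap raster is drawn without a graphics device (including its
  color bar and the Pavg label, stamped with a built-in 3 × 5 bitmap
  font), so identical inputs yield byte-identical PNGs.

## Problem sizes used by the checks

The property suites run at sizes chosen to exercise the full regime while
staying desk-scale: 1000-draw band-membership properties, an exhaustive
split-size check for every dataset size from 2 to 1000 images, 100
simulated images (≈ 2900 follicles) for label recovery and detector
precision/recall, 1000 random circle pairs for the IoU cross-check, every
detection instance up to size 6 for the AP oracle, and three simulated
12-region subjects (healthy / moderate / severe mixtures with 30–45 /
15–25 / 5–12 follicles per image) for the Pavg ordering check.

## Known limitations

* The classifier is rule-based by design; it inherits any bias in the
  pixel thresholds and does not learn from data.
* Thickness measurement assumes strands at least ~1 px wide and breaks
  down under heavy strand crossings or overlapping follicles.
* The reference detector is calibrated to the simulator's rendering model
  and is a baseline, not a clinical detector.
* P compares patches on a fixed absolute scale; scalps imaged at a
  different magnification must be resized first or every threshold
  reinterpreted.
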