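---
title: "Motility phenotyping of label-free cell tracks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motility phenotyping of label-free cell tracks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motrack)
```

`motrack` quantifies single-cell mesenchymal migration from phase-contrast
time-lapse stacks and classifies cell populations by their motility
parameters. This vignette documents the model and procedure, the tunable
parameters and their defaults, the synthetic generator used for validation,
and the design decisions taken where the method left genuine freedom.

## Segmentation

Phase-contrast images of spread cells show a bright halo at the cell rim
and low-contrast interiors, so segmentation is edge-based rather than
intensity-based.

The chain is: Sobel gradient magnitude (L2 norm of the two 3×3
first-derivative responses, borders by edge replication) → binarization at
a fixed threshold (strictly greater; the threshold is tuned once per
acquisition setup and reused) → morphological smoothing → convex-hull
outline extraction.

The morphology uses two frozen structuring elements:

* **octagon, radius 3 px** (dilation): all offsets with
  `max(|dx|,|dy|) <= 3` and `|dx|+|dy| <= 4` — origin-to-side distance 3
  along the axes; 37 pixels;
* **diamond, radius 5 px** (erosion, applied twice after hole filling):
  all offsets with `|dx|+|dy| <= 5` — origin-to-vertex distance 5;
  61 pixels.

Dilation treats pixels outside the frame as background and erosion treats
them as foreground, the convention of the mainstream image-processing
toolboxes, so cells touching the frame edge are not eroded from that side.
Hole filling treats the background as 4-connected.

Each 8-connected component at least `min_area_um2` (default 200 µm², an
order of magnitude below a spread fibroblast of ~1900–2250 µm²) is replaced
by its **filled convex hull**: thin, noisy protrusion detections are
absorbed and the outline is smoothed at the cost of bridging true
concavities — acceptable here because touching cells terminate tracking
anyway. Centroid (mean of filled-hull pixel coordinates), area (hull pixel
count × pixel size²), equivalent circle diameter, and the major axis of the
moment-equivalent ellipse are measured per region.

Conventions that tests rely on: pixel coordinates are 0-based, x rightward,
y downward, pixel centers at integers; `centroid_mode = "pixel"` (default)
rounds the centroid to the nearest pixel, half away from zero, which is
what produces the characteristic grid-angle artifact discussed below;
`"subpixel"` keeps the exact mean. The major-axis estimator (second central
moments of the hull pixel set; length `4*sqrt(lambda_max)`; orientation of
the leading eigenvector mapped to [−90°, 90°)) and the 8-connectivity of
components are package decisions — the underlying protocol does not fix
either.

## Tracking

One track is seeded per cell segmented in the first frame. To advance a
track, a square ROI of side `roi_scale` × the previous major-axis length
(default 2.0 — large enough to hold the cell after a one-frame move, small
enough to exclude well-separated neighbours) is centered on the previous
centroid, translated — never shrunk — to stay inside the frame, and the
segmentation chain is re-run inside the crop:

* exactly one qualifying region → its centroid/area/axis are appended;
* no region → stop (`no_centroid`);
* two or more regions (division, or a neighbour entering the ROI) → stop
  (`multiple_centroids`);
* one region whose area exceeds `merge_area_factor` (default 1.8) × the
  previous area → stop (`multiple_centroids`): two touching cells segment
  as a single convex object, and the area jump is the only signature of
  that merge in a convex-hull representation.

A matched region must also lie within half the ROI side of the previous
centroid (sanity guard against jumps to a different object). Frames are
processed strictly sequentially with no gap closing or re-acquisition;
points are never appended at or after a stop event. Only tracks strictly
longer than `min_track_duration_min` (default 60 min) enter the analysis —
one hour covers at least one burst cycle of the fast phenotype.

## Motility parameters

For centroids $p_i$ at uniform spacing $\Delta t$ (default 60 s),
$r_i = p_i - p_{i-1}$, speeds $|r_i|/\Delta t$, and turn angles
$\theta_i = \mathrm{atan2}(|r_i \times r_{i+1}|,\ r_i \cdot r_{i+1})$
in [0°, 180°]. When either adjacent displacement is zero the angle is
defined as 0 and flagged; flagged angles are excluded from turn counts and
distance-per-turn denominators but contribute 0 to the angle sum.

The ten per-cell parameters:

| parameter | units | notes |
|---|---|---|
| `mean_speed_um_s` | µm/s | mean step speed |
| `freq_below_90/60/30` | turns per 30 h | strict `<`; zero-steps excluded |
| `md_below_90/60/30` | µm | total path length / below-threshold turn count; `NA` when no turn qualifies |
| `sum_turn_angles` | degrees per 30 h | cumulative polarity change |
| `quiescent_time_s` | s | time with speed strictly below the cell's own mean |
| `total_length` | µm per 30 h | path length |

Turn frequencies, the angle sum, and the total length grow with observation
time, so they are normalized to a 30-h window (hourly value × 30); the
quiescent time is reported raw (with the fraction of track duration as a
convenience column) and the distances-between-turns are intrinsic ratios.
Two readings were genuinely open: the distance between turns is implemented
as path length over turn count (the natural reading that makes "fewer
shallow turns ⇒ longer distance per turn" arithmetically coherent), not as
a mean over gaps between consecutive qualifying turns; and the quiescence
threshold is the cell's own mean speed, not a population mean. Both choices
are recorded here rather than asserted as the only possible reading.

Useful invariants, all enforced by tests: the parameters are invariant
under rigid motions of the trajectory; `freq_below_30 <= freq_below_60 <=
freq_below_90`; and `total_length = mean_speed_um_s × 108000` exactly
(30 h = 108000 s).

## Discrimination

Per-cell parameter values feed Pearson correlation matrices per group,
Welch two-sample t-tests (two-sided; sidedness was unstated upstream), and
LDA/QDA. Class covariances are the sample estimators; LDA pools them as
$S = ((n_1-1)S_1 + (n_2-1)S_2)/(n_1+n_2-2)$ — the printed source for this
estimator is corrupted, and the standard pooled form is used. Covariances
must pass a Cholesky check; degenerate pairs (e.g. a saturated turn
frequency with zero variance) raise a fit error and rank last (`NA`) in the
pair search.

Classification assigns a point to the class with the smaller squared
Mahalanobis distance. The source material states "$d_1^2 - d_2^2 \ge 0$ ⇒
positive" with class 1 the positive class, which contradicts nearest-class
logic; `motrack` implements nearest-class assignment and resolves the exact
tie $d_1^2 = d_2^2$ to the positive class, preserving the "≥" at the only
point where the two rules differ.

Cross-validation is stratified (per-class shuffling into k = 10 folds) and
seeded; stratification is a package decision that guarantees both classes
appear in every training and held-out set at the ~50-cell class sizes
typical here. `pair_search()` evaluates all 45 unordered parameter pairs
per discriminant kind and ranks by accuracy (ties: sensitivity, then pair
name); it scores by cross-validation by default (resubstitution available)
— whether the reference results used resubstitution or CV is unstated, and
CV is the defensible default. Equal priors and equal misclassification
costs are implicit throughout; no ROC analysis and no ≥3-parameter models
are provided.

## Synthetic ground truth

The generator is the package's own model of the two reported phenotypes,
not part of the measurement method: headings evolve by wrapped-normal
increments with concentration κ (variance 1/κ rad²; κ = 0 degenerates to
uniform headings, κ → ∞ to a straight line), and speed follows either a
two-state Markov chain (transient bursts) or a constant-with-jitter
process. Defaults were chosen once from the reported cell behavior:

* `preset_population_spec("cancerlike")`: two-state speed, v_high = 0.05,
  v_low = 0.008 µm/s, switch probabilities 0.12 (high→low) and 0.06
  (low→high) per minute — stationary mean ≈ 0.022 µm/s with burst spacing
  well under 100 min — and κ = 8 (directional);
* `preset_population_spec("fibroblastlike")`: constant 0.015 ± 0.004 µm/s,
  κ = 2 (meandering). The two presets reproduce the ~1.5× mean-speed ratio
  of the reference cell types.

`render_scene()` draws each cell as an ellipse (default semi-axes
30 × 20 µm ≈ 1900 µm²) at a small negative interior offset, a Gaussian
bright halo along the rim (amplitude 0.35, σ = 2 px), optional faint
1-px protrusions, and additive Gaussian noise, at 0.65 µm/px. It emulates
the gross appearance phase contrast gives a spread cell — enough to
exercise edge detection, morphology, hull extraction and ROI tracking —
but not phase-contrast optics: no Zernike point-spread function, no
shade-off, no intensity flicker, no cell deformation over time (shape and
orientation are fixed per cell). Passing tests therefore demonstrate
correctness of the measurement chain on geometry-faithful images, not
robustness to every real-microscopy artifact; the edge threshold still
needs per-setup tuning on real data.

## Numerical choices and degenerate inputs

* Strict inequalities throughout ("below threshold", quiescence, the
  binarization): ties go to the non-event side.
* Centroid rounding is half-away-from-zero (base R's `round()` is
  half-to-even).
* Hull filling includes boundary pixels (tolerance 1e-9); degenerate hulls
  (collinear components) fall back to the component's own pixel set.
* A single-pixel region has no major axis (`degenerate_region` error); a
  track whose previous axis is non-positive stops as `roi_degenerate`.
* `md_between_turns` with no qualifying turn is `NA`, and rows with `NA`
  in a fitted pair are dropped with a logged count.
* All randomness flows through explicit seeds (`simulate_*`, fold
  shuffling, scene rendering); repeated calls with the same seed are
  bit-identical, and seeded helpers restore the caller's RNG state.

## Validation problem sizes

The test suite validates: the Sobel/morphology/hull chain pixel-for-pixel
against naive reference implementations on 20 random 128×128 frames; turn
angles against an arccos oracle on 10⁴ random trajectories (tolerance
1e-9); tracking on a rendered 61-frame scene with 5 non-contacting cells
(no premature stops, mean centroid error ≤ 1 px) and on a scripted
cell-cell merge (stop at the contact frame with prior points intact);
discriminant algebra against definitional oracles and an exhaustive
enumeration of confusion matrices with counts ≤ 5; calibration with 50+50
simulated cells per condition (near-chance cross-validated accuracy for
identical populations, ≥95% for strongly separated ones, and recovery of a
deliberately informative parameter pair); and the pixel-grid angle
artifact — with pixel-mode centroids and ~1 px/min motion, pooled
turn-angle histograms peak at 0°, 45°, 90°, 135° and 180°, an artifact of
displacement quantization that real centroid tables computed in integer
pixels share. These sizes keep the whole suite within a few minutes on one
CPU while leaving each check statistically comfortable.

## Known limitations

* Convex-hull smoothing cannot represent constricted or highly branched
  morphologies; strongly non-convex cells inflate the area and can shift
  the centroid.
* Touching cells are recognized as one object; tracking stops rather than
  resolving the contact, so dense cultures yield short tracks.
* No gap closing: a single dropped detection ends a track.
* The merge heuristic (area factor 1.8) can miss a contact in which the
  partner contributes little in-ROI area, and can trigger on genuinely
  fast spreading.
* The discriminant models are two-class and two-parameter by design.
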