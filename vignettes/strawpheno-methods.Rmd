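---
title: "strawpheno: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strawpheno: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Strawberry management decisions lean on a small set of morphological
traits: crown diameter (an early-vigor and yield indicator), plant height
and petiole length (growth and dormancy status), leaf area/length/width
(photosynthesis and training decisions), and flower and fruit areas
(yield proxies). `strawpheno` measures all of these from a single RGB
photograph that contains the plant part together with a square fiducial
marker of known physical side length (4.7 cm by default), held coplanar
("beside and parallel") with the part.

The pipeline is: locate the marker → solve the pixel→cm plane homography
→ detect the part(s) → (for area traits) segment the detection crop →
convert geometry to physical units. Detection and segmentation are
abstracted behind a backend interface so the same trait code runs on
synthetic ground truth, a classical color-based detector, or (in
principle) a learned model.

## Spatial calibration

Four detected corner points $x_i$ and the four physical corners of the
square determine the homography exactly (direct linear transform on the
8×9 system; the solution is the right singular vector). We deliberately
model a *projective* correction only: four coplanar points cannot
identify radial lens distortion, so lens terms are not estimated. The
residual of the four corners after the round trip is checked against
1e-6 cm and a `spt_degenerate_corners` condition is raised for collinear
or non-convex corner sets.

Two consequences the user must understand:

* **Coplanarity contract.** Distances are physical only for content on
  the marker plane. The library cannot verify this from one image; the
  capture protocol (hold the part parallel to the marker) is the user's
  responsibility.
* **`scale_cm_per_px` is reporting-only.** It is defined as the side
  length divided by the mean detected side in pixels. All measurement
  math goes through the full matrix; the scalar is recorded as
  provenance on each measurement.

## Marker detection

The synthetic fiducial is a dark achromatic square with a light square
cue in its top-left quadrant (so the corner order is unambiguous without
decoding a real QR payload). Detection proceeds by: chroma-screened dark
thresholding (colored plant parts are excluded by saturation), 4-connected
component labelling, convex-hull + farthest-point quadrilateral fitting
with solidity and aspect screens, then **sub-pixel edge refinement**: on
each edge, scanlines sample the anti-aliased intensity profile and the
edge position is estimated by the coverage-moment method (the summed ink
fraction of an outside→inside profile equals the covered length, which is
exact for box-sampled straight edges and, unlike mid-level crossing
interpolation, is unbiased for any edge blur width). A total-least-squares
line per edge and adjacent-line intersections give the corners; on
generator output the localisation error is far below the 0.5 px contract.
Zero candidates raise `spt_marker_not_found`, more than one raise
`spt_ambiguous_marker`. Externally decoded corners can bypass all of this
via `marker_detection()`.

## Trait definitions

* **CD (mm).** The crown is annotated/detected as a box enclosing its
  thickest part. The midpoints of the box's left and right edges are
  mapped through the homography and CD is their separation **along the
  rectified horizontal axis**. We use the width component rather than
  the Euclidean chord because under residual camera tilt the two
  midpoints land at slightly different rectified heights; the chord
  would inflate CD second-order in the tilt (up to ~1% at 30°), whereas
  the width component is exact for an upright crown.
* **PH, PL (cm).** Both are endpoint distances: the plane-mapped
  centers of the two endpoint boxes (crown/topmost leaf for PH,
  crown-attachment/leaflet-junction for PL). Centers were chosen over
  extreme box edges because the endpoint boxes mark *regions around the
  endpoints*, for which the center is the natural representative; the
  two conventions differ by half the endpoint-box heights, which is a
  documented assumption, not a measurable from the data we have.
* **LA, LL, LW.** The leaf mask is rectified to the metric plane; LA is
  the foreground cell count times cell area; LL/LW are the foreground
  extents along the principal (largest-variance) axis and its
  perpendicular, plus one grid cell to account for the cell footprint
  (the cell-center extent underestimates the physical extent by one
  spacing in expectation). Extents are ordered so LL ≥ LW always.
  Principal-axis extents, not maximum Feret diameters, are used: they
  are cheaper, more stable under boundary noise, and identical for the
  ellipses and rectangles used in validation.
* **Fl.A, Fr.A.** Rectified foreground count × cell area. These traits
  are per-instance: an image with three fruits yields three
  measurements. Single-valued traits (CD, PH, PL) use the
  highest-confidence detection of each required part.

Missing parts yield an *empty measurement list*, not an error — the
absence is data, counted by the detection-frequency statistic.

## Numerical choices

* **Rectification grid.** The default grid spacing is **half** the
  marker-derived scale, clamped to [0.005, 0.2] cm/px. The native scale
  was the original design intent, but nearest-neighbor resampling at the
  native spacing leaves a grid-phase area bias that we measured above 1%
  on flower-sized masks (≈3.3 cm²), defeating the pipeline's own 1%
  recovery target; halving the spacing removes it (measured bias
  −0.04%). This is a deliberate, benchmarked deviation.
* **Extent correction.** Adding one grid cell to the projected extent
  makes the rectangle case exact and is mean-unbiased for smooth convex
  shapes; the residual is bounded by one cell per axis.
* **Homography conditioning.** The DLT is solved by SVD; `H` is
  normalised to `H[3,3] = 1` when possible and singularity raises a
  degenerate-corners condition.
* **Ties and degeneracies.** k-means ties go to the lower-index center;
  a zero-variance paired difference reports t = 0, p = 1; zero
  within-group variance with distinct means reports F = ∞, p = 0; zero
  total variance is an error (`spt_degenerate_groups`).

## Statistics

`validate_trait()` computes Pearson r (two-sided p via the t transform),
R² = r², RMSE, the paired t-test, and the detection frequency
100·n/attempts — all closed-form, cross-checked in the tests against
`stats::cor.test()`/`t.test()` to 1e-10.

`kmeans_clusters()` is 1-D k-means with k-means++ initialisation run on
the *sorted* values, which makes assignments invariant to input order
while keeping the seeded k-means++ contract; converged clusters are
relabelled by descending mean so "cluster 1" is always the largest-size
cluster (the convention used when clustering crowns into large/medium/
small, with k = 3 by default). The tests compare against an exhaustive
dynamic-programming optimum.

`anova_tukey()` is one-way ANOVA plus Tukey HSD with a compact letter
display built by the insert-and-absorb algorithm (start with one letter
covering all groups, split it for every significant pair, absorb subset
columns). Groups sharing a letter are not significantly different at
α = 0.05; the tests verify this equivalence against the pairwise p-value
matrix directly. All tests are two-sided.

## The synthetic world

The generator renders what the capture protocol assumes: a planar scene
holding the 4.7 cm marker and flat colored plant proxies, imaged by a
projective camera. Default physical sizes follow typical greenhouse
measurements: crown 14.4 mm wide, plant-height endpoints 24.6 cm apart,
petiole 15.1 cm, leaf ellipse 7.0 × 5.5 cm, flower disk 3.26 cm², fruit
disk 6.52 cm². Image resolution is per-trait (40 px/cm for crown and
flower close-ups down to 16 px/cm for whole-plant height shots),
emulating natural shooting distances; viewing distance is drawn from
80–140 cm.

Pose model: "tilt ≤ 30°" is interpreted as the **total angle between the
optical axis and the plane normal**, sampled as a tilt magnitude about a
random in-plane axis (independent per-axis Euler tilts of ±30° would
allow 41° total). The camera is aimed at the target part and **rolled so
the plane's vertical axis appears upright at the aim point** — this is
what a photographer framing the target does, and it matters: without the
roll, axis-aligned box annotations of a tilted scene lean in-image and
box-width traits degrade by up to ~15% at dual 30° tilt. That failure
mode is a property of box annotations, not of the calibration, and is
the reason the capture protocol insists on correct marker/camera
positioning.

Rendering is anti-aliased with a 16-sample N-rooks subpixel pattern
(16 distinct offsets per axis, so near-axis-aligned edges do not alias
the way a regular subgrid does); ground-truth masks use the crisp
pixel-center membership rule, and ground-truth *boxes* are the exact
geometric bounding boxes of the projected shapes (analytic, via corner
mapping for rectangles and the dual conic for ellipses), so the oracle
backend isolates geometry-pipeline error from rasterisation error. The
rasterised tight box agrees with the analytic box within one pixel and
the tests assert this consistency.

**What a green test does not establish**: the generator draws flat,
uniformly colored, unoccluded shapes with ideal edges. Real detector
error, occlusion, non-planarity (curled leaves), lens distortion,
lighting and background clutter are all outside the synthetic world, so
end-to-end recovery within 1% here bounds only the geometric/statistical
machinery, not field accuracy.

## Known limitations

* Only projective (not radial) distortion is corrected.
* CD/PH/PL assume upright framing; large camera roll biases box-width
  semantics (documented above).
* Coplanarity is assumed, never verified.
* Ripe/unripe fruit classification and canopy-scale traits are out of
  scope.
* The weight model's functional form is a design choice (linear by
  default, log–log behind a flag); with only a "strong positive
  relationship" to go on, the minimal model was preferred.
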