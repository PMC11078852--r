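---
title: "Measuring polyp size and location from tracked endoscopic image pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring polyp size and location from tracked endoscopic image pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypsize)
```

## The measurement problem

Visual estimation of polyp size during endoscopy is unreliable: the apparent
size on the monitor depends on the unknown camera-to-lesion distance, and
inter-observer differences of several millimetres straddle the clinical
decision thresholds (5 and 10 mm) that drive resection and surveillance
policy. `polypsize` implements a quantitative alternative for endoscopes
carrying an electromagnetic (EM) tracking sensor: the tracker supplies the
camera pose (position in mm plus orientation) for every captured frame, which
turns a pair of ordinary monocular images into a calibrated stereo pair.

The pipeline is:

1. **Border extraction** (`refine_mask()`, `extract_border()`,
   `resample_contour()`). Segmentation masks (produced upstream by any
   segmentation model; the model itself is not part of this package) are
   cleaned with morphological opening, small-component removal and hole
   filling, optionally refined with a region-based active contour, and traced
   into a sub-pixel, uniformly resampled closed border polygon.
2. **Correspondence** (`compute_descriptor()`, `match_shapes()`). Endoscopic
   tissue is texture-poor, so classical feature matching fails; instead each
   border point is described by a *shape context* — a log-polar histogram
   (5 radial x 12 angular bins) of the positions of all other border points —
   and the two point sets are put in one-to-one correspondence by exact
   optimal assignment under the chi-squared histogram distance.
3. **Reconstruction** (`reconstruct_border()`, `fit_ellipse_3d()`). Each
   matched point pair is back-projected into two viewing rays in tracker
   coordinates and triangulated at the midpoint of their common
   perpendicular; the segment length is an interpretable residual in mm. A
   plane is fitted through the 3D border (centroid + smallest principal
   direction) and a conic constrained to ellipses is fitted in that plane by
   direct least squares. The full major axis is the clinically reported
   *longest length*; the distance from the ellipse centre to a tracked
   anatomical landmark (e.g. the oesophago-gastric junction) is the
   *location*.
4. **Multi-pair pooling** (`aggregate_pairs()`, `measure_polyp()`). All frame
   pairs that pass the motion-quality gate are measured independently. If the
   polyp is stationary its reconstructed centre must agree across pairs, so
   pairs whose centre lies beyond the Tukey fence (Q3 + 1.5 IQR on
   centre-to-median distances) are excluded, and the final size and location
   are the means over the remaining pairs.

Agreement statistics used to validate such a system on repeated sessions —
two-way mixed-effects ICC for absolute agreement, Bland–Altman limits of
agreement in units and percentages, RMSD/median-absolute-difference
summaries, and the Fisher-z sample-size calculation — are provided by
`icc_absolute()`, `bland_altman()`, `error_summaries()` and
`sample_size_correlation()`.

## Motion-quality gating

Two-view triangulation degrades predictably with camera motion, so pairs are
gated (`check_pair()`) on four rules with configurable thresholds:

| rule | default | rationale |
|---|---|---|
| `large_translation` | > 30 mm fails | large moves break the small-rotation assumptions and field-of-view overlap |
| `large_rotation` | > 30 degrees fails | large relative rotation invalidates image-frame descriptor matching |
| `minimal_movement` | < 3 mm fails | a short baseline makes depth ill-conditioned |
| `forward_backward` | translation within 15 degrees of the mean optical axis fails | near-axial motion gives almost parallel rays on the optical axis |

The inequalities are strict: a pair at exactly 30 mm, 30 degrees or 3 mm
passes. All rules are always evaluated so an operator report can name every
violated recommendation. The 15-degree forward-backward threshold is this
package's quantification of "pure forward-backward movement"; it is
configurable and recorded in the run manifest.

## Correspondence: design choices and a failure mode

Shape-context angles are measured in the image frame rather than relative to
the local tangent: valid pairs are constrained to under 30 degrees of
relative rotation, so image orientation is usable signal, and discarding it
would make every point on a near-circular border look alike. Radii are
normalized by the shape's mean pairwise distance (scale invariance); the
radial range spans 1/8 to 2 times that distance and points outside it are
dropped, following the usual shape-context construction. Matching solves the
assignment problem exactly (`clue::solve_LSAP`) rather than greedily; on
shapes small enough to enumerate, the result equals the exhaustive minimum
(verified in the tests).

Raw optimal assignment has a documented failure mode on this problem: two
uniform resamplings of the *same smooth border* produce many assignments
with nearly equal total cost (the descriptors vary slowly along the
contour), and among these are order-reversing "phantom" matchings whose
triangulations are epipolar-consistent — low residuals — yet reconstruct an
inflated, tilted border. `measure_polyp()` therefore applies
`refine_cyclic()` between matching and triangulation: the assignment is
projected onto its dominant order-preserving cyclic shift (the physical
truth for two samplings of one closed curve), each match is then allowed to
snap within ±2 samples to its cheapest descriptor bin, and a pair whose raw
assignment agrees with the dominant shift on fewer than 60% of points is
dropped as `inconsistent_matching`. Two further guards act downstream:
points whose epipolar line runs within asin(0.35) of the border tangent in
the second view are dropped before triangulation (along-curve position is
unconstrained there), and a pair whose ellipse-fit RMS error exceeds 10% of
its fitted major axis is dropped as `poor_ellipse_fit`. During development a
residual-minimizing shift search was evaluated and rejected: it
systematically selects the epipolar-consistent phantom and worsens size
accuracy — triangulation residuals cannot arbitrate correspondence on
near-circular borders.

## Numerical choices

* **Triangulation** is the midpoint of the common perpendicular, not a DLT:
  it is exact for intersecting rays, closed-form, and its residual is a
  physical distance in mm used both for outlier capping (default 2 mm per
  point) and as a diagnostic.
* **Ellipse fitting** uses the numerically stable Halir–Flusser formulation
  of the direct least-squares conic fit with the ellipse constraint, applied
  after orthogonal projection onto the principal plane. Degenerate conics
  (hyperbola, parabola, rank-deficient design, collinear points) raise
  errors rather than returning nonsense. The reported RMS fit error is the
  radial distance between each in-plane point and the ellipse.
* **Undistortion** inverts the Brown–Conrady model by fixed-point iteration
  (cap 50 iterations, tolerance 1e-12) and fails loudly if it does not
  converge.
* **Border extraction** applies a 3x3 box average to the binary mask before
  marching squares, so the 0.5-level crossing interpolates the edge at
  sub-pixel accuracy instead of tracing the pixel staircase (a digital disc
  of radius 40 px would otherwise read ~6% long in perimeter).
* **Orientation convention**: contours are stored counter-clockwise (positive
  shoelace area in stored coordinates) so angular bins are comparable across
  images; quaternions are scalar-first; all interface lengths are mm and
  angles degrees.
* **Active contour**: a morphological Chan–Vese-style two-phase refinement
  (region competition in a narrow band, opening-closing smoothing, 200
  iteration cap), chosen over edge-based snakes because endoscopic borders
  are low-contrast. It runs only when explicitly requested with an intensity
  image, since the trigger condition ("model output covers the polyp
  partially") is a judgement the caller must make.

## The synthetic scene generator

There is no public dataset pairing endoscopic frames with tracker poses, so
the package ships a ground-truthed simulator used by the tests and the
validation script:

* `make_polyp()` builds a planar ellipse border (optionally with smooth
  out-of-plane waviness as a stand-in for non-rigid, asymmetric polyps) of
  known major axis — the stored ground truth.
* `make_pose_set()` places look-at cameras near a working distance of 60 mm
  with lateral offsets arranged so every pair satisfies the motion rules,
  emulating the recommended capture protocol.
* `render_views()` projects the border through each true pose, rasterizes
  the filled polygon as the mask, adds Gaussian pixel noise to the contour,
  and perturbs the *reported* poses with Gaussian position and orientation
  noise — the tracker error model.

The validation cohort (`simulate_cohort()`) uses 30 polyps with major axes
uniform in 5–20 mm (the size range reported for validation polyps in ex vivo
work), aspect ratios uniform in 0.5–0.95, five views per polyp, pairwise
baselines of 5–25 mm, pose noise of 0.3 mm and 0.3 degrees, and pixel noise
of 0.5 px. The noise magnitudes are plausible EM-tracker and segmentation
figures; no public measurement of the in-vivo noise spectrum exists, so they
are configuration, not constants. Landmarks are placed 150–250 mm from the
polyp centre. With these settings the size RMSE is below 1 mm and the
location RMSE below 3 mm (the bounds established for the method's prior
bench evaluation); `scripts/acceptance.R` recomputes both.

What the simulator does *not* model: photorealistic appearance (masks are
exact polygon rasterizations; real segmentation errors are structured, not
i.i.d. Gaussian), tissue deformation between frames, specular highlights and
occlusion, or correlated tracker drift. Passing the simulated bounds
demonstrates the geometry, matching and pooling are correct under the stated
noise; it does not certify performance on clinical data.

## Statistical module choices

* The ICC is the single-measure, absolute-agreement form from the two-way
  model, ICC(A,1) = (MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE)),
  because each session yields one measurement per polyp; confidence bounds
  use the standard F-based (Satterthwaite) approximation and the p-value
  tests ICC = 0 via MSR/MSE.
* Bland–Altman limits default to d ± 1.96s (the explicit 95% normal
  interval); d ± 2s is available via `loa_factor = 2`. The Shapiro–Wilk
  normality p-value is attached as advisory metadata — the analysis is
  always computed, never refused.
* The sample-size rule inverts the Fisher-z test of a zero correlation,
  n = ((z₁₋α/₂ + z_power)/atanh(r))² + 3, inflates by the attrition fraction
  and rounds up once at the end; with r = 0.7, α = 0.05, power 0.8 and 10%
  inflation this gives 15. Rounding up *before* inflation would give 16;
  the single final ceiling is deliberate.

## Problem sizes and runtime

Defaults keep everything interactive on one CPU: 100 border samples per
contour for matching (so a 100x100 assignment per pair), 200 border samples
in the simulator, 640x640 px rendered masks, C(5,2) = 10 pairs per polyp.
A full 30-polyp cohort with the complete shape-context pipeline runs in
about 20 seconds; the test suite in under a minute.

## Known limitations

* The method measures the border ellipse, not the 3D surface: strongly
  non-planar or lobulated lesions violate the planarity assumption, and the
  ellipse-fit RMS error should be inspected (it is reported per pair).
* Correspondence on *perfectly* circular borders is fundamentally ambiguous
  up to rotation from silhouettes alone; the cyclic-shift refinement
  resolves it through image-frame orientation, which relies on the <30
  degree relative-rotation gate.
* Location is the straight-line Euclidean distance in tracker coordinates,
  not an along-lumen path length.
* Hand-eye calibration between sensor and camera is accepted as
  configuration and assumed correct; errors in it translate rigidly into
  both size and location estimates.
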