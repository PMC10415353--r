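---
title: "Reconstructing coronary bifurcations from IVUS and biplane angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing coronary bifurcations from IVUS and biplane angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intravascular ultrasound (IVUS) images a coronary artery from inside: a
motorized pullback at constant speed (0.5 or 1.0 mm/s, about 30 frames/s,
hence 0.017 or 0.033 mm between frames) yields a stack of cross-sections in
which the lumen, the external elastic membrane (EEM) and plaque components
(calcium, fibrosis, fibrolipid) can be segmented. IVUS alone has no 3D
context; coronary angiography supplies it. `bifuse` fuses the two for
*bifurcations*: the main vessel (MV) and side branch (SB) are each pulled
back, their centerlines are triangulated from two angiographic projections at
least 30 degrees apart, the segmented frames are strung along those
centerlines, and the two branch surfaces are merged into one watertight
model, with plaque bodies as true 3D solids rather than surface attributes.

## Pipeline and the choices inside it

**Centerline triangulation.** An isocentric C-arm camera model (RAO/LAO
rotation about the patient's long axis, cranial/caudal about the lateral
axis; source-isocenter and source-detector distances given) backprojects
each point of one 2D centerline to a ray, intersects its epipolar line with
the second curve under a monotone ordering constraint, and takes the
midpoint of the common perpendicular of the two rays. Views closer than 15
degrees are refused, below 30 degrees a warning is raised. Because the
epipolar match reprojects exactly onto both measured points by construction,
the recorded `reprojection_rms` is defined as the residual against the
second curve's sample under index correspondence — zero for consistent
inputs, growing with 2D noise.

**Frame placement.** Gated (end-diastolic) frames are placed perpendicular
to the centerline at arc length `s0 + (frame_index - first_index) *
speed/frame_rate`. Orientation transport uses rotation-minimizing frames via
the double-reflection method: Frenet frames are undefined on straight
segments and add torsion-driven spin, which the CAD-style workflow this
mirrors implicitly avoids. In-plane, each frame is translated so the
*lumen centroid* sits on the centerline (frame centroid registration). The
catheter (transducer) point then generally sits off-axis, and the per-frame
catheter points form the *virtual catheter path*.

**Why centroid registration matters.** Near the carina the lumen widens into
the ostium and its centroid jumps; centroid-registered frames are then
displaced and the catheter path kinks. `correct_catheter_path()` fits a
cubic smoothing spline (GCV) per coordinate against arc length, flags points
whose residual norm exceeds `k = 3` times the MAD, and replaces them with a
refit through the remaining points; the flag-and-refit loop iterates because
a 30-frame excursion can drag a single GCV fit with it. Flagged frames'
contours are translated by the same in-plane vector. This automates what was
a manual correction step in the workflow this package reimplements.

**Twist correction.** Catheter torsion rotates successive frames about the
catheter center. The relative rotation between consecutive lumens is found
by a grid search (±45 degrees in 1-degree steps, one 0.1-degree refinement)
over the mean squared difference of radial profiles (360 samples about the
catheter point), with ties broken toward the smallest magnitude, then
negative. Non-star-shaped lumens fall back to a polygon-to-polygon mean
distance. Two safeguards:

* a *quality gate* (`max_profile_mismatch = 0.15`): if even the best match
  leaves an RMS profile difference above 15% of the mean radius, the shapes
  genuinely differ (the lumen morphs across the ostium) and rotation is not
  identifiable; the increment is set to zero rather than trusting noise;
* the estimate is *relative*, so errors accumulate as a random walk. The
  carina registration pins the absolute roll at the carina frame.

On near-elliptical sections with realistic segmentation noise the
per-pair estimator is noise-limited (the only orientation signal is the
second harmonic of the radial profile), and the accumulated drift of the
*correction itself* can exceed the twist it removes. This is why the bench
mode — like the silicone bench experiments the validation emulates — treats
pullbacks as twist-free and skips the stage, and why the full-noise phantom
recovery runs use bench mode: in-plane rotations are neutral for the
diameter and shape-ratio metrics, while correction drift bends the junction
geometry. The correction itself is validated separately by
injection-recovery tests (RMSE < 2 degrees over 50-frame random walks),
which is the regime — identifiable shapes, genuine twist — it exists for.

**Carina registration.** Each stack receives one global roll so that, in the
carina frame's plane, the annotated carina direction points at the
projection of the other branch's take-off direction (the other centerline's
tangent at its point nearest the carina, oriented distally). This is the
absolute-orientation anchor; its residual is reported.

**Lofting and the branch union.** Rings are resampled to `n_theta` points at
equal angles about the frame origin starting on the frame's u axis — a
correspondence that is robust to vertex count and starts are automatically
continuous after roll correction. Rings that are not star-shaped about the
origin (merged slices near the ostium) fall back to arc-length resampling
started at the vertex nearest angle zero. Consecutive rings are stitched
into triangles and capped. The MV and SB tubes are merged on a signed
distance grid (default pitch 0.1 mm) whose pointwise minimum is isosurfaced
with marching tetrahedra: exact mesh booleans fail on the near-tangent
carina contact, whereas the grid union is robust and its error is
pitch-controlled (orthogonal-cylinder test: volume within 2% of the
inclusion-exclusion value at 0.05 mm pitch). The grid is deliberately
misaligned with the mesh caps by a fraction of a pitch, and exact-zero node
values are pushed outside, so the triangulation stays non-degenerate.

**Mapping back and refinement.** Every frame plane slices the reconstructed
surface; the slice loop whose centroid is nearest the frame origin is
compared with the segmented contour (mean and max point-to-curve distance).
`refine_to_contours()` pulls vertices near each frame plane toward the
closest contour point until the mean deviation reaches `tol` (default
0.05 mm); the deviation never increases because a worsening sweep reverts.
The pipeline refines the *branch lofts* before the union — the vertex-pull
needs the ring structure of a loft, and mapping back against the merged
model near the ostium would measure the real branch aperture rather than
reconstruction error.

**Carina landmark.** The carina point is found by marching from the take-off
point along the bisector of the two distal branch directions until the ray
exits the lumen, then bisecting. The definition is identical for
ground-truth and reconstructed models — which is exactly what carina-based
co-registration needs — and the located point lies on the lumen surface by
construction. The take-off itself is the most distal main-vessel point the
side-branch centerline approaches, not the globally nearest one, because an
SB pullback typically runs several millimetres inside the shared trunk.

## Validation metrics

Serial cross-sections are taken every 0.1 mm perpendicular to each branch
centerline. Per section: area, area-equivalent diameter `2*sqrt(area/pi)`
(the underlying reports do not define "diameter"; the area-equivalent
reading is the default and a maximum-chord variant is available through
`max_chord_and_width()`), the maximum chord (distance X), the full polygon
extent perpendicular to it (distance Y), and the shape ratio Y/X (1 =
circle). Polygons are densified to 512 boundary points first, keeping the
chord discretization error below 0.1%.

Two models are compared by re-origining arc length at the carina (s = 0,
positive toward the proximal end), pairing sections on a common grid, and

* regressing z-scored diameters (A on B). The z-score `(x - mean)/sd` uses
  the *sample* standard deviation: reading "standard deviation of the mean"
  as the standard error would make z-scores scale with sqrt(n) and break the
  unit-variance interpretation. The normalization removes the systematic
  lumen-size offset between modalities (IVUS overestimates), which is why a
  uniformly dilated copy regresses back to slope 1, intercept 0;
* Bland-Altman analysis of the shape ratios (differences `a - b`, limits
  `mean ± 1.96 sd`);
* medians and interquartile ranges of the shape ratio per model.

SB sections proximal of the carina are excluded: a plane normal to the SB
centerline there cuts obliquely through the main vessel, i.e. the other
branch's domain. Regression p-values below 0.01 are flagged significant.

## The phantom: what it emulates and what it does not

`phantom_spec()`/`make_phantom()` build a synthetic bifurcation with known
ground truth, standing in for the silicone bench models (which are not
publicly available). Defaults are coronary-scale and are the package's
stated world:

* MV radius 1.5 mm and SB radius 1.2 mm at the bifurcation; branch lengths
  about 33 and 14 mm; bifurcation angle 55 degrees; a gentle 3D curve.
* The proximal trunk radius obeys Murray's law (`r^3 = 1.5^3 + 1.2^3`,
  about 1.72 mm), exponent configurable.
* Distal taper (MV 1.0%/mm, SB 2.5%/mm). Real coronaries taper; just as
  importantly, the z-score comparison is only well-posed when the diameter
  series has variance — it is undefined on constant series.
* Oval cross-sections (axis ratio 0.85, area preserved), so the shape-ratio
  metric has non-trivial ground truth; optional Gaussian stenosis.
* The SB centerline continues about 3 mm into the proximal trunk, as an SB
  pullback does.
* Virtual pullback corruptions: cumulative twist (random walk, default test
  level 2 degrees/frame), a smooth in-plane catheter offset field (0.1 mm),
  and boundary-correlated radial contour noise (0.05 mm) — uncorrelated
  vertex noise would self-intersect the narrow waist of merged slices, and
  real segmentation errors are smooth along the boundary.
* Virtual biplane projections are exact cone-beam projections of the
  centerlines with optional 2D Gaussian noise.

Not emulated: speckle or acoustic shadowing (contours are given, not
images), cardiac motion ("swinging"), respiratory or table motion,
pincushion distortion, ECG irregularity. A green phantom test therefore
establishes the geometric fidelity of the fusion pipeline given segmented
contours and calibrated projections — not segmentation robustness.

## Numerical choices

* Watertightness = every directed edge appears exactly once with its
  reverse; checked on every emitted mesh.
* Signed distance: scanline-parity sign (jittered rays) with exact narrow-
  band distances within 3 pitches of the surface; marching tetrahedra (6
  per cube) with orientation from the per-tet linear-field gradient, which
  is robust for sliver triangles.
* Ray-polygon radial sampling nudges angles by ~1e-9 rad so rays never pass
  exactly through vertices.
* Tie-breaks: twist search prefers the smallest |angle|, then negative;
  maximum-chord ties take the lexicographically smallest vertex pair.
* Pullback simulation keeps 0.5 mm clear of the ground-truth end caps so
  slicing planes never graze them; reconstruction mirrors this via `s0_mm`.
* Degenerate inputs error early and by name: two-point "polygons",
  self-intersecting rings, zero-area sections, views 5 degrees apart,
  pullbacks overhanging the centerline, ungated carina frames.

## What the phantom recovery tests establish

With no corruption, the reconstructed lumen lies within about 1% of the mean
lumen radius of the ground-truth surface (mean symmetric distance, measured
over the common coverage window; the pullback starts 0.5 mm inside the
phantom, so end caps are excluded). Under the realistic corruption levels
(twist 2 degrees/frame, 0.1 mm catheter offset, 0.05 mm contour noise), the
z-scored diameter agreement with ground truth reaches mean r-squared of
about 0.97 on the main vessel over five seeds. The side branch is harder:
its stored frames near the ostium are large merged cross-sections whose
placement depends on the catheter-path repair, and the resulting flare of
the lofted branch surface contaminates perpendicular sections for about
2 mm distal of the carina; side-branch r-squared varies between roughly
0.89 and 0.98 per seed (mean about 0.94). These numbers are computed live by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, not quoted.

## Known limitations

* Twist estimation on near-circular lumens is noise-limited (see above);
  clinical-grade twist handling would need either richer shape features or
  an external orientation reference.
* The lofted correspondence assumes sections are star-shaped about the
  registered centroid; strongly concave lumens fall back to arc-length
  correspondence, which may rotate the seam slightly.
* Plaque solids are lofted from full polygons and capped at their first and
  last appearance; sub-frame axial extents are quantized to the gated
  spacing (single-frame components become discs one gated spacing thick).
* The union accuracy is bounded by the grid pitch; sub-pitch wall details
  are smoothed.
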