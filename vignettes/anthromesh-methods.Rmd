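---
title: "Measuring bodies from meshes: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bodies from meshes: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthromesh)
```

## What the package computes

`anthromesh` turns a 3D body mesh into the quantities a clinician or
anthropometrist reads off a body scanner: stature, girths (chest, waist,
hip, upper arms, thighs), segment lengths, and the chest slab volume. The
pipeline is: read the mesh (STL or OBJ, geometry only) → optionally reduce
its vertex count → render a frontal perspective depth map → detect eleven
body seed points on the silhouette → segment the body → section the mesh
with landmark-anchored horizontal planes and integrate.

Every stage is backed by a synthetic A-pose humanoid generator whose
measurements are known in closed form, so the whole chain is testable as a
parameter-recovery problem.

## The camera and depth-map model

The camera is an ideal perspective pinhole defined by the vertical field of
view `fovy` (degrees, default 40), the `aspect` ratio (default 1) and the
depth range `[near_n, far_f]` (mm, defaults 1000–6000). The projection
matrix is the standard symmetric frustum: `m[1,1] = cot(fovy/2)/aspect`,
`m[2,2] = cot(fovy/2)`, bottom row `(0, 0, -1, 0)`; the canonical
projection plane sits at `z = -cot(fovy/2)`. The camera stands
`cam_height` metres above the floor and `cam_distance` metres in front of
the subject, looking horizontally. The defaults (1 m, 3 m) are the
placement that minimizes both ratio-error components on the reference
camera grid shipped with the package (`camera_grid_reference()`;
`select_camera()` reproduces the choice).

Depth maps are rasterized on the CPU with a z-buffer (nearest surface wins,
no antialiasing — crisp silhouettes matter more to the landmark rules than
smooth edges). Intensity maps camera depth linearly from `[near_n, far_f]`
to `[255, 1]`; the direction (nearer = brighter) is a convention chosen so
the subject stands out bright on a black background. The unquantized depth
is kept alongside the 8-bit image so pixels back-project to world points
exactly; on disk it is stored as a two-channel 16-bit encoding next to the
display PNG. `fovy = 40` frames a 1.9 m subject with margin at 3 m and is
exposed as a parameter.

## Seed-point rules

Eleven keypoints segment the body: head end, neck, two shoulders, two
armpits, two fingertips, two toes, and the crotch. The roster counts the
bilateral landmarks twice and the midline ones (head end, neck, crotch)
once — that bilateral reading is the only way the anatomical categories sum
to eleven, and we document it as an inference. The rules, applied in order
on the frontal silhouette:

1. **Head end** — topmost silhouette row, centroid column.
2. **Neck** — the thinnest smoothed width within the top 30% of the
   silhouette. Applied literally this would fire on the head crown, where
   the width tends to zero; the detector therefore walks down to the head's
   widest row first (the first local maximum of the smoothed width) and
   minimizes below it. Ties resolve to the topmost row.
3. **Shoulders** — per side, the first sign change of the second difference
   of the smoothed side contour below the neck (the inflection of the
   neck-to-shoulder curve). The estimator is our choice; second differences
   on integer contours are noise-sensitive, hence the smoothing.
4. **Armpits** — per side, the first row below the shoulder where a gap
   opens between the arm and the torso, taken at the torso-side gap
   boundary. Both the gap and the separated arm interval must span at least
   2 px: single-pixel gaps between near-tangent rounded surfaces are
   rasterization jitter, not anatomy.
5. **Fingertips** — per side, a range search over the columns outside the
   row's *central span* (see below): the bottommost such pixel.
6. **Toes** — the bottom row of the central region, one landmark per leg
   interval.
7. **Crotch** — scanning upward from the toes along the leg midline, the
   first row whose silhouette covers the midline (where the legs merge).

The *central span* is the per-row column interval connected to the body
midline, walked downward from the armpit row: torso, then hips, then legs.
Classifying "arm" as "outside the central span" rather than "outside the
armpit-row torso interval" matters for wide-hipped, narrow-chested bodies,
whose thighs extend beyond the chest width.

The silhouette width profile is smoothed with a 5-row moving average before
the minimum/inflection rules; the raw profile is used for the gap
(interval-count) tests, which must not be blurred. "Top 30%" is measured
over silhouette rows, not image rows. Detection runs on the frontal view
only, and *left/right follow image coordinates* (the left landmark has the
smaller column), not anatomical side.

Segmentation partitions the silhouette exactly: head above the neck row,
neck down to the shoulder row, arms outside the central span below the
armpit rows, legs below the crotch split at its column, torso the rest.

## Measurement model

**Cross-sections.** Each face is intersected with the plane `y = const`;
the resulting segments are chained into closed loops by nearest-endpoint
matching (hash bins of 1e-6 mm with a neighbourhood search, so endpoints
straddling a rounding boundary still pair). Vertices exactly on the plane
are nudged by 1e-9 mm; zero-length segments from planes grazing a mesh ring
are discarded; genuinely open chains (non-watertight regions) are dropped
with a warning rather than aborting.

**Girths.** Torso girths (chest, waist, hip) use the *convex hull* of the
section loop — a tape measure spans concavities. Limb girths use the raw
loop perimeter. Both modes are exposed and switchable. Limb loops are
selected by proximity to the limb axis interpolated between its landmarks.
Note that limbs are sectioned with horizontal planes: for an arm abducted
25° from vertical this overestimates the axis-normal girth by roughly
1/cos(25°) averaged over the ellipse (≈5%); the torso and thigh girths are
unaffected because those parts are vertical.

**Measurement planes** are anchored to landmarks rather than fixed height
fractions, because published girth definitions are landmark-relative: the
waist is the torso-perimeter *minimum* in the upper 60% of the
crotch-to-armpit span; the chest is the *maximum* between the waist plane
and the armpit line (searching below the waist would pick up the hip flank
on wide-hipped bodies); the hip is the maximum between crotch and waist;
thighs are sectioned 5% of stature below the crotch and upper arms 25% of
the shoulder-to-fingertip span below the armpit. Extremum searches use a
25-point coarse grid plus a 9-point refinement; maxima break ties toward
the armpit (a constant-girth torso degenerates to the armpit line, with a
warning), minima toward the crotch.

**Volumes.** The chest volume integrates the largest loop's area (torso
only — arm loops are excluded by the largest-area rule) between the waist
and chest planes with the trapezoid rule over 64 slices; integration planes
are kept infinitesimally inside the slab so flat end caps are not lost.
The observed error halves when the slice count doubles, consistent with
the trapezoid's quadratic order.

**Lengths.** Arms: Euclidean shoulder-to-fingertip distance. Legs: armpit
height to toe. Torso: neck to crotch height. **Indices:** `bmi()` and
`whtr()` implement kg/m² and waist/height.

## Vertex reduction

Scanned bodies arrive with ~250k vertices; `reduce_stepwise()` removes
10,000 at a time (floor 60,000 — the level below which body information is
judged lost) using iterative shortest-edge collapse with midpoint placement.
The collapse algorithm is our choice — a quadric-error variant could be
swapped in behind the same contract.

The loss guard is *dimensional*, not visual: probe planes at 10/30/45/55/72%
of the reference height are sectioned through both meshes and the largest
relative deviation of total perimeter is the loss. The metric is normalized
by the reference, hence asymmetric in its arguments. The trace records the
*running maximum* of this deviation: decimation is nested, so information
once lost is not recovered, and recording the running maximum makes the
trace's monotone-degradation invariant hold by construction. A momentary
girth re-approach at a finer probe would otherwise make the raw per-step
number non-monotone without any information having returned.

`resize_to_height()` calibrates a mesh to the subject's known stature by
uniform scaling about the floor point; girths scale linearly and volumes
cubically, which the tests assert to 1e-6 relative.

## The synthetic humanoid

The generator emulates a standing adult in A-pose: a lofted elliptical
torso (girth-controlled 256-gon profiles at crotch/hip/waist/chest/shoulder
levels — 0.47/0.53/0.62/0.72/0.81 of stature — joined by cosine
interpolation, so each control is a true local extremum), an ellipsoid head
on a tapering neck (producing the top-30% width minimum at 0.89 of
stature), cylindrical legs parted by a stance gap, and cylindrical arms
abducted 25° with hemispherical deltoid caps. The caps are not cosmetic: a
flat tilted cap rasterizes as a detached sliver beside the shoulder taper
and falsely triggers the armpit gap rule, whereas every horizontal slice of
a hemisphere stays connected to the torso.

Defaults: stature 1700 mm, chest/waist/hip 100/85/98 cm, torso ellipse
aspect 0.7, head radius 90 mm, neck radius 51 mm, arm radius 45 mm, arm
length 0.38·H, stance half-gap 0.015·H. Radii scale with stature; girths
are free parameters. Abduction must exceed 10° and the stance gap must be
positive — the armpit and crotch rules need visible gaps.

Ground truth is analytic by construction: control girths are exact polygon
perimeters (profiles are polygons precisely so truth avoids elliptic
integrals); the chest slab volume is a Simpson integral of the closed-form
profile areas; the armpit height solves the arm-inner-surface/torso-profile
tangency equation by root finding; the neck height solves the
head-width-equals-neck-width equation in closed form.

`sample_population()` draws stature from U(1500, 1900) mm and chest, waist
and hip girths from U(80, 115), U(60, 105) and U(80, 115) cm, rejecting
draws whose waist is not at least 2 cm below chest and hip (a waist within
2 cm of its neighbours makes the perimeter minimum ill-defined). All
randomness flows through one seeded generator and the global RNG state is
restored afterwards.

What the generator does *not* emulate: soft-tissue asymmetry, pose
variation, clothing, scanner noise and self-occlusion. Passing the recovery
suite therefore demonstrates the correctness of the geometry and of the
rule implementations, not robustness to real scan artifacts.

## Evaluation metrics

`ratio_error_pair()` computes A (chest/waist-ratio error) and B
(arm/thigh-ratio error), relative by default (`|Δr|/r_ref`); an absolute
mode (`|Δr|`) is provided because either reading is defensible. Ratios are
scale-free, so uniform scaling of either report changes nothing.

`select_camera()` operationalizes "minimize the error of each A and B" as
minimizing A+B per model over non-broken grid cells; on the reference grid
this reproduces the (1 m, 3 m) placement for both models, which validates
the rule at the only available data point. If models were to disagree, the
cell minimizing the summed score over models is returned and flagged.

`error_summary()` / `aggregate_accuracy()` implement the per-part percent
error `100·|actual − generated|/actual`, their mean, and the accuracy
`100 − mean`; parts with a zero actual value are excluded with a warning.

## Numerical choices and problem sizes

- Weld tolerance 1e-6 mm on STL read; binary STL stores float32, so
  round-trips agree to ~1e-3 mm at body scale.
- Section chaining tolerance 1e-6 mm, match radius 4e-6 mm.
- Depth maps 512×512 by default (~4.3 mm/px vertically for a 1.7 m subject
  at 3 m); landmark heights recover to ~1% of stature at this resolution.
- The test and acceptance suites run the full pipeline on 20 sampled
  humanoids at 512×512, and exercise decimation on meshes of ~85k
  vertices — sizes chosen to exercise every rule while keeping a full run
  in minutes on one CPU.

## Known limitations

- Frontal-view landmarking only; side views are rendered but not
  landmarked.
- Arm girths are horizontal-section girths (see above).
- The measurement-plane definitions are search-based surrogates for the
  survey definitions they approximate; they are self-calibrating and
  testable, but not guaranteed to match any specific survey item.
- Face orientation is trusted as given; there is no re-orientation or mesh
  repair pass.
- The decimator has no topological link-condition check; on pathological
  inputs a collapse can create non-manifold configurations (harmless to the
  girth metrics, which drive its use here).
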