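---
title: "Guide-wire planning and drill-guide design for hip resurfacing: methods"
author: "sraguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-wire planning and drill-guide design for hip resurfacing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

In hip surface replacement arthroplasty (SRA) the femoral component is
aligned on a guide wire drilled through the femoral head along a planned
axis. Small alignment errors matter: varus malpositioning and cortical
notching of the neck raise the risk of femoral neck fracture. `sraguide`
implements a desk-scale computational analogue of a patient-specific
drill-guide workflow:

1. **Anatomy fitting** — recover the femoral head sphere and the anatomical
   neck axis from a triangle surface mesh of the proximal femur.
2. **Planning** — the guide-wire axis is the anatomical neck axis plus the
   surgeon's valgus/version adjustments, with a cortex-clearance (notching)
   check.
3. **Jig design** — parametric generation of the patient-specific drill
   guide: a slightly more-than-hemispherical cage over the anterior femoral
   head, an anterior neck support, four cutting knives on the central arch,
   and a drill-guide cylinder on the planned axis.
4. **Evaluation** — register a (simulated) optical scan of the resected head
   back onto the planning model with trimmed ICP, fit the drill channel, and
   report the angular deviation (true-3D plus frontal/axial/sagittal
   components) and the insertion-point distance.

Because no clinical imaging data accompany this workflow, the package ships
a seeded synthetic femur generator with exact ground truth; every stage of
the pipeline is validated end-to-end against known injected deviations.

## The synthetic femur

The bone is composed analytically: a spherical head (default radius 24 mm),
an elliptic neck (semi-axes 16 x 13 mm — superoinferior x anteroposterior)
whose centred sections make the ground-truth neck axis exact by
construction, a circular-arc bend realizing the CCD angle (default 127
degrees), an anteversion tilt (default 15 degrees), and a shaft stub. The
surface is produced as a single swept vertex grid (sections perpendicular to
the skeleton; the per-section radius is the union of the primitives), so
the mesh is watertight by construction and bit-identical for identical
parameters and seed.

Two features deserve comment:

* **Fovea capitis.** A spherical dimple (radius 6 mm, depth 2 mm, 25 degrees
  posteroinferior of the apex) is subtracted from the head. Besides being
  standard anatomy, the fovea is the feature that makes scan-to-model
  registration well posed: a resected femoral head is otherwise close to
  rotationally symmetric (a sphere plus a short, two-fold-symmetric elliptic
  neck stump), and a human operator aligning retrieval scans uses exactly
  this landmark.
* **Cartilage.** CT segmentation yields the bone surface; articular
  cartilage is not visible on CT and is often damaged in osteoarthritic
  hips. The generated mesh therefore represents bone only;
  `cartilage_thickness` is carried as metadata and motivates the knife
  design (blades that cut through cartilage to seat on bone).

The neck profile is a constant elliptic cylinder over its waist and flares
quadratically toward the trochanter from 95% of the neck length. This
"waist plateau, then rising area" shape is what the corridor-detection
saddle rule of the neck-axis fit keys on. Surface noise (default 0.15 mm,
about one tenth of a CT voxel at the stated 2.5 mm slice spacing) is applied
along vertex normals after ground truth is recorded.

What the generator does *not* emulate: segmentation artifacts, osteophyte
fields beyond simple smooth bumps (`n_osteophytes`), cortical/trabecular
interior structure, pathological head deformity, and scanner-specific noise
spectra. Passing tests therefore demonstrate correctness of the
computational chain under controlled geometry, not clinical performance.

## Anatomy fitting

**Head sphere.** The algebraic least-squares sphere (linearized
`|p - c|^2 = r^2`) refined by residual trimming whose inclusion band shrinks
with the core residual scale: head-neck crease points cannot bias the
final estimate, and a noise-free sphere is recovered to machine precision.
A seeded RANSAC mode (500 four-point hypotheses, 0.5 mm consensus band)
provides the initial localization and outlier robustness.

**Neck axis.** The anatomical neck axis is defined morphometrically: the
total-least-squares 3D line through neck cross-section centroids, re-slicing
perpendicular to the current axis until the direction changes by less than
0.01 degrees (50-iteration cap). Section centroids are the plain mean of the
boundary-crossing midpoints: the mesh crosses the plane once per vertex
column, so the midpoints sample the section evenly and their mean recovers
the centre of the (possibly oblique-cut) elliptic section exactly —
ellipticity does not bias the fit, and even a poor initial direction is
corrected after one pass. (Length-weighting the segments would couple the
centroid to the noise-induced jaggedness of the boundary and inflate its
variance several-fold.) The neck corridor runs
from 1.05 head radii past the head centre to the distal-most point of the
waist plateau (tolerance 1.5%, a value set to ride above the perimeter
jitter induced by 0.15 mm surface noise), bounded to 0.25-0.42 head radii.
Under the default noise the axis is recovered to within a quarter of a
degree in all of 50 seeded replicates (95th percentile 0.16 degrees).

**Anatomical frame.** Superior opposes the distal shaft direction. The
medial axis comes from an anterior reference direction when available — CT
planning data are acquired in a patient-aligned scanner frame, which is what
published frontal/axial/sagittal components refer to. Without a reference
the frame falls back to the frontal plane spanned by the shaft and neck
axes; that fallback carries no anteversion information (the neck then lies
in the frontal plane by construction). A mirrored right femur flips the
medial axis; the frame triple then has determinant -1, as in per-side
conventions of the motion-analysis literature. All angle computations are
unsigned, so handedness never enters the reported numbers.

## Planning

With both adjustments zero the plan axis *is* the neck axis. `valgus_adjust`
rotates the drilling direction within the frontal plane, with the sign fixed
operationally: positive valgus brings the wire closer to the distal shaft
direction (a larger neck-shaft angle). `version_adjust` then rotates about
the superior axis, positive meaning the into-the-head end of the wire gains
anterior inclination. The default `valgus_adjust = +3` degrees reflects the
standard recommendation to err on the valgus side. The order
(valgus then version) is a convention; it is covered by an explicit
rotation-composition oracle test.

The clearance check sweeps a cylindrical corridor (wire radius, or the
implant stem radius) along the plan axis through the neck corridor and
reports the minimal signed margin to the superior and inferior cortex;
a negative margin is notching. Margins are computed from mesh vertices plus
area-weighted surface samples and agree with a dense-sampling oracle to
0.1 mm.

## Angular-deviation decomposition

The deviation between planned and achieved drill directions is reported as
the true-3D angle plus frontal, axial and sagittal components. The
components are the resolved parts of the **minimal rotation vector** carrying
the planned direction onto the achieved one: component = theta * |axis .
plane normal|, where theta is the true-3D angle and the plane normals are
anterior (frontal), superior (axial) and medial (sagittal). Two properties
recommend this definition over in-plane projections of the two directions:

* each component is bounded by the true-3D angle, and the squared components
  sum exactly to the squared true-3D angle — the arithmetic that published
  per-plane deviation tables for this procedure satisfy to printed rounding;
* projected angles violate the bound: rotating a direction with in-plane
  fraction *s* about a perpendicular axis produces a projected component
  `atan(tan(theta)/s) > theta`.

A degenerate flag covers parallel directions (undefined rotation axis, all
components zero).

## Jig design

All parts are generated as analytic signed fields and the union is meshed by
marching tetrahedra (Freudenthal lattice split) on a grid anchored to the
jig's local frame. This field-based CSG cannot produce non-manifold output —
the extracted surface is watertight unconditionally — and makes generation
exactly rigid-transform equivariant (transforming femur and plan transforms
the jig to within floating-point error). Sub-voxel slivers are retained in
the triangulation (dropping them would open the surface); they carry zero
area and are ignored by all geometric queries.

* **Cage**: spherical shell, inner radius = head radius + `contact_offset`
  (default 0.5 mm — the stand-off that absorbs residual cartilage and
  manufacturing tolerance), thickness 3 mm, extending 100 degrees from the
  pole ("slightly more than hemispherical"), with the beyond-equator band
  kept only on the anterior side. The pole sits on the plan-axis entry
  point, which guarantees the drill cylinder attaches.
* **Knives**: four thin wedges (1.5 mm wide, 20-degree included angle,
  0.6 mm edge land) on the central arch — the great circle in the plane of
  the drill axis and the anterior direction, at -45/-15/+15/+45 degrees from
  the pole. Edge radius equals the head-fit sphere radius, so the blades
  bridge the offset gap and seat on the segmented bone surface (in the
  physical situation: cut through cartilage to bone). A `knife_penetration`
  parameter moves the edges deeper if desired.
* **Neck support**: an offset shell (offset = `contact_offset`, thickness
  3 mm) over the measured radial surface profile of the anterior neck
  (160-degree wrap, 25 mm along the axis), continued proximally as the loft
  bridge to the cage rim. The profile is measured from the actual bone mesh
  by ray casting from the neck axis, so the support follows any femur, not
  just the synthetic family.
* **Cylinder**: a tube on the plan axis (bore = wire + 0.2 mm, outer =
  bore + 4 mm, length 30 mm); the bore is subtracted through every part,
  and a ray cast along the drill axis verifies patency.

The default lattice spacing is 0.35 mm; on a smooth field the surface
placement error of linear interpolation is O(voxel^2 x curvature), orders of
magnitude below the 0.1 mm contract tolerances.

### Snap-fit validation

The surgeon-facing qualitative checklist ("unique position, passive
stability, full neck contact, knife contact") is quantified on the synthetic
analogue through a contact cost model:

* each knife edge is an **embedded point constraint** — a blade seated in
  the cut it has made resists displacement in every direction (isotropic
  spring on the tip contact point);
* the neck support grips through the **superior and inferior rim lips** of
  its wrap (the outermost 8% of the half-wrap): point-to-surface springs
  that slide freely along the bone and resist normal motion. The anterior
  face of the support stands off the bone by the cartilage offset and is not
  a contact.

The design pose has exactly zero cost. A Nelder-Mead search from random
pose restarts within +/-5 mm and +/-10 degrees looks for competing
zero-cost seatings; the number of seated clusters is the analogue of the
checklist's "number of possible positions". Direction-resolved stiffness is
probed with unit anteroposterior and mediolateral translations and a unit
varus-valgus rotation, attributing each to the contact families by zeroing
them in turn. The model reproduces the intended mechanism: the knives
dominate AP/ML stability (removing the support changes AP stiffness by
about 8%), while varus-valgus stability is dominated by the neck support
(about 56% of it disappears with the support). The rim-lip band and the
probe magnitudes are calibration choices of this proxy, not measured
quantities.

## Post-operative evaluation

The simulated optical scan is the resected head (osteotomy at 85% of the
neck length) with a cylindrical drill channel subtracted along the
*achieved* axis — the planned axis tilted by a known angular error about a
perpendicular axis at a chosen azimuth and shifted tangentially at the
entry point — meshed from the same analytic field as the planning bone,
noised, and posed rigidly. The default pose distribution (rotation up to 15
degrees, translation up to 20 mm) represents the residual misalignment
after the coarse manual pre-alignment that precedes fine registration in
scan-processing software.

Registration is classic point-to-point ICP (closed-form Kabsch update from
exact closest points on the target triangles, grid-accelerated) with
trimming, organized in stages that reflect the geometry of the problem:

1. **Global initialization.** The scan's own stump direction (centroid of
   points beyond the head sphere, seen from the scan's RANSAC head centre)
   is aligned with the planned neck direction, fixing the tilt; the
   remaining twist about the neck axis is resolved by a fan of 24 twist
   candidates, each refined by a short trimmed-ICP run. Candidates are
   scored by trimmed rmse *plus a fovea-landmark term* (mean squared
   distance of the planning model's fovea region to the registered scan):
   trimming alone cannot see the few fovea points, and the elliptic stump
   is two-fold symmetric, so the landmark term is what rejects the
   180-degree twist.
2. **Staged trimming** (18%, then 25%). The scan is ~72% sphere; at large
   misalignment the informative stump residuals are the largest ones, so
   aggressive early trimming would discard exactly the signal.
3. **Twist lock.** Fixed-fraction trimming carries no gradient in the twist
   about the near-symmetric neck axis (the few fovea points are always in
   the trimmed tail), so the residual twist is estimated directly: the
   scan's own fovea points — identified intrinsically as surface points
   lying 0.6-3.5 mm inside the fitted head sphere, away from the channel
   mouth — are swept through a fan of twist angles about the planned axis
   and the angle minimizing their distance to the planning surface is
   applied (coarse 0.75-degree then fine 0.14-degree steps).
4. **Absolute-threshold polish.** The final refinement rejects
   correspondences only above an absolute 0.8 mm residual (true outliers:
   cut-face and channel interiors) instead of a fixed fraction, so every
   plausibly bone-on-bone point — including the stump and fovea points that
   carry the rotational information — participates in the closed-form
   updates. Under the default conditions the registration converges to
   about 0.1 degree total rotation error, and re-evaluating one simulated
   case under different random scan poses reproduces the deviation record
   to a few thousandths of a degree.

The achieved axis is the least-squares cylinder through the channel-wall
points (vertices close to the axis whose outward normals point back at it),
initialized from the principal axis and refined by BFGS on
`sum((rho - r)^2)`. Extraction and fitting alternate three times: seeding
the wall search with the planned axis truncates a tilted channel
asymmetrically, which under noise attenuates the fitted angle; re-centring
on the fitted axis restores complete wall rings.

The insertion-point distance is the 3D chord between the entry points of the
planned and achieved axes on the planning model ("true three dimensions"),
not a geodesic along the head.

Under the default study conditions (five cases, injected angular errors of
1-3 degrees and entry shifts of 1-2.2 mm, scan noise 0.1 mm) the pipeline
recovers the injected deviations with median absolute errors well below
0.2 degrees and 0.2 mm; the acceptance script recomputes these numbers at
run time.

## Numerical choices and degenerate inputs

* Angle equality tests use 1e-9 degrees (pure double-precision geometry);
  iterative stages use their own stated tolerances.
* Zero-length directions, non-orthonormal rotations and frames, adjustment
  angles beyond +/-20 degrees, axes that miss the bone, channel radii at or
  above the neck minor radius, empty cohorts and missing files all raise
  classed errors (`sraguide_*`) that the CLI maps to exit code 1.
* ICP carries a monotonicity safeguard: if the trimmed rmse ever rises, the
  last transform is kept and iteration stops.
* All randomness (noise, sampling, RANSAC, pose draws, restarts) flows
  through explicit seeds with the caller's RNG state restored afterwards;
  identical configuration and seed reproduce reports byte-identically.

## Problem sizes used by the shipped validation

The test-suite and acceptance-script problem sizes are chosen to exercise
every claim at full fidelity while staying desk-scale: synthetic femurs at
1 mm target edge length (~47k faces), 2000-point registrations, 50-replicate
neck-axis recovery, a five-case end-to-end pilot, and one fully validated
jig per run (0.45 mm lattice for testing, 0.35 mm default for export).

## Known limitations

* The snap-fit cost is a kinematic proxy; it says nothing about contact
  mechanics, friction or press-fit elasticity.
* The jig's visual styling (fillets, embossing, exact strut cross-sections
  of the commercial device) is out of scope; the generated solid realizes
  the functional contract (contacts, offsets, patency, stability split).
* Without a fovea (or comparable asymmetry) on the head, the twist component
  of scan registration is fundamentally underdetermined; the pipeline then
  still reports true-3D angle and insertion distance correctly (both are
  twist-invariant) but per-plane components inherit the twist ambiguity.
* Registration assumes the scan covers the head plus a usable neck stump;
  heads resected flush at the equator would need landmark-based
  initialization instead.
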