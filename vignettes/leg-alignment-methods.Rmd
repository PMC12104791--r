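---
title: "Methods: standardized 3D leg alignment analysis on labeled bone models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized 3D leg alignment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(legalign)
```

## The measurement problem

Lower-limb deformity analysis and osteotomy planning rest on a handful of
angles: the hip–knee–ankle angle (HKAA), the mechanical lateral distal femoral
angle (mLDFA), the medial proximal tibial angle (mMPTA), their sagittal
counterparts (mPDFA, mMPPTA, mLPPTA), femoral version (FVA) and tibial torsion
(TTA). Measured on radiographs these angles suffer from projection and
positioning error; measured on 3D bone surface models they depend entirely on
*how* joint centres, joint-orientation lines/planes and coordinate systems are
derived from the mesh. `legalign` implements one coherent, fully specified
derivation chain built on a single principle: every centre and axis is derived
from **all available articular surface data**, never from single landmark
points, because a "most medial point" only exists relative to a coordinate
system that is itself still being constructed.

The package takes labeled triangle meshes — a femur and a tibia+fibula, each
with named articular regions — and returns the eight angles with residual
diagnostics. The required regions follow the standard articular subdivisions:
the distal femoral surface splits into medial condyle, lateral condyle and
trochlea at the sulcus terminalis and trochlear groove; the distal
tibial/fibular surface splits into tibial plafond, medial malleolus facet and
lateral malleolus facet at the medial gutter. Identifying those boundaries on
a real segmentation is the labeler's responsibility: the package validates
label consistency (disjointness, coverage, index ranges) but does not attempt
to detect the sulcus terminalis or the medial gutter on the mesh itself.

## Derivation chain

**Joint centres.**

* Hip: centre of a geometric (orthogonal-distance) sphere fit to the femoral
  head region. An algebraic fit initializes; Levenberg–Marquardt plus a short
  Gauss–Newton polish refines.
* Knee, femoral side: a geometric cylinder is fit to the union of both
  condylar regions; its central axis is intersected with the whole femur mesh,
  and the centre is the midpoint of the two extreme intersections. A config
  switch (`center.femoral_intersection_scope`) restricts the intersection to
  the labeled condyles for cortices distorted by osteophytes.
* Knee, tibial side: midpoint of the two plateau area-weighted centroids.
* Ankle: the single pooled area-weighted centroid of plafond + both malleolar
  facets (pooled, deliberately *not* the midpoint of per-region centroids —
  the two definitions differ whenever the regions have unequal areas, and the
  tests pin the pooled one).

**Mechanical axes.** mFA joins hip and femoral knee centre, mTA joins ankle
and tibial knee centre, and the mechanical leg axis (Mikulicz line, mLA) joins
ankle and hip. Directions are stored pointing proximally.

**Coordinate systems.** All frames are right-handed orthonormal triads with
x medial–lateral pointing to the *patient's right*, y posterior–anterior
pointing anteriorly, z distal–proximal pointing cranially. The femoral frame
sits at the distal femoral joint centre with z along mFA and x the condylar
cylinder axis projected along z onto the axial plane; the tibial frame is the
analogue from mTA and the plateau-centroid line; the leg frame shares the
femoral origin and x-construction but takes z along mLA. Because meshes arrive
in an arbitrary scanner frame, a 3×3 `orientation.hint` (approximate right,
anterior and cranial directions) resolves the global signs; for left legs the
x-axis still points patient-right, and all clinical angles are computed from
side-aware medial/lateral semantics so reported values are side-invariant.

**Joint orientations.** The distal femoral tangent (DFJ) joins the most distal
point of each condyle in the leg frame, ties within 1e-9 mm averaged (flat or
cylindrical condyle bottoms make the argmin a whole line; averaging is
deterministic and leaves the line direction unchanged, since tied points lie
on a common generator). The supracondylar-trochlear plane (SFJ) passes through
one most-proximal point per region (trochlea and both condyles) in the femoral
frame — the figure-faithful three-point construction; a border-band variant
(least-squares plane on the top 2% of each region's z-range, reading "most
proximal borders" as curves) is available via `sfj.mode = "border_band"` but
is not the default. Plateau orientations are area-weighted total-least-squares
planes per compartment and combined; the combined plane serves the coronal
mMPTA, the per-compartment planes the sagittal slopes.

**Angle conventions.** The paper-level definitions name the side of each angle
("the medial angle", "the posterior angle") but not the sign algebra; the
package fixes it operationally:

| angle | plane | rays | neutral | deformity sense |
|---|---|---|---|---|
| HKAA | leg coronal | mFA proximal vs mTA distal, medial side | 180 | varus < 180 |
| mLDFA | leg coronal | mFA proximal vs DFJ lateral | 90 | varus > 90 |
| mMPTA | leg coronal | mTA proximal vs (PTJ ∩ coronal) medial | 90 | varus < 90 |
| mPDFA | femoral sagittal | mFA distal vs (SFJ ∩ sagittal) posterior | 90 | anterior-proximal pitch p → 90 − p |
| mMPPTA/mLPPTA | tibial sagittal | mTA distal vs (PTJ ∩ sagittal) posterior | 90 | posterior slope σ → 90 − σ |
| FVA | femoral axial | condylar vs neck–femur axis, acute | build | anteversion when the m→l neck projection points posteriorly |
| TTA | tibial axial | plateau vs intermalleolar axis, acute | build | external when the m→l intermalleolar projection points posteriorly |

The HKAA medial-side resolution uses the resultant of the two projected rays:
if it points medially the medial angle is the acute-side angle (varus),
otherwise its reflex complement (valgus). The FVA/TTA labels read the anterior
component of the medial-to-lateral second axis in the reference frame, which
mirrors correctly to left legs without any special casing.

**Knee-extension prerequisite.** Coronal angles are only meaningful with the
knee extended — mFA and mTA parallel in the leg sagittal plane. The extension
residual is the angle between their sagittal projections; a pure coronal
deformity contributes nothing to it. `analyze_leg()` applies a policy:
`auto` (default) virtually extends when the residual exceeds 0.5°, `strict`
errors, `ignore` computes with a warning. Virtual extension rigidly rotates
the tibia+fibula about the condylar cylinder axis — the only consensus-derived
medial-lateral knee axis — by the signed sagittal residual, recomputing the
ankle centre, leg frame and residual each iteration (the residual is implicit
because the ankle moves with the tibia) until it drops below 0.01° or 50
iterations. This is a pure rigid repositioning: no soft tissue or joint-gap
model is implied, and the choice of the condylar axis over a functional
flexion axis is a package decision, not a consensus prescription.

## Numerical choices

* **Area-weighted face centroids** are the default point material for every
  fit and centroid (`region_points(..., "FACE_CENTROIDS")`): surface-uniform
  weighting makes results invariant to retriangulation, which raw vertex sets
  are not. The cost is a small quadrature bias for curved surfaces — face
  centroids of a tessellated sphere lie slightly inside it — which biases the
  fitted head radius by O(h²) and the centre by ~0.02 mm at 3 mm edge length.
  The bias is radial and nearly symmetric, so its effect on angles is below
  a few millidegrees; tests assert exact recovery on vertex samples and
  quantization-bounded recovery on centroid samples.
* **Geometric, not algebraic fits** are the contract: algebraic solutions
  (Kåsa) only initialize, because partial articular coverage biases algebraic
  fits. Cylinder initialization tries all three principal scatter directions
  as axis candidates (with a circle fit in each orthogonal plane) and refines
  the best; convergence tolerance 1e-10, at most 200 iterations, then a short
  Gauss–Newton polish so that equivariance under rigid motions holds to
  ~1e-8 rad. A cylinder fit whose points a sphere explains equally well is
  rejected as axis-unidentifiable.
* **Vertex merging** on mesh read snaps coordinates to a 1e-6 mm grid;
  binary STL stores 32-bit floats and therefore round-trips leg-scale
  coordinates to ~3e-5 mm (ASCII STL and PLY round-trip to 1e-6 mm or exactly).
* **Ties** in extremal-point searches (flat condyle bottoms, symmetric
  proximal borders) are averaged; all guards (short mechanical axes,
  near-parallel projections, degenerate fits) raise classed errors rather than
  proceeding silently.

## The phantom generator

Because no study meshes are distributed, validation runs entirely on
parametric phantoms with analytic ground truth (`generate_phantom()`). A right
leg is built in the canonical patient frame and mirrored for left sides:
femoral head = sphere sector (radius 24 mm) at the hip point; neck = full
cylindrical band whose axis realizes the femoral version (default 15°
anteversion, a typical adult value); condyles = two sector bands of a shared
22 mm cylinder embedded in a closed distal shell (full cylinder + end caps, so
axis–bone intersections behave as on a closed cortex and the chord midpoint is
the construction centre exactly); trochlea = a disjoint anterior sector of the
same shell; plateaus = planar parallelograms tilted by the coronal deformity
and per-compartment posterior slopes; plafond and malleolar facets = planar
patches whose centroid line realizes the tibial torsion (default 25° external,
again a typical adult value); shafts = unlabeled coarse tubes that are
geometrically inert downstream. Mesh boundaries snap to the patch edges, so
labeled regions end exactly at the construction boundaries. Knee flexion is a
rigid rotation of the tibia+fibula about the condylar axis; surface noise is
Gaussian along vertex normals (mimicking segmentation error while keeping
labels on-surface), seeded and applied after assembly.

Ground truth is computed in closed form from the construction *before* noise
and independently of mesh density: centres and axes directly, plateau planes
from the patch frames, the combined plateau plane from exact parallelogram
surface moments, and the supracondylar points by analytic arg-max over each
patch. Truth angles come from the unflexed configuration (what an
extended-knee analysis should recover); the expected extension residual from
the flexed one. The truth is self-consistent: recomputing the angles from the
truth primitives (`phantom_truth_angles()`) reproduces them to 1e-9°, which
the tests assert.

Deformities compose predictably: femoral varus γ~f~ and tibial varus γ~t~
give HKAA = 180 − (γ~f~ + γ~t~), mLDFA = 90 + γ~f~, mMPTA = 90 − γ~t~;
posterior slopes σ give 90 − σ; the supracondylar pitch p gives
mPDFA = 90 − p; version and torsion are recovered as built, with labels.

**What the phantoms do and do not show.** They exercise the entire derivation
chain — fits, centroids, intersections, frames, extension, projections, sign
conventions — against exact analytic truth, over deformity ranges (±10°
coronal, up to 12° slopes, −30…40° torsion) and realistic surface noise
(σ = 0.2 mm). They are *not* statistically shaped bones: articular surfaces
are ideal geometric primitives, there is no cartilage, no osteophyte, no
segmentation topology error, and region labels are exact. Passing phantom
validation therefore demonstrates correctness of the geometry pipeline under
the framework's assumptions, not robustness to labeling disagreement on
pathological anatomy — on real data the labels are the dominant uncertainty.

The default study conditions (validation problem sizes): presets NEUTRAL,
VARUS5 (2° femoral + 3° tibial), VALGUS8 (−5° and −3°), FLEXED10,
TORSION_SWEEP (−20…30° in 10° steps) and NOISY (σ = 0.2 mm, 10 replicates) at
1.5 mm mesh density (≈20k faces per bone); the frame-invariant sweep uses
1000 randomized phantoms at 4 mm density. Noise-free recovery tolerance is
0.2° per angle and the noisy tolerance 1.0°; observed errors are ~0.001° and
≤0.35° respectively, the noise-free floor being set by the vertex quantization
of the extremal-point constructions (DFJ/SFJ), not by the fits.

## Known limitations

* The supracondylar "most proximal borders" ambiguity (points vs border
  curves) is resolved in favour of the three-point figure construction;
  the border-band alternative is implemented but not default.
* mMPTA uses the combined plateau plane intersected with the coronal plane;
  the plateau-centroid line alternative is not implemented.
* Fixed flexion deformities that cannot be virtually extended should be
  analyzed with `angles.extension_policy = "ignore"`, reading the per-frame
  sagittal angles with the warning in mind; the package does not guess intent.
* Posterior-condylar-axis legacy measures, anatomical (shaft) axes,
  joint-line convergence and normative-range interpretation are out of scope,
  as are segmentation, DICOM reading and mesh repair beyond vertex merging.

## A worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(femoral_varus_deg = 2, tibial_varus_deg = 3))
report <- analyze_leg(ph$femur, ph$tibfib)
report
tidy(report)
max(abs(report$angles_deg - ph$truth$angles_deg))  # ~1e-3 degrees
autoplot(report)
```
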