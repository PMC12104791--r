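# legalign

Standardized 3D leg alignment analysis from labeled bone surface models.

## What this is for

Planning correction osteotomies around the knee (and interpreting deformity
in general) requires a small set of alignment angles: the hip–knee–ankle
angle (HKAA), the mechanical lateral distal femoral angle (mLDFA), the medial
proximal tibial angle (mMPTA), the sagittal angles mPDFA, mMPPTA and mLPPTA,
femoral version (FVA) and tibial torsion (TTA). When these are measured on 3D
bone models, the values depend entirely on how joint centres, joint
orientations and coordinate systems are derived from the mesh — and published
methods vary enough that results are not comparable across studies.

`legalign` implements a single, fully specified derivation chain built on one
principle: every centre and axis comes from **all available articular surface
data** of the relevant region, never from individual landmark points. It is
aimed at biomechanics engineers and orthopaedic researchers who have
segmented bone models (femur, tibia+fibula) with labeled articular regions
and want reproducible 3D alignment parameters.

## The derivation chain

With labeled articular regions (femoral head, neck, medial/lateral condyle,
trochlea; medial/lateral plateau, plafond, medial/lateral malleolar facets):

* **Joint centres** — hip: centre of a geometric sphere fit to the femoral
  head; knee (femoral): the condylar cylinder-fit axis intersected with the
  femur, midpoint of the extreme intersections; knee (tibial): midpoint of
  the two plateau centroids; ankle: pooled area-weighted centroid of plafond
  and both malleolar facets.
* **Mechanical axes** — mFA = hip→knee, mTA = ankle→knee,
  mLA (Mikulicz) = ankle→hip.
* **Coordinate systems** — right-handed triads with x medial–lateral
  (patient-right), y anterior, z cranial: femoral (origin at the distal
  femoral centre, z ∥ mFA, x = projected condylar axis), tibial (z ∥ mTA,
  x = projected plateau-centroid axis) and leg (z ∥ mLA, x = projected
  condylar axis).
* **Joint orientations** — condylar tangent DFJ (most distal condyle points),
  supracondylar–trochlear plane SFJ (most proximal point per region),
  per-compartment and combined plateau planes (area-weighted total least
  squares), neck–femur axis NFA, intermalleolar axis IMA.
* **Angles** — HKAA, mLDFA, mMPTA in the leg coronal plane; mPDFA in the
  femoral and mMPPTA/mLPPTA in the tibial sagittal plane; FVA and TTA as
  acute axial-plane angles with anteversion/retroversion and
  external/internal labels. Straight neutral anatomy gives
  180/90/90/90/90/90.
* **Extension prerequisite** — coronal angles require an extended knee
  (mFA ∥ mTA in the leg sagittal plane); flexed inputs are virtually extended
  by rigid rotation about the condylar axis (policy-configurable).

A parametric phantom generator (`generate_phantom()`) builds labeled synthetic
legs with analytic ground truth for every angle, so the whole pipeline is
testable without patient data; a CLI (`inst/scripts/legalign`) wraps reading,
validation, analysis and phantom emission.

## Worked example

```r
library(legalign)

# a right leg with 2 deg femoral + 3 deg tibial varus, 15 deg anteversion,
# 25 deg external torsion; truth angles are known analytically
ph <- generate_phantom(phantom_spec(femoral_varus_deg = 2, tibial_varus_deg = 3))
report <- analyze_leg(ph$femur, ph$tibfib)
report
```

```
3D leg alignment report (right leg)
  extension residual: 0.000 deg

  HKAA     175.00 deg  [hip-knee-ankle angle]
  mLDFA     92.00 deg  [lateral distal femoral angle]
  mMPTA     87.00 deg  [medial proximal tibial angle]
  mPDFA     90.00 deg  [posterior distal femoral angle]
  mMPPTA    90.00 deg  [medial posterior proximal tibial angle]
  mLPPTA    90.00 deg  [lateral posterior proximal tibial angle]
  FVA       15.00 deg (ANTEVERSION)  [femoral version]
  TTA       25.00 deg (EXTERNAL)  [tibial torsion]
```

The 5° of built varus split exactly as constructed: HKAA = 180 − 5, mLDFA =
90 + 2 (femoral contribution), mMPTA = 90 − 3 (tibial contribution); version
and torsion are recovered with their direction labels. Against the phantom's
analytic truth:

```r
max(abs(report$angles_deg - ph$truth$angles_deg))
#> 0.00068   # degrees
tidy(report)     # tibble of angles; glance(report) for a one-row summary
autoplot(report) # dot plot against neutral references
```

Real data enter through `read_bone_model()` (STL or PLY mesh plus a JSON
region-label sidecar, or a PLY `region_id` face property), or from the shell:

```sh
Rscript inst/scripts/legalign analyze \
  --femur femur.stl --femur-labels femur_labels.json \
  --tibfib tibfib.stl --tibfib-labels tibfib_labels.json \
  --side right --out report.json
```

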