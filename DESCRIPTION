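Package: legalign
Title: Standardized 3D Leg Alignment Analysis from Labeled Bone Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a consensus-based framework for three-dimensional lower-limb
    alignment analysis on labeled triangle-mesh bone models. Joint centres are derived
    from all available articular surface data (sphere fit to the femoral head, condylar
    cylinder axis intersected with the femur, plateau centroids, pooled ankle centroid),
    femoral, tibial/fibular and combined leg coordinate systems are constructed from
    mechanical axes and central medial-lateral joint axes, and the clinical alignment
    angles (HKAA, mLDFA, mMPTA, mPDFA, mMPPTA, mLPPTA, femoral version, tibial torsion)
    are measured in the anatomical planes of those systems. Includes STL/PLY mesh input,
    a JSON region-label sidecar format, virtual knee extension, a synthetic bone phantom
    generator with analytic ground truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
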