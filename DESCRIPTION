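Package: ccmark
Title: Terraced Marching-Cubes Reconstruction and Computer-Calculated
    Soft-Tissue Landmarks for CBCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs cone-beam computed tomography (CBCT) facial
    soft-tissue surfaces with a binary marching-cubes algorithm whose
    edge-midpoint vertices produce the stepped contour lines and flat
    "mountain tabletop" plateaus characteristic of 0.3 mm voxel data.
    Soft tissue is segmented automatically by Otsu thresholding and
    largest-component selection.  On the terraced mesh the package
    locates computer-calculated (CC) landmark points for six convex
    facial landmarks (pronasale, columella, upper and lower lip points,
    right and left cheek) as the centroid of the tabletop patch around a
    seeded starting point, filtered by a 50-pixel neighbourhood and a
    one-pixel band along each landmark's fixed anatomical normal, and
    verifies their perturbation consistency.  Rater-reliability
    statistics (two-item Cronbach's alpha, absolute coordinate
    differences, paired t tests, exact noncentral-t sample-size
    computation) and a synthetic face-phantom generator with known
    protrusion apices complete the pipeline, so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
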