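Package: celldepth
Title: Pseudo-3D Cell Architecture Inference from a Single 2D Histology Section
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a per-cell depth (z coordinate) and whole-cell radius from
    a single instance-labelled nuclear segmentation of an H&E-stained tissue
    section. Reconstruction is cast as penalized sphere packing: hinge
    penalties on the cell-to-nucleus radius ratio, the section depth box and
    pairwise non-interpenetration (at nuclear-radius distance) are minimized
    by a particle swarm optimizer with linearly scheduled inertia and
    cognitive/social coefficients and per-coordinate feasibility projection.
    Includes nuclear feature extraction from labelled masks, ASCII PLY
    icosphere export, cell-centric 60x60 patch construction, morphometric
    validation (nuclear-to-cytoplasmic ratio, its Shannon entropy, a random
    radius null model and two-sample Kolmogorov-Smirnov comparison), and a
    synthetic tissue generator providing feasible ground-truth packings for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
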