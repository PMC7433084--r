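Package: subchondralFE
Title: Voxel Finite-Element Analysis of Subchondral Bone After Microfracture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parametric voxel-based finite-element modelling of the subchondral
    bone plate after microfracture surgery. Builds a simplified two-layer
    osteochondral block (dense 0.3 mm subchondral plate over homogenised
    trabecular bone), drills vertical microfracture holes at configurable
    spacings, meshes the geometry with trilinear hexahedral elements, solves
    the small-strain isotropic linear-elasticity problem under a compressive
    load, and reports peak von Mises stress, peak displacement and safety
    factors against the plate yield stress. Includes a synthetic micro-CT
    phantom generator with threshold segmentation and layer labelling to
    exercise the image-to-mesh path, a mesh-convergence study, and VTK export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
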