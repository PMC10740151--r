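Package: brainshiftr
Title: Physics-Based Non-Rigid Registration for Intra-Operative Brain-Shift Compensation
Version: 0.1.0
Authors@R:
    person("CRTC", "Artifact", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deformable registration of pre-operative to intra-operative 3D MR
    volumes using block matching driven sparse displacements regularized by a
    linear-elastic tetrahedral finite-element model. Implements three outlier
    rejection schemes: iterative point rejection (PBNRR), nested
    expectation-maximization point and element rejection with resection-cavity
    recovery (NEMNRR), and adaptive incremental warping with remeshing (ANRR),
    together with registration-point-aware isotropic and anisotropic mesh
    sizing metrics, a synthetic phantom generator with known ground-truth
    deformation, and a Canny/Hausdorff evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
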