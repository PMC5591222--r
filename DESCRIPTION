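Package: meshfidelity
Title: Shape Fidelity Assessment of 3D-Printed Anatomical Models via
    Iterative Closest Point Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative assessment of how faithfully a fabricated or
    scanned surface model reproduces a reference model, as used in the
    validation of 3D-printed surgical phantoms. Aligns a test mesh to a
    reference mesh by an iterative closest point (ICP) procedure with
    SVD-based rigid transform estimation and stochastic surface
    resampling, computes per-vertex signed deviation ("fidelity") maps
    and their summary statistics, and provides a free-form-deformation
    validation harness that perturbs synthetic meshes by random
    translation, rotation and bounded control-point distortion. Includes
    STL input/output, synthetic test geometries, a benchmark driver, and
    a small linear calibration utility relating CT attenuation to
    contrast-agent concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
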