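Package: fetopose
Title: Monocular Placental Pose Estimation and Shared-Control Simulation for Fetoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the inclination of the placental surface relative to a
    fetoscopic camera from a single monocular image, and uses the estimate to
    autonomously align a flexible distal instrument tip perpendicular to the
    surface in a closed-loop simulation. Provides a synthetic fetoscopic scene
    generator with exact inclination labels (textured plane, camera-co-located
    cone illumination, Lambertian shading, inverse-square falloff), a minimal
    two-component orientation representation with rotation-based label
    augmentation, a small convolutional network regressor trained on the
    synthetic data, fulcrum-constrained instrument kinematics with a
    constant-curvature flexible tip, and evaluation tooling (angular accuracy,
    combined-error RMS, error heatmaps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    png,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
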