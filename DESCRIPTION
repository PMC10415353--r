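Package: bifuse
Title: IVUS and Angiography Fusion for 3D Coronary Bifurcation Reconstruction
Version: 0.1.0
Authors@R:
    person("bifuse", "developers", email = "bifuse@example.org", role = c("aut", "cre"))
Description: Fuses segmented intravascular ultrasound (IVUS) pullbacks with
    biplane angiographic centerlines to reconstruct coronary artery
    bifurcations in 3D, including lumen, external elastic membrane and plaque
    component solids. Provides biplane centerline triangulation, rotation
    minimizing frame placement of IVUS cross-sections, catheter twist and
    carina-reference corrections, virtual catheter path outlier repair,
    contour lofting into watertight meshes, signed-distance branch union,
    mapping-back quality control and refinement, geometric validation metrics
    (serial cross-sections, equivalent diameter, maximum chord and
    perpendicular width, z-score normalization, linear regression and
    Bland-Altman agreement), and a synthetic bifurcation phantom simulator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    digest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
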