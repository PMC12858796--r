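Package: mirrorwell
Title: Dual Orthogonal-View 3D Behavioral Analysis of Zebrafish Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for dual orthogonal-view (top plus
    45-degree-mirror side view) 3D behavioral analysis of zebrafish larvae
    in mirrored multi-well plates. Provides the plate/camera geometric
    model with thin-lens pixel-to-millimetre conversion, a refractive
    ray-tracing distortion model (Snell's law through air, plastic and
    water) and slanted-edge MTF resolution estimation, keypoint quality
    control and fusion of two 2D skeleton views into 3D skeletons,
    2D/3D locomotor kinematics (speed, acceleration, travel distance,
    tail angle, bout counting, occupancy and depth profiles), swim-bladder
    ellipsoid reconstruction from two projected ellipses with
    height-corrected volume, and a synthetic dual-view larva simulator
    used as the test bed for the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
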