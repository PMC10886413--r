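Package: skate3d
Title: Markerless 3D Motion Capture Pipeline for Treadmill Skate Skiing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A two-camera markerless motion-capture pipeline for skate
    skiing on a treadmill, together with the marker-based reference
    computation and the agreement statistics used to validate it.
    Implements 11-parameter direct linear transformation (DLT) camera
    calibration and multi-view triangulation, zero-phase Butterworth
    filtering, pole-strike event detection and cycle segmentation with
    time normalization, joint-center and joint-vector-angle kinematics,
    and Bland-Altman / RMSE / Pearson / ICC(A,1) method-agreement
    reports.  A deterministic synthetic skier simulator provides
    ground-truth kinematics, camera projections and marker-based
    counterparts so every pipeline stage can be checked against an
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
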