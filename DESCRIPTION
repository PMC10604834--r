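Package: hypocom
Title: Seated Whole-Body Center of Mass from Markerless Motion Capture
    under Simulated Hypogravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the whole-body center of mass (CoM) of seated
    subjects from multi-camera markerless keypoints, and for designing underwater
    hypogravity simulations. Includes sex-specific body-segment parameter tables
    (Plagenhoef water-immersion statistics), the segmental weighted-sum CoM
    estimator over the 25-keypoint skeleton, pinhole camera models with
    confidence-weighted DLT triangulation of OpenPose-format JSON, PCK pose
    quality evaluation, buoyancy-compensating ballast design for simulated lunar
    gravity (Archimedes force balance), endurance-time windowed trial summaries,
    per-sex ordinary least-squares analysis of pelvis-relative CoM displacement
    on gravity level and task, and a fully deterministic synthetic-study
    generator that renders 3D seated-task kinematics into noisy multi-camera 2D
    keypoint JSON so every pipeline stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
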