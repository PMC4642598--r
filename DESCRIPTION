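Package: vesselreg
Title: Vessel-Based Rigid Registration of Tracked 2D Ultrasound to
    Preoperative Centre-Line Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments vessel centre points from tracked 2D B-mode
    ultrasound frames (Hessian vesselness enhancement combined with an
    intensity-dip detector along the beam direction, contour extraction,
    ellipse fitting with geometric outlier rejection), reconstructs them
    into a 3D point cloud via the probe calibration and tracking poses,
    and rigidly registers a preoperative vessel centre-line graph to the
    cloud using landmark/vector initialisation followed by point-to-line
    iterative closest point. Includes target registration error
    evaluation with distance-stratified summaries and a synthetic tube
    phantom simulator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
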