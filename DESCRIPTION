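Package: foxwatch
Title: Activity Monitoring of Captive Animals from Camera Bounding-Box Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-frame bounding-box detections of a single captive
    animal, observed by two fixed cameras, into movement time series, fused
    activity classifications, residence heat maps and 24-hour activity
    overviews. Includes the standard detector-evaluation metrics (IoU,
    precision, recall, 11-point interpolated average precision, mAP),
    readers and writers for the YOLO/LabelImg annotation dialect, stratified
    dataset splitting, Darknet configuration arithmetic, and a ground-truthed
    cage simulator that emulates a state-switching animal seen by two cameras
    with blind spots, an interval motion detector and periodic manual spot
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
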