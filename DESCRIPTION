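Package: droneval
Title: Detection-Reliability Evaluation for Drone-Based Marine Fauna Surveys
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the reliability of automated animal
    detections in frame-synchronised multi-camera drone video. Matches
    model-generated bounding boxes to manually annotated ground-truth tracks
    by intersection-over-union (IoU) thresholding, tallies true positives,
    false positives and false negatives per flight and camera treatment, and
    reports precision, recall and F1. Includes keyframe track interpolation,
    temporal clipping, a central-frame region filter, event-anchor frame
    synchronisation across cameras, and a synthetic-scene simulator that
    emulates surfacing-and-diving dolphins under depth-dependent,
    treatment-specific detectability so the full pipeline can be exercised
    without raw footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
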