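Package: lesionprep
Title: Dataset Preparation and Patient-Wise Evaluation for MRI Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing breast DCE-MRI lesion-detection datasets and
    evaluating detectors patient-wise. Implements logarithmic funneling slice
    selection that trims loose-bounding-box edge slices from annotated tumor
    slice ranges, image and bounding-box rescaling with per-slice Pascal VOC
    annotation export, patient-wise train/test splitting and k-fold
    cross-validation planning with a remainder-to-train rule, patient-wise
    detection metrics (accuracy, IoU and score averages, false-negative slice
    counts) with cross-fold aggregation, deterministic training-schedule
    arithmetic (epochs, cosine learning-rate decay, uniform weight
    initialization, augmentation), and a synthetic phantom cohort generator
    with a configurable synthetic detector so the full pipeline runs
    end-to-end without any clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
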