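Package: lidmorph
Title: Periocular Morphometry and Rule-Based Eyelid Disorder Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A testable re-implementation of an anatomy-driven eyelid disorder
    screening pipeline. A seeded parametric generator renders periocular scenes
    (lid margins, cornea, canthal folds, lesions, and a 10-mm fiducial marker)
    with exact analytic ground truth; a pluggable segmenter, anatomical region
    decomposition, fiducial scale calibration, and eight calibrated
    morphological parameters (MRD1, MRD2, palpebral fissure, corneal, lateral
    and medial areas, upper and lower eyelid lengths) feed threshold- and
    texture-based abnormality detectors; a declarative morphological-atlas rule
    engine composes single-disease and multimorbidity diagnoses, evaluated per
    eye with multi-label accuracy, sensitivity, specificity, F1, and AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
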