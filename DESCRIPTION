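Package: trajcast
Title: Multimodal Transformer Forecasting of Ordinal Disease-Severity
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts an ordinal disease-severity trajectory (baseline
    diagnosis plus T future time points) from a baseline medical image and
    scalar clinical variables, using a clinically-inspired multi-agent
    transformer: a radiologist block over imaging tokens, a context block
    over clinical-variable tokens, and a general-practitioner block that
    fuses both to emit one severity prediction per horizon.  Training uses
    a calibrated upper-bound loss on temperature-scaled cross-entropy with
    per-task learnable inverse temperatures, a masked prognosis loss for
    missing follow-up labels, and an L1 consistency term between the
    radiologist's and practitioner's baseline-diagnosis logits.  Includes
    a synthetic longitudinal cohort generator whose images geometrically
    encode severity, calibration-aware evaluation (balanced accuracy,
    expected calibration error, one-vs-one multiclass AUROC), and
    attention-map extraction for interpretability.  All network machinery
    (reverse-mode automatic differentiation, convolutional backbones,
    transformer encoders) is implemented in base R matrix code so the
    whole pipeline runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    png,
    RNifti,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
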