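Package: mtbench
Title: Validation of Massive-Transfusion Prediction Scores in Trauma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements six early massive-transfusion (MT) risk scores for severe
    trauma (TASH, PWH/Rainer, Vandromme, ABC, Schreiber, Larson) as declarative
    banded point tables evaluated by a single engine, together with the receiver
    operating characteristic (ROC) validation machinery used to compare them:
    concordance AUC, Hanley-McNeil, DeLong and bootstrap confidence intervals,
    Youden-index cut-off selection, sensitivity/specificity/PPV/NPV at fixed or
    data-driven cut-offs, and a confidence-interval-based test for the difference
    of two AUCs. A synthetic trauma-registry cohort generator with a latent
    severity factor, calibrated MT prevalence and registry-style marginals makes
    the full pipeline testable without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
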