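Package: tavicap
Title: Mechanistic and Machine-Learning Prediction of Conduction
    Abnormalities after Transcatheter Aortic Valve Implantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting new conduction
    abnormalities (CA) after transcatheter aortic valve implantation
    (TAVI). Combines a parametric aortic-root/membranous-septum geometry
    model, a simplified radial-spring valve-deployment model producing
    contact-pressure biomarkers (Cpmax, CPI) over the conduction-system
    region of interest, a calibrated synthetic cohort generator emulating
    published group-conditional feature distributions, an ensemble
    machine-learning protocol (eight base classifiers, bagging and voting
    ensembles, accuracy-based selection), and the descriptive and
    inferential statistics layer for cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Rcpp,
    e1071,
    rpart,
    ranger,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
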