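Package: glucopred
Title: Mid-Term Post-Meal Blood Glucose Prediction from Dietary and Insulin Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the 60 to 180 minute post-meal blood glucose trajectory of
    insulin-dependent patients from lifestyle logs (meal composition, bolus and
    basal insulin events, baseline fingertip glucose) and continuous glucose
    monitor (CGM) series sampled every 2 minutes. A two-compartment stomach-gut
    absorption model turns each meal's nutrient composition into a glucose
    infusion rate curve; dynamics parameters of that curve (time to peak, time
    to half peak, maximal rate, area under the curve) together with insulin
    dosing and timing feed a small feed-forward neural network trained with a
    quasi-Newton regime that regresses the full CGM trajectory at 2 minute
    resolution. Includes per-patient training and evaluation pipelines
    (chronological splits, threefold cross-validation, paired t-tests, windowed
    RMSE/MAE), a hybrid short/mid-term predictor, and a virtual-patient
    simulator that generates complete synthetic cohorts with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
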