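Package: tnmbn
Title: Probabilistic TNM Edition Reclassification and Survival Prediction
    with Discrete Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing non-small-cell lung cancer TNM staging
    across classification editions 5, 6 and 7 using a ten-node discrete
    Bayesian network with hidden 7th-edition descriptor nodes. Conditional
    probability tables are primed from declarative cross-edition priors and
    fitted by expectation-maximization on registry-style records that never
    carry paired-edition labels. Includes exact posterior inference with an
    enumeration oracle, a rule-based 7th-to-6th edition reclassifier with
    ambiguity ranges, a synthetic cancer-registry simulator with
    right-censored survival, and an evaluation suite (multiclass
    macro/micro metrics, worst-case ambiguity adjustment, ROC-AUC,
    probability calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
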