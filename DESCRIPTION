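Package: laryngobn
Title: Bayesian Network Treatment Decision Support for Laryngeal Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian-network engine and a packaged treatment-decision
    model for primary laryngeal carcinoma. Treatment recommendations (larynx
    surgery, radiotherapy, radiochemotherapy, chemotherapy, immunotherapy) are
    inferred from TNM staging and chemotherapy tolerance by exact variable
    elimination; conditional probability tables are compiled from declarative
    guideline-style rule sets. Includes the validation workflow used for
    clinical decision-support models (accuracy, F1, ROC/AUC, precision-recall,
    k-fold cross-validation with Dirichlet/EM parameter learning) and a
    synthetic tumor-board cohort simulator with CSV case-file input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
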