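Package: gliobayes
Title: Hybrid Bayesian Networks for Multimodal MRI Glioma Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading cerebral gliomas from multimodal magnetic
    resonance imaging features with conditional linear Gaussian (CLG)
    Bayesian networks. Provides a synthetic cohort generator emulating a
    published 56-patient feature table with modality-level block
    missingness, Kruskal-Wallis feature screening, maximum-likelihood
    parameter estimation, exact posterior inference of tumor grade under
    partially missing modalities, K2 greedy structure learning with a BIC
    score, two-part network composition, leave-one-out cross-validation,
    and ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
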