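Package: radresponse
Title: Cancer Disease Response Classification from Radiology Report Conclusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers four-class cancer disease response (no evidence of disease,
    partial response, stable disease, progressive disease) from the free-text
    conclusion section of radiology reports. Provides a labeled-corpus data model
    with patient-level splitting, a synthetic radiology-conclusion generator with a
    rule-based label oracle, sentence-permutation data augmentation with a
    consistency-loss training objective, TF-IDF classical baselines (linear
    max-margin, logistic regression, gradient-boosted trees, soft-voting ensemble),
    small neural sequence classifiers (transformer, Bi-LSTM, CNN) trained with or
    without consistency regularization, cloze-prompt few-shot fine-tuning of a
    masked language model with a verbalizer, and an evaluation harness (micro/macro
    F1, confusion matrices, multi-seed aggregation, paired t-tests, learning
    curves, Cohen's kappa, Spearman's rho, and token-saliency rendering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    e1071,
    glmnet,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
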