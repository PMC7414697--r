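Package: ordsmooth
Title: Non-Uniform Label Smoothing and Ordinal Evaluation for Disease Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs hard, uniformly smoothed and non-uniformly (Gaussian)
    smoothed soft labels for ordinal disease grades such as diabetic
    retinopathy stages, together with the ordinal evaluation protocol that
    goes with them: soft-target cross-entropy, quadratic-weighted kappa,
    pairwise-averaged multiclass AUROC, support-weighted precision, recall
    and F1, multiclass Matthews correlation, and paired stratified-bootstrap
    model comparison with Bonferroni-corrected decisions. Includes a
    synthetic ordinal fundus-grading data generator with neighbor-biased
    annotator noise, a small trainable classifier harness, and a
    command-line interface for end-to-end experiments.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
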