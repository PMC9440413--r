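Package: maskdoor
Title: Mask-Based Backdoor Attacks on Clinical Time-Series Mortality Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Research workbench for studying backdoor data-poisoning attacks
    that use missing-value masks as triggers in ICU mortality prediction.
    Provides a synthetic generator of irregular 48-hour, 17-channel ICU
    episodes; discretization, imputation and mask extraction (plus the exact
    inverse, so trigger episodes survive re-preprocessing bit-for-bit); random
    and variational-autoencoder trigger-mask generators; random and targeted
    label-flip poisoning under false-alarm and missing-detection scenarios;
    four victim classifiers (logistic regression, multilayer perceptron, LSTM,
    GRU) trained on value-and-mask inputs; and evaluation tools: area under
    the precision-recall curve with its prevalence baseline, attack success
    rate, calibration curves, cosine-similarity heat maps and percentile
    detection ratios, with multi-trial campaign orchestration and 95%
    confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
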