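Package: valuecode
Title: Behavioral Value Models and Neural Value-Coding Analyses for
    Probabilistic Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how reinforcement shapes choice and striatal
    activity in a two-alternative probabilistic reversal learning task. The
    package simulates the task (70%/10% reward blocks with a debiasing rule),
    implements four trial-by-trial learning models (two extended Q-learning
    variants, REINFORCE, and an actor-critic) with maximum a posteriori and
    hierarchical Bayesian fitting, parameter-recovery and model-confusion
    diagnostics, and a conditioned-reinforcer value (kappa) re-fit. On the
    neural side it provides a bilinear spike-train encoding model (raised
    cosine event kernels multiplicatively scaled by trial-by-trial values),
    circular-shift and pseudosession null distributions for calibrated
    significance, time-resolved population decoding with nested stratified
    cross-validation, and generators for synthetic spike trains and wheel
    traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
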