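Package: seqelim
Title: Sequential Multi-Arm Elimination Trials with Triangular Boundaries
    and Rao-Blackwell Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and post-trial analysis of group-sequential
    trials with binary outcomes in which several treatments are compared
    pairwise at interim analyses and inferior arms are eliminated. Decision
    rules are straight-line (triangular and double-triangular) boundaries in
    the (V, Z) plane of the efficient score and Fisher information for a
    log-odds ratio. Post-trial estimation corrects the selection bias induced
    by sequential stopping: a naive unadjusted estimate, an analytic
    Rao-Blackwell estimate for two-arm trials based on recursive numerical
    integration of group-sequential stopping distributions, and a
    reverse-simulation Rao-Blackwell estimate applicable to multi-arm
    elimination trials, in which earlier interim analyses are reconstructed
    from the terminal sufficient statistics by hypergeometric back-sampling
    and paths inconsistent with the observed stopping pattern are discarded.
    Monte Carlo evaluation of design operating characteristics and estimator
    sampling properties is included, together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
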