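Package: ascoh
Title: Coherence Analysis of Arterial-Stiffness Time Series for
    Spinal-Hypotension Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict post-spinal hypotension severity from
    pre-induction beat-by-beat arterial-stiffness (AS) recordings.
    Non-uniform beat series are spline-resampled to a uniform 10 Hz grid,
    summarised by normalized autocorrelation spectra, and reduced to an
    absolute-area coherence statistic that is assessed against cumulative
    phenylephrine dosage via ROC/Youden analysis.  A from-scratch
    feed-forward neural network with the matching multi-run training
    protocol (random splits, early stopping, run ensembles, node/layer
    sweeps) provides the complementary black-box classifier, and a
    synthetic-cohort generator emulates the statistical structure of the
    clinical recordings for truth-known evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
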