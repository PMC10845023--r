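Package: breathloop
Title: Closed-Loop Adaptive Breath Training, Interoceptive Assessment, and
    Alpha-Band EEG Network Analysis for Digital Mindfulness Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing a digital mindfulness and
    compassion training trial built around closed-loop, performance-adaptive
    attention-to-breath practice. Provides the deterministic adaptive training
    engine (level progression gated by tap-consistency, chime feedback, staged
    compassion prompts), a median/MAD response-time classifier for the
    eyes-closed interoceptive breath-monitoring assessment, an alpha-band
    (8-12 Hz) EEG pipeline with minimum-norm source projection and
    network-level (FPN/CON/DMN) activity contrasts, the trial's inferential
    statistics (pooled-SD Cohen d, normality-gated paired tests, Cronbach
    alpha, Spearman and partial Spearman correlations, two-by-two mixed
    ANOVA), and a synthetic cohort generator with configurable ground-truth
    effects so the full pipeline can be exercised and validated end to end
    without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
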