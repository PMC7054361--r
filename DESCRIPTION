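Package: turnbias
Title: Individual Motor Bias Statistics for Larval Zebrafish Behavior and
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies individual left/right motor bias in
    larval zebrafish. Implements turn-bias metrics (net turn angle, Match
    Index, percent rightward turns) with the standard trial-exclusion rules,
    a Markov-chain Monte-Carlo null model for turn-direction bias driven by
    a sequential-persistence ("lock index") parameter, a one-sample
    permutation test of the Match Index against 0.5, baseline-noise-scaled
    classification of calcium-imaging light-ON/OFF responders from delta-F/F
    traces, and the effect-size measures (Cohen's d, rank-biserial r,
    partial eta squared) reported alongside standard group tests. A seeded
    synthetic-data generator produces turn-event cohorts, heading time
    series, and fluorescence traces with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
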