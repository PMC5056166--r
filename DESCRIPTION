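Package: pranr
Title: Lexical Competition and Pre-Activation Negativity (PrAN) Analysis for ERP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes word-initial-fragment (WIF) lexical-competition scores
    from a pronunciation lexicon and a corpus frequency list, reduces
    event-related-potential (EEG) epochs to windowed region-of-interest mean
    amplitudes, and runs the statistical analyses used in studies of the
    pre-activation negativity (PrAN): median-split repeated-measures ANOVA
    with topographic factors and standardized regressions of windowed ERP
    amplitude on log lexical competition with one-tailed directional tests.
    Includes synthetic lexicon and EEG generators with recorded ground truth
    so the full pipeline can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
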