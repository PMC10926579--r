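Package: egfrparse
Title: Rule-Based Extraction of EGFR Mutation Test Results from Free-Text
    Laboratory Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, rule-based text-analysis framework for turning
    free-text molecular pathology reports into structured EGFR
    (epidermal growth factor receptor) mutation test results. The
    framework converts Rich Text Format report bodies to plain text,
    normalizes and splits reports into named sections, tokenizes result
    sentences against a small clinical lexicon, parses the token
    sequence with a context-free grammar of result-sentence forms, and
    maps the parse tree to a structured record of test status and
    per-location mutation calls (exon 19 deletions, exon 20 insertions,
    T790M, L858R, L861Q, G719X, S768I). Includes a batch pipeline for
    delimited laboratory exports, an evaluation module (confusion
    matrix, accuracy, sensitivity, specificity), and a seeded synthetic
    report generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
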