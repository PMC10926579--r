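# Shared fixture builders for the test suite. Everything is constructed in
# code; the only checked-in fixture is the RTF document under fixtures/.

fixture_rtf <- function() {
  paste(readLines(test_path("fixtures", "report.rtf"), warn = FALSE,
                  encoding = "UTF-8"),
        collapse = "\n")
}

# Expected plain text of fixtures/report.rtf, derived by hand from RTF
# semantics: control words and destination groups drop, \par becomes a
# newline, \'e9 is Windows-1252 e-acute, and the unicode escape for
# code point 8805 (the >= sign) keeps its one fallback character (uc1)
# swallowed.
fixture_rtf_expected <- function() {
  paste0("Specimen: left lung biopsy\n",
         "Interpretation and Comments:\n",
         "The specimen was tested for EGFR mutations.\n",
         "Résumé of assay: see below.\n",
         "EGFR Mutation Assay:\n",
         "The deletions in Exon 19 was identified.\n",
         "Note:\n",
         "Assay sensitivity ≥5%.\n",
         "Comment:\n",
         "None.\n")
}

# A SAD-style report body around a given result sentence.
sad_report <- function(sentence, comment = "None.") {
  paste("Interpretation and Comments:",
        "Testing performed by real-time PCR.",
        "EGFR Mutation Assay:",
        sentence,
        "Note:",
        "This assay screens hotspot mutations in the EGFR gene.",
        "Comment:",
        comment,
        sep = "\n")
}

# Extract straight from a sentence through the SAD section layout.
extract_sentence <- function(sentence, grammar = egfr_grammar(),
                             lexicon = egfr_lexicon(),
                             dialect = dialect_sad()) {
  sr <- split_sections(normalize_text(sad_report(sentence)), dialect$headers)
  extract_result(sr, lexicon, grammar, dialect)
}

# One-row SAD table around a sentence, optionally RTF-wrapped.
sad_table <- function(sentence, rtf = TRUE, id = "SAD-000001",
                      uli = "000000001") {
  body <- sad_report(sentence)
  if (rtf) body <- rtf_wrap(body)
  tibble::tibble(RESULT_ID = id, ULI = uli,
                 SPECIMEN_ACCN = "S19-00001",
                 SPECIMEN_SOURCE = "lung, right upper lobe",
                 TEST_NAME = "EGFR Result",
                 TEST_TASK = "EGFR (Interpretation)",
                 RTF_RESULT = body,
                 RESULT_SHORT = "See report")
}

# Sorted comparable view of long-format records for round-trip checks.
roundtrip_view <- function(records) {
  d <- as.data.frame(records[c("result_id", "status", "location", "specific")])
  d <- d[order(d$result_id, d$location), , drop = FALSE]
  rownames(d) <- NULL
  d
}
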