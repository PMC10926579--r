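# Dataset dialect presets: how each laboratory export stores its reports.
keyword: egfr
dialects:
  sad:
    name: sad
    id_column: RESULT_ID
    patient_column: ULI
    body_column: RTF_RESULT
    body_is_rtf: true
    filter_columns: [SPECIMEN_ACCN, SPECIMEN_SOURCE, TEST_NAME, TEST_TASK, RTF_RESULT]
    headers:
      - "interpretation and comments:"
      - "egfr mutation assay:"
      - "note:"
      - "comment:"
    result_section_priority:
      - "egfr mutation assay:"
      - "interpretation and comments:"
    # Specific filter values seen in this dialect (documentation; the generic
    # keyword filter subsumes them):
    #   TEST_NAME contains "EGFR Result"
    #   TEST_TASK contains "EGFR (Interpretation)" or "EGFR (Qualitative)"
  nad:
    name: nad
    id_column: RESULT_ID
    patient_column: ULI
    body_column: RESULTS
    body_is_rtf: false
    filter_columns: [RESULTS]
    headers:
      - "result:"
    result_section_priority:
      - "result:"
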