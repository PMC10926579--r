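# egfrparse

Rule-based extraction of structured EGFR mutation test results from
free-text molecular pathology reports.

## The problem

Activating mutations in the epidermal growth factor receptor (*EGFR*) gene
predict response to tyrosine kinase inhibitors in non-small cell lung
cancer, so knowing each patient's test result matters for outcomes research.
In many laboratory repositories, however, the result exists only as free
text inside a report — often wrapped in Rich Text Format markup — rather
than as a coded field. `egfrparse` is for researchers and data engineers who
need to turn such laboratory exports into analyzable records: one test
status per result (`identified`, `not_detected`, `insufficient_dna`,
`cancelled`, or `unparseable` for manual review) and, for positive tests,
one call per mutation location (exon 19 deletions, exon 20 insertions,
T790M, L858R, L861Q, G719X, S768I).

Because result sentences in these reports are short and highly regular,
extraction is fully deterministic — no statistical model, no training data.

## The method

The framework is a two-stage compiler front end applied to clinical text.

**Lexical analysis.** RTF bodies are converted to plain text; text is
normalized (lowercase, trimmed, whitespace collapsed); the report is split
into its named sections (`"Interpretation and Comments:"`,
`"EGFR Mutation Assay:"`, `"Note:"`, `"Comment:"` in the southern export
dialect; `"Result:"` in the northern one) by exact header matching at line
starts; and the result sentence is tokenized against a small lexicon by
longest-match scanning, mapping key words to symbols
(`"exon 19"` → `exon_19_location`, `"deletions"` →
`deletion_specific_result`, `"identified"`/`"positive"` →
`identified_result`, ...) while ignoring intermediary English words.

**Syntax analysis.** Tokenized sentences are parsed with a context-free
grammar G = (V, Σ, R, S), with variables
V = {S, Location, Result, Conjunction, Specific_Result} and productions

```
S               -> Location Result | Location Conjunction S | S Conjunction Location
Location        -> Location Specific_Result | Specific_Result Location | <location terminal>
Conjunction     -> 'and' | ','
Result          -> Identified | Not Detected
Specific_Result -> Deletion | Insertion | epsilon
```

plus status productions for insufficient-DNA and cancelled-test sentences
(the packaged grammar ships with and without these extensions; disabling
them reproduces the failure mode in which cancelled tests cannot be
extracted). The grammar is left-recursive and ambiguous, so parsing uses an
Earley chart parser, which terminates on every input; the terminals on the
leaves of the canonical parse tree *are* the test result, and a tree walk
yields the status and the (location, specific) pairs.

The package also provides the batch pipeline (dialect-aware filtering,
extraction, de-duplication, summary counts), the validation protocol
(seeded simple random sampling, actual-vs-predicted confusion matrix,
accuracy / sensitivity / specificity), and a seeded synthetic report
generator with ground truth, since the real laboratory exports are not
publicly available.

## Worked example

```r
library(egfrparse)

body <- paste(
  "Interpretation and Comments:",
  "Testing performed by real-time PCR.",
  "EGFR Mutation Assay:",
  "The deletions in Exon 19 and T790M were identified.",
  "Note:", "Hotspot screen.", "Comment:", "None.", sep = "\n")

text   <- rtf_to_text(rtf_wrap(body))$text          # strip the RTF envelope
report <- split_sections(normalize_text(text), dialect_sad()$headers)
toks   <- tokenize(report$sections[["egfr mutation assay:"]], egfr_lexicon())
toks$symbol
#> [1] "deletion_specific_result" "exon_19_location" "conjunction"
#> [4] "t790m_location"           "identified_result"

parse_tokens(toks$symbol, egfr_grammar())
#> <cfg_parse> accepted: deletion_specific_result exon_19_location conjunction t790m_location identified_result
#> S
#>   Location
#>     Specific_Result
#>       'deletion_specific_result'
#>     Location
#>       'exon_19_location'
#>   Conjunction
#>     'conjunction'
#>   S
#>     Location
#>       't790m_location'
#>     Result
#>       'identified_result'

res <- extract_result(report, egfr_lexicon(), egfr_grammar(), dialect_sad())
res
#> <egfr_result> identified  [egfr mutation assay:]
#>   - exon19 (deletion)
#>   - T790M

result_to_records(res, list(result_id = "SAD-000001", patient_id = "000000001"))
#> # A tibble: 2 × 6
#>   result_id  patient_id status     location specific source_section
#>   <chr>      <chr>      <chr>      <chr>    <chr>    <chr>
#> 1 SAD-000001 000000001  identified exon19   deletion egfr mutation assay:
#> 2 SAD-000001 000000001  identified T790M    none     egfr mutation assay:
```

The sentence parses as S → Location Conjunction S: the deletion binds to
exon 19 inside its Location phrase and never crosses the conjunction, so
T790M carries no specific result. For whole tables, `filter_records()` +
`run_extraction()` do the same per row and return the long-format records, a
summary (status counts, per-location counts, multi-location distribution,
location-pair combinations), and a reject list of unparseable rows for
manual review. A command-line front end over the same functions is installed
at `inst/cli/egfrparse.R` (`generate`, `extract`, `summarize`, `sample`,
`evaluate`).

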