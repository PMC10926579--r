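---
title: "Deterministic extraction of EGFR test results: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic extraction of EGFR test results: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrparse)
```

## The extraction model

`egfrparse` treats a molecular pathology report the way a compiler treats a
source file. The pipeline is a fixed sequence of deterministic stages:

1. **RTF stripping** (`rtf_to_text()`): report bodies stored as Rich Text
   Format are reduced to plain text. Stripping is deliberately lossy — all
   formatting control words are dropped, destination groups (font table,
   color table, stylesheet, document info, embedded pictures, and any
   group opened with the ignorable marker `\*`) are skipped wholesale, and
   `\par`/`\line` become newlines. Hex escapes decode as Windows-1252, the
   dominant encoding of clinical RTF exports; the encoding and the
   destination list are arguments for exports that differ.
2. **Normalization** (`normalize_text()`): lowercase, trim, collapse
   whitespace runs. Newlines survive so that section headers remain
   anchored at line starts. The function is idempotent.
3. **Section splitting** (`split_sections()`): an exact, case-insensitive
   match of a header label at the start of a line opens a section. Line-start
   anchoring is a design choice: the header strings can occur inside
   narrative sentences ("see EGFR Mutation Assay below"), and anchoring
   prevents those false hits. Duplicate headers get suffixed keys; text
   before the first header is kept as residual rather than dropped.
4. **Tokenization** (`tokenize()`): a longest-match, left-to-right scan
   against a small lexicon maps key words to symbols in five categories
   (location, result, specific result, conjunction, status). Longest-match
   is the only deterministic policy compatible with multi-word keys:
   "exon 19" must never tokenize as a bare "exon", and the status phrase
   "test cancelled due to insufficient dna" must beat its own
   "insufficient dna" substring. Words that match nothing are ignored —
   the grammar below never sees them. Inflections are handled by
   enumerating surface variants ("deletion", "deletions", "del") rather
   than stemming: the vocabulary is tiny and enumeration is auditable.
5. **Parsing** (`parse_tokens()`): the token sequence is tested against a
   context-free grammar of result-sentence forms and, on acceptance, the
   canonical parse tree is walked to produce the structured result.

The grammar's language is intentionally narrow. A result sentence is one or
more Location phrases joined by conjunctions and closed by a single result
word, a bare "not detected", or a status sentence (insufficient DNA /
cancelled). A Location phrase is a location terminal with an optional
specific result (deletion/insertion) attached on either side. Two
consequences are worth making explicit:

* a specific result always binds to the location inside its own phrase; it
  cannot cross a conjunction, which matches how the reports attach
  "deletions" to exon 19 and "insertions" to exon 20;
* mixed-polarity sentences ("X identified and Y not detected") are not in
  the language. They surface as `unparseable` and land in the reject list
  for manual review — the safe behavior, since the correct reading cannot
  be decided by this grammar.

### Parsing algorithm and canonical derivation

The grammar is left-recursive (`S -> S Conjunction Location`) and ambiguous,
so recursive descent is unusable. `parse_tokens()` is an Earley chart
parser with the nullable-prediction completion fix, which terminates on
every input and handles ε-productions (`Specific_Result -> EPSILON`).
Ambiguity is resolved reproducibly: the canonical tree is built over the
chart by trying rules in file order (lowest rule index first) and splitting
each right-hand side leftmost-first with shortest spans first. Extraction
is additionally required to be derivation-invariant — every parse tree of
an ambiguous sentence must yield the same status and the same
(location, specific) pairs — and the test suite checks this by exhaustive
derivation enumeration on all in-language strings of up to 4 tokens.

Same-(variable, span) recursion during tree building, which arises only
through ε-padding derivations, is cut by a path guard; a minimal derivation
never needs such a cycle, so the guard cannot lose a parseable input.
Rejections record the 0-based index of the first token at which no partial
derivation survives.

### Status extensions

The base sentence forms cover detected and not-detected results. Real
corpora also contain "there was insufficient DNA for the test" and
"test cancelled (due to insufficient DNA)" results; the packaged grammar
includes productions for both (`egfr_grammar(extensions = TRUE)`, the
default). Loading `extensions = FALSE` gives the core grammar without
them, which is kept for regression testing: on a corpus containing
cancelled tests the core grammar fails exactly those records, and enabling
the extension restores full status accuracy. One deliberate deviation from
an obvious alternative: the status-only production is
`S -> 'not_detected_result'` rather than `S -> Result`, because the latter
would also accept a bare "identified" — a result claiming a mutation with
no location, which violates the record invariant that identified results
carry at least one mutation call. Rejecting it at the grammar level keeps
the invariant out of patch-up code.

### The wildcard alternative

The engine supports an `ANY` element in grammar files — a terminal slot
matching any single token — for grammar variants that want an arbitrary
unrecognized-modifier position adjacent to a location. The packaged
grammars do not use it: the tokenizer already drops unknown words, so the
slot is unreachable in the default configuration.

## Extraction semantics

`extract_result()` chooses the result section by dialect priority
(southern: the assay section, falling back to interpretation-and-comments;
northern: the result section; the residual text when no header matched),
splits it into sentences at periods and newlines, and takes the **first
parseable sentence** — the simplest auditable rule when several candidate
sentences exist. Repeated mentions of one location collapse to a single
call, keeping a non-none specific over none: results are counted per
location, not per mention. Every input row yields exactly one result;
failures become `unparseable` records with the raw sentence retained, never
exceptions.

The note/comment sections are never analyzed: they carry clinician
commentary (e.g. low tumor cellularity) that does not change the extracted
result, and a test asserts extraction is invariant to comment content.
Samples whose comment made the result non-definitive are therefore
extracted as their sentence states (typically "Not Detected"), and the
evaluation's correctness rule scores them accordingly.

## Evaluation protocol

`draw_sample()` is a seeded uniform simple random sample without
replacement (returned in original order, as a reviewer would process
records). `build_confusion()` tallies a 4×4 actual-by-predicted matrix over
the classes detected / not_detected / inconclusive / not_tested, with
extraction statuses mapped by `status_to_class()`. `compute_metrics()`
scores three cells as correct — detected→detected,
not_detected→not_detected, and inconclusive→not_detected — and reports
accuracy, sensitivity (over actual detected) and specificity (over actual
not detected); zero denominators give `NA`, never 0. When full per-sample
predictions exist, a logical `correct` vector can replace the matrix-cell
rule, enabling the stricter criterion that a detected sample must also
carry the right location set — the matrix alone cannot express location
agreement. `location_metrics()` adds a supplementary per-location
precision/recall table; it is not part of the headline accuracy.

## What the synthetic generator emulates — and what it does not

The real southern/northern laboratory exports are governed by health-data
privacy law and are not available, so `generate_corpus()` builds corpora
with known ground truth. Choices, made once:

* **Status mix default** (74% not detected, 18% identified at one
  location, 6% at several, 1% insufficient DNA, 1% cancelled)
  approximates the proportions reported for the southern export, so
  summary shapes are comparable; the corpus does not claim to reproduce
  the real counts.
* **Location weights** follow the reported per-location tallies (exon 19
  deletions most common, then L858R, G719X, T790M, S768I, L861Q, exon 20
  insertions), and the 2/3/4-location split of multi-location results
  follows the reported ratios.
* **Templates** render the four general result forms with word-order
  permutations, optional filler words, both specific-result attachment
  orders, "and"/comma conjunction mixes, and synonym phrasings
  ("positive"/"negative") at a configurable rate — deliberately richer
  than the grammar's language so the ignore-unknown-words behavior is
  exercised. Out-of-grammar noise templates (tagged at design time) are
  injected at `noise_rate` and are ground-truthed `unparseable`.
* Reports carry the full dialect structure (all four southern headers, RTF
  envelope by default for the southern dialect; northern "Result:") plus
  occasional low-cellularity comments that must not affect extraction.
* Everything derives from one integer seed; the same configuration gives a
  byte-identical corpus.

What passing round-trip tests on this corpus shows is that every stage
composes correctly on sentence forms the grammar was designed for, under
realistic report packaging. What it cannot show is coverage of real-world
phrasing diversity: the template inventory is a surrogate built from the
documented result taxonomy and one published worked sentence. On real
exports, unseen sentence forms would surface as `unparseable` records in
the reject file — the intended failure mode — and would require new lexicon
entries or grammar rules.

## Numerical and degenerate-input choices

* Token spans are 0-based half-open; purely an internal convention,
  declared so tests are reproducible.
* Probability vectors in `generator_config()` must sum to 1 within 1e-9.
* Empty input text tokenizes to zero tokens; a report with no recognized
  section and no residual yields `unparseable` with reason
  "no result section"; an empty table flows through the pipeline to empty
  records and an all-zero summary.
* A lexicon token the grammar has no terminal for (possible under the core
  grammar) marks the sentence unparseable rather than raising — outside a
  wildcard grammar there is no derivation to find.
* Unbalanced RTF braces and truncated escapes are recoverable: best-effort
  text plus a problem flag on the record.
* Duplicate result identifiers merge by unioning location records;
  conflicting statuses keep the first and are flagged as a data-quality
  warning.

## Validation problem sizes

The shipped suite checks parser acceptance against brute-force derivation
enumeration for **all** token strings of length ≤ 4 over the full terminal
alphabet (41,370 sequences), derivation invariance of extraction over every
in-language string of length ≤ 4, and round-trip recovery on seeded
1000-report corpora per dialect; the acceptance script re-runs the
validation protocol on an 8,900-report synthetic corpus with a 362-record
sample, mirroring the published study dimensions. These sizes were chosen
as the smallest that exercise every rule of the grammar and every status
class with comfortable margins.

## Known limitations

* The lexicon's negation vocabulary is exactly "negative"/"not detected";
  there is no general negation-scope handling (no NegEx), no
  spell-checking, and no morphological analysis beyond enumerated
  variants.
* Mixed-polarity sentences are unrepresentable by design and require
  manual review.
* "S78I" is treated as an alias of S768I (a documented typo in the
  location list); if real data ever shows a genuine S78I variant this
  must be revisited.
* Variant nomenclature is not normalized to HGVS, and clinician
  commentary is not interpreted.
* Registry linkage (matching extracted results to a cancer registry
  cohort) is out of scope; an optional patient-identifier allowlist can
  stand in for cohort restriction.
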