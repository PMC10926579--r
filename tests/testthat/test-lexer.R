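lex <- egfr_lexicon()

test_that("normalization lowercases, trims and collapses whitespace", {
  expect_identical(normalize_text("  Exon 19  "), "exon 19")
  expect_identical(normalize_text("NOT   DETECTED"), "not detected")
  expect_identical(normalize_text(""), "")
  # newlines survive as line separators
  expect_identical(normalize_text("A:\n  B  C \nD"), "a:\nb c\nd")
})

test_that("normalization is idempotent", {
  withr::with_seed(41, {
    pool <- c("Exon", "19", "  ", "\t", "\n", "T790M", "Not", "DETECTED", ",")
    for (i in 1:50) {
      x <- paste(sample(pool, 12, replace = TRUE), collapse = "")
      expect_identical(normalize_text(normalize_text(x)), normalize_text(x))
    }
  })
})

test_that("section splitting recognizes the SAD headers", {
  d <- dialect_sad()
  text <- normalize_text(sad_report("The EGFR mutation was Not Detected."))
  sr <- split_sections(text, d$headers)
  expect_named(sr$sections, c("interpretation and comments:",
                              "egfr mutation assay:", "note:", "comment:"))
  expect_match(sr$sections[["egfr mutation assay:"]], "not detected")
  expect_identical(sr$residual, "")
})

test_that("section splitting recognizes the NAD result header", {
  sr <- split_sections(normalize_text("Result: Not Detected"), "result:")
  expect_identical(sr$sections[["result:"]], "not detected")
})

test_that("text without headers lands in residual; duplicates get suffixes", {
  sr <- split_sections("free text with no headers", c("result:"))
  expect_length(sr$sections, 0)
  expect_identical(sr$residual, "free text with no headers")

  sr2 <- split_sections("note:\nfirst\nnote:\nsecond", c("note:"))
  expect_named(sr2$sections, c("note:", "note:#2"))
  expect_identical(sr2$sections[["note:#2"]], "second")
})

test_that("section splitting loses no text", {
  d <- dialect_sad()
  corpus <- generate_corpus(generator_config(n_reports = 25, seed = 5))
  for (body in corpus$reports$RTF_RESULT) {
    text <- normalize_text(rtf_to_text(body)$text)
    sr <- split_sections(text, d$headers)
    expect_identical(egfrparse:::reconstruct_sections(sr), text)
  }
})

test_that("tokenization matches the worked result sentence", {
  toks <- tokenize("the deletions in exon 19 was identified", lex)
  expect_identical(toks$symbol, c("deletion_specific_result",
                                  "exon_19_location", "identified_result"))
})

test_that("conjunctions and multi-word keys tokenize; fillers are ignored", {
  toks <- tokenize("exon 19 and t790m mutations identified", lex)
  expect_identical(toks$symbol, c("exon_19_location", "conjunction",
                                  "t790m_location", "identified_result"))
  expect_identical(tokenize("", lex)$symbol, character())
  # the comma is a conjunction even when attached to a word
  toks2 <- tokenize("exon 19, t790m and l858r were identified", lex)
  expect_identical(toks2$symbol[2], "conjunction")
  expect_identical(toks2$surface[2], ",")
})

test_that("longest match wins: 'exon 19' is never a bare 'exon'", {
  toks <- tokenize("deletions in exon 19 were seen", lex)
  expect_identical(toks$surface[toks$category == "location"], "exon 19")
  # status phrase beats its own substring
  toks2 <- tokenize("test cancelled due to insufficient dna", lex)
  expect_identical(toks2$symbol, "cancelled_status")
})

test_that("token spans are strictly increasing, non-overlapping and faithful", {
  texts <- c("the deletions in exon 19 was identified",
             "exon 19, t790m and l858r were identified",
             "test cancelled due to insufficient dna today")
  for (tx in texts) {
    toks <- tokenize(tx, lex)
    expect_true(all(toks$end > toks$start))
    if (nrow(toks) > 1) {
      expect_true(all(toks$start[-1] >= toks$end[-nrow(toks)]))
    }
    expect_identical(substr(rep(tx, nrow(toks)), toks$start + 1, toks$end),
                     toks$surface)
  }
})

test_that("synonyms fold to the same token symbol", {
  expect_identical(tokenize("negative", lex)$symbol,
                   tokenize("not detected", lex)$symbol)
  expect_identical(tokenize("positive", lex)$symbol,
                   tokenize("identified", lex)$symbol)
})

test_that("tokenization is deterministic", {
  tx <- "deletions in exon 19 and insertions in exon 20 were identified"
  expect_identical(tokenize(tx, lex), tokenize(tx, lex))
})

test_that("lexicon validation rejects duplicates and unknown locations", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon 19\texon_19_location", "exon 19\tt790m_location"), tmp)
  expect_error(read_lexicon(tmp), "duplicate")
  writeLines("exon 21\texon_21_location", tmp)
  expect_error(read_lexicon(tmp), "unknown location")
})
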