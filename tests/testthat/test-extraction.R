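g <- egfr_grammar()
lex <- egfr_lexicon()
d <- dialect_sad()

test_that("the worked sentence extracts one exon 19 deletion", {
  res <- extract_sentence("The deletions in Exon 19 was identified.")
  expect_identical(res$status, "identified")
  expect_identical(nrow(res$mutations), 1L)
  expect_identical(res$mutations$location, "exon19")
  expect_identical(res$mutations$specific, "deletion")
  expect_identical(res$source_section, "egfr mutation assay:")
})

test_that("status-only sentences extract with empty mutation lists", {
  nd <- extract_sentence("Not Detected.")
  expect_identical(nd$status, "not_detected")
  expect_identical(nrow(nd$mutations), 0L)

  ins <- extract_sentence("There was insufficient DNA for the test.")
  expect_identical(ins$status, "insufficient_dna")

  can <- extract_sentence("Test cancelled due to insufficient DNA.")
  expect_identical(can$status, "cancelled")
  expect_identical(nrow(can$mutations), 0L)
})

test_that("multi-location sentences extract one call per location", {
  # membership and pairing checked against derivation enumeration below
  res <- extract_sentence("deletion exon 19 and t790m identified")
  expect_identical(res$status, "identified")
  expect_identical(res$mutations$location, c("exon19", "T790M"))
  expect_identical(res$mutations$specific, c("deletion", "none"))

  toks <- tokenize("deletion exon 19 and t790m identified", lex)$symbol
  expect_true(paste(toks, collapse = " ") %in% language_strings(g, 5))
  for (tree in all_parse_trees(toks, g)) {
    ext <- egfrparse:::extract_from_tree(tree)
    expect_identical(ext$status, "identified")
    expect_setequal(paste(ext$mutations$location, ext$mutations$specific),
                    c("exon19 deletion", "T790M none"))
  }
})

test_that("every derivation of an ambiguous sentence extracts the same result", {
  lang <- language_strings(g, 4)
  lang <- lang[nzchar(lang)]
  for (s in lang) {
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    trees <- all_parse_trees(toks, g, max_trees = 40)
    exts <- lapply(trees, egfrparse:::extract_from_tree)
    keys <- vapply(exts, function(e) {
      paste(e$status,
            paste(sort(paste(e$mutations$location, e$mutations$specific)),
                  collapse = ";"))
    }, character(1))
    expect_length(unique(keys), 1)
  }
})

test_that("mutation calls are conserved: one per distinct location token", {
  cases <- list(
    list(txt = "exon 19 and t790m and l858r mutations were identified", n = 3L),
    list(txt = "insertions in exon 20 were identified", n = 1L),
    list(txt = "g719x, s768i identified", n = 2L))
  for (cs in cases) {
    res <- extract_sentence(cs$txt)
    expect_identical(res$status, "identified")
    expect_identical(nrow(res$mutations), cs$n)
  }
  # repeated identical locations collapse, keeping the specific
  toks <- c("deletion_specific_result", "exon_19_location", "conjunction",
            "exon_19_location", "identified_result")
  p <- parse_tokens(toks, g)
  expect_true(p$accepted)
  ext <- egfrparse:::extract_from_tree(p$tree)
  expect_identical(nrow(ext$mutations), 1L)
  expect_identical(ext$mutations$specific, "deletion")
})

test_that("synonym phrasings yield identical results", {
  a <- extract_sentence("The exon 19 deletion was identified.")
  b <- extract_sentence("The exon 19 deletion was positive.")
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$status, b$status)

  c1 <- extract_sentence("The EGFR mutation was Not Detected.")
  c2 <- extract_sentence("The EGFR test was negative.")
  expect_identical(c1$status, c2$status)
})

test_that("the G719 family and the S768I alias fold to one location each", {
  for (v in c("g719s", "g719a", "g719c", "g719x")) {
    res <- extract_sentence(paste("the", v, "mutation was identified."))
    expect_identical(res$mutations$location, "G719X")
  }
  for (v in c("s768i", "s78i")) {
    res <- extract_sentence(paste("the", v, "mutation was identified."))
    expect_identical(res$mutations$location, "S768I")
  }
})

test_that("unparseable inputs yield one flagged result, never an error", {
  # mixed polarity is outside the grammar by design
  mixed <- extract_sentence("exon 19 identified and t790m not detected")
  expect_identical(mixed$status, "unparseable")

  # out-of-grammar word order
  oog <- extract_sentence("Positive for exon 19.")
  expect_identical(oog$status, "unparseable")
  expect_identical(oog$reason, "no parseable sentence")
  expect_match(oog$raw_sentence, "positive for exon 19")

  # no recognized section, no residual
  empty <- extract_result(split_sections("", d$headers), lex, g, d)
  expect_identical(empty$status, "unparseable")
  expect_identical(empty$reason, "no result section")

  # section present but contentless
  blank <- extract_sentence("Awaiting review.")
  expect_identical(blank$status, "unparseable")
  expect_identical(blank$reason, "no tokens")
})

test_that("residual text is used when no header is recognized", {
  sr <- split_sections(normalize_text("the exon 19 deletion was identified."),
                       d$headers)
  res <- extract_result(sr, lex, g, d)
  expect_identical(res$status, "identified")
  expect_identical(res$source_section, "(residual)")
})

test_that("comment content does not affect extraction", {
  s <- "The EGFR mutation was Not Detected."
  a <- extract_result(split_sections(normalize_text(sad_report(s)), d$headers),
                      lex, g, d)
  b <- extract_result(split_sections(normalize_text(
    sad_report(s, comment = "Low tumor cellularity noted.")), d$headers),
    lex, g, d)
  expect_identical(a$status, b$status)
  expect_identical(a$mutations, b$mutations)
})

test_that("result invariants are enforced by the constructor", {
  expect_error(new_egfr_result("identified"), "at least one mutation")
  expect_error(new_egfr_result("not_detected",
                               tibble::tibble(location = "exon19",
                                              specific = "none")),
               "no mutation calls")
  expect_error(new_egfr_result("identified",
                               tibble::tibble(location = c("exon19", "exon19"),
                                              specific = c("none", "none"))),
               "duplicate")
})

test_that("records flatten one row per mutation, one row otherwise", {
  two <- new_egfr_result("identified",
                         tibble::tibble(location = c("exon19", "T790M"),
                                        specific = c("deletion", "none")))
  expect_identical(nrow(result_to_records(two, list(result_id = "r1",
                                                    patient_id = "p1"))), 2L)

  four <- new_egfr_result("identified",
                          tibble::tibble(location = c("exon19", "T790M",
                                                      "L858R", "G719X"),
                                         specific = rep("none", 4)))
  expect_identical(nrow(result_to_records(four, list(result_id = "r2",
                                                     patient_id = "p2"))), 4L)

  nd <- new_egfr_result("not_detected")
  rec <- result_to_records(nd, list(result_id = "r3", patient_id = "p3"))
  expect_identical(nrow(rec), 1L)
  expect_true(is.na(rec$location))
})
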