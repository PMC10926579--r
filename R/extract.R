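.loc_label <- c(exon_19_location = "exon19",
                exon_20_location = "exon20",
                t790m_location = "T790M",
                l858r_location = "L858R",
                l861q_location = "L861Q",
                g719x_location = "G719X",
                s768i_location = "S768I")

.spec_label <- c(deletion_specific_result = "deletion",
                 insertion_specific_result = "insertion")

.egfr_statuses <- c("identified", "not_detected", "insufficient_dna",
                    "cancelled", "unparseable")

empty_mutations <- function() {
  tibble::tibble(location = character(), specific = character())
}

#' Construct a structured EGFR test result
#'
#' The payload record of the framework: a test status and, when a mutation was
#' identified, one call per distinct location. Invariants are enforced:
#' `identified` requires at least one mutation call, every other status
#' requires none, and locations are not duplicated.
#'
#' @param status One of `identified`, `not_detected`, `insufficient_dna`,
#'   `cancelled`, `unparseable`.
#' @param mutations Tibble with columns `location` (one of `exon19`, `exon20`,
#'   `T790M`, `L858R`, `L861Q`, `G719X`, `S768I`) and `specific` (`deletion`,
#'   `insertion`, `none`, or other surface text under a wildcard grammar).
#' @param source_section Header label of the section the sentence came from.
#' @param raw_sentence The original sentence text, retained verbatim.
#' @param reason Optional explanation for `unparseable` results.
#' @return An object of class `egfr_result`.
#' @export
new_egfr_result <- function(status, mutations = empty_mutations(),
                            source_section = NA_character_,
                            raw_sentence = "", reason = NA_character_) {
  status <- match.arg(status, .egfr_statuses)
  stopifnot(is.data.frame(mutations),
            all(c("location", "specific") %in% names(mutations)))
  if (status == "identified" && nrow(mutations) == 0L) {
    stop("status 'identified' requires at least one mutation call",
         call. = FALSE)
  }
  if (status != "identified" && nrow(mutations) > 0L) {
    stop("status '", status, "' must carry no mutation calls", call. = FALSE)
  }
  if (anyDuplicated(mutations$location)) {
    stop("duplicate mutation locations in one result", call. = FALSE)
  }
  structure(list(status = status,
                 mutations = tibble::as_tibble(mutations),
                 source_section = source_section,
                 raw_sentence = raw_sentence,
                 reason = reason),
            class = "egfr_result")
}

#' @export
print.egfr_result <- function(x, ...) {
  cat("<egfr_result>", x$status)
  if (!is.na(x$source_section)) cat("  [", x$source_section, "]", sep = "")
  cat("\n")
  if (nrow(x$mutations)) {
    for (i in seq_len(nrow(x$mutations))) {
      cat("  -", x$mutations$location[i],
          if (x$mutations$specific[i] != "none") paste0("(", x$mutations$specific[i], ")"),
          "\n")
    }
  }
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

# Walk a canonical (or any) parse tree and read off the test result: the
# terminals on the leaves are the result. Each maximal Location phrase holds
# exactly one location terminal plus any specific-result terminals attached
# within the phrase; specifics never bind across a conjunction because they
# live inside the Location subtree.
extract_from_tree <- function(tree) {
  leaves <- tree_leaves(tree)
  status <- if (any(leaves == "cancelled_status")) "cancelled"
    else if (any(leaves == "insufficient_dna_status")) "insufficient_dna"
    else if (any(leaves == "identified_result")) "identified"
    else if (any(leaves == "not_detected_result")) "not_detected"
    else "unparseable"

  calls <- list()
  walk <- function(node, parent_label) {
    if (node$terminal) return(invisible())
    if (node$label == "Location" && !identical(parent_label, "Location")) {
      lv <- tree_leaves(node)
      locs <- lv[lv %in% names(.loc_label)]
      specs <- lv[lv %in% names(.spec_label)]
      other <- setdiff(lv, c(names(.loc_label), names(.spec_label)))
      specific <- if (length(specs)) unname(.spec_label[specs[1L]])
        else if (length(other)) paste0("other(", other[1L], ")")
        else "none"
      if (length(locs)) {
        calls[[length(calls) + 1L]] <<- c(unname(.loc_label[locs[1L]]), specific)
      }
      return(invisible())
    }
    for (ch in node$children) walk(ch, node$label)
  }
  walk(tree, NA_character_)

  mutations <- if (length(calls)) {
    m <- tibble::tibble(location = vapply(calls, `[[`, "", 1L),
                        specific = vapply(calls, `[[`, "", 2L))
    # repeated identical locations collapse, keeping a non-none specific
    m <- m[order(match(m$location, m$location), m$specific == "none"), ]
    m[!duplicated(m$location), ]
  } else {
    empty_mutations()
  }
  if (status != "identified") mutations <- empty_mutations()
  list(status = status, mutations = mutations)
}

#' Extract a structured EGFR result from a sectioned report
#'
#' Selects the result section by the dialect's priority order (southern
#' dialect: `"egfr mutation assay:"`, falling back to
#' `"interpretation and comments:"`; northern dialect: `"result:"`; the
#' residual text is used when no recognized section is present), splits it
#' into candidate sentences, tokenizes each, and parses with the grammar. The
#' first parseable sentence wins; its parse tree's terminal leaves are mapped
#' to a test status and per-location mutation calls. Sentences that tokenize
#' non-empty but fail to parse yield `status = "unparseable"` with the raw
#' text retained for manual review.
#'
#' @param report A `sectioned_report` from [split_sections()] on normalized,
#'   RTF-stripped text.
#' @param lexicon An `egfr_lexicon`.
#' @param grammar A `cfg_grammar`; extraction expects the packaged variable
#'   naming (`Location`, `Result`, ...).
#' @param dialect An `egfr_dialect` (see [dialect_sad()]), used for its
#'   `result_section_priority`.
#' @return An `egfr_result`. Every input yields exactly one result; no input
#'   errors out of extraction.
#' @examples
#' rep <- split_sections(normalize_text(
#'   "EGFR Mutation Assay:\nThe deletions in Exon 19 was identified."),
#'   dialect_sad()$headers)
#' extract_result(rep, egfr_lexicon(), egfr_grammar(), dialect_sad())
#' @export
extract_result <- function(report, lexicon, grammar, dialect) {
  stopifnot(inherits(report, "sectioned_report"))
  secnames <- names(report$sections)
  base <- sub("#[0-9]+$", "", secnames)
  sect <- NULL
  for (p in normalize_text(dialect$result_section_priority)) {
    idx <- which(base == p)
    if (length(idx)) { sect <- secnames[idx[1L]]; break }
  }
  if (is.null(sect)) {
    if (!nzchar(report$residual)) {
      return(new_egfr_result("unparseable", source_section = NA_character_,
                             raw_sentence = "", reason = "no result section"))
    }
    body <- report$residual
    src <- "(residual)"
  } else {
    body <- report$sections[[sect]]
    src <- sect
  }

  sentences <- trimws(strsplit(body, "[.\n]+")[[1]])
  sentences <- sentences[nzchar(sentences)]
  first_tokenized <- NA_character_
  for (s in sentences) {
    toks <- tokenize(s, lexicon)
    if (nrow(toks) == 0L) next
    if (is.na(first_tokenized)) first_tokenized <- s
    # a lexicon symbol the grammar has no terminal for (e.g. a status token
    # under the core grammar) cannot parse; the sentence stays for review
    if (!all(toks$symbol %in% c(grammar$terminals, NA))) {
      has_any <- any(vapply(grammar$rules, function(r) any(r$kind == "any"),
                            logical(1)))
      if (!has_any) next
    }
    p <- parse_tokens(toks$symbol, grammar)
    if (p$accepted) {
      ext <- extract_from_tree(p$tree)
      if (ext$status == "identified" && nrow(ext$mutations) == 0L) {
        return(new_egfr_result("unparseable", source_section = src,
                               raw_sentence = s,
                               reason = "identified without location"))
      }
      return(new_egfr_result(ext$status, ext$mutations, src, s))
    }
  }
  if (is.na(first_tokenized)) {
    new_egfr_result("unparseable", source_section = src, raw_sentence = body,
                    reason = "no tokens")
  } else {
    new_egfr_result("unparseable", source_section = src,
                    raw_sentence = first_tokenized,
                    reason = "no parseable sentence")
  }
}

#' Flatten an EGFR result to long-format output records
#'
#' `identified` results emit one record per mutation call; every other status
#' emits exactly one record with empty location fields.
#'
#' @param result An `egfr_result`.
#' @param ids Named list with `result_id` and `patient_id`.
#' @return Tibble with columns `result_id`, `patient_id`, `status`,
#'   `location`, `specific`, `source_section`.
#' @export
result_to_records <- function(result, ids) {
  stopifnot(inherits(result, "egfr_result"),
            !is.null(ids$result_id))
  pid <- if (is.null(ids$patient_id)) NA_character_ else as.character(ids$patient_id)
  if (result$status == "identified") {
    tibble::tibble(result_id = as.character(ids$result_id),
                   patient_id = pid,
                   status = result$status,
                   location = result$mutations$location,
                   specific = result$mutations$specific,
                   source_section = result$source_section)
  } else {
    tibble::tibble(result_id = as.character(ids$result_id),
                   patient_id = pid,
                   status = result$status,
                   location = NA_character_,
                   specific = NA_character_,
                   source_section = result$source_section)
  }
}
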