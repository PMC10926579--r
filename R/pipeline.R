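new_dialect <- function(x) {
  needed <- c("name", "id_column", "patient_column", "body_column",
              "body_is_rtf", "filter_columns", "headers",
              "result_section_priority")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("dialect config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$headers <- normalize_text(unlist(x$headers))
  x$result_section_priority <- normalize_text(unlist(x$result_section_priority))
  x$filter_columns <- unlist(x$filter_columns)
  extra <- setdiff(x$result_section_priority, x$headers)
  if (length(extra)) {
    stop("result_section_priority label(s) not in headers: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(x[needed], class = "egfr_dialect")
}

#' @export
print.egfr_dialect <- function(x, ...) {
  cat("<egfr_dialect>", x$name, "\n")
  cat("  body:", x$body_column, if (x$body_is_rtf) "(RTF)" else "(plain)", "\n")
  cat("  filter:", paste(x$filter_columns, collapse = ", "), "\n")
  cat("  headers:", paste(x$headers, collapse = " | "), "\n")
  invisible(x)
}

#' Read dataset dialect presets from a YAML config
#'
#' Dialects are data, not code branches: each entry describes how a
#' laboratory export stores its reports (which column holds the body, whether
#' it is RTF, which columns the biomarker keyword filter searches, the
#' section header list, and the result-section priority). New sources are
#' added as config blocks.
#'
#' @param path YAML config file; defaults to the packaged presets for the
#'   southern (`sad`) and northern (`nad`) export dialects.
#' @return List with `keyword` and `dialects` (named list of `egfr_dialect`).
#' @export
read_dialect_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dialects.yaml", package = "egfrparse",
                        mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  list(keyword = cfg$keyword %||% "egfr",
       dialects = lapply(cfg$dialects, new_dialect))
}

#' Packaged dialect presets
#'
#' `dialect_sad()` describes the southern export: report bodies in Rich Text
#' Format in `RTF_RESULT`, sections "Interpretation and Comments:",
#' "EGFR Mutation Assay:", "Note:", "Comment:", keyword filtering over
#' `SPECIMEN_ACCN`, `SPECIMEN_SOURCE`, `TEST_NAME`, `TEST_TASK`, `RTF_RESULT`
#' (the short-result column is deliberately not a filter or extraction
#' source — it lacks the mutation location). `dialect_nad()` describes the
#' northern export: plain text in a single `RESULTS` column with a
#' "Result:" section.
#'
#' @return An `egfr_dialect`.
#' @export
dialect_sad <- function() read_dialect_config()$dialects$sad

#' @rdname dialect_sad
#' @export
dialect_nad <- function() read_dialect_config()$dialects$nad

#' Filter laboratory rows for a biomarker keyword
#'
#' Keeps rows in which the keyword occurs case-insensitively as a substring in
#' at least one of the dialect's filter columns. Rows with a missing patient
#' identifier are retained (they may still link to existing patients), and
#' row order is preserved.
#'
#' @param table Data frame of laboratory rows.
#' @param dialect An `egfr_dialect`.
#' @param keyword Search keyword; plain substring, not a word-boundary match,
#'   so variants such as "EGFR Mutation Assessment/Assay" all match.
#' @param patient_allowlist Optional character vector of patient identifiers
#'   standing in for a registry-derived cohort (registry linkage itself is out
#'   of scope). When given, rows are kept only if their patient identifier is
#'   on the list or empty.
#' @return The filtered data frame.
#' @export
filter_records <- function(table, dialect, keyword = "egfr",
                           patient_allowlist = NULL) {
  stopifnot(is.data.frame(table), inherits(dialect, "egfr_dialect"))
  missing <- setdiff(dialect$filter_columns, names(table))
  if (length(missing)) {
    stop("configured filter column(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) == 0L) return(table)
  hit <- rep(FALSE, nrow(table))
  for (col in dialect$filter_columns) {
    v <- as.character(table[[col]])
    hit <- hit | (!is.na(v) & grepl(keyword, v, ignore.case = TRUE, fixed = FALSE))
  }
  if (!is.null(patient_allowlist) &&
      dialect$patient_column %in% names(table)) {
    pid <- as.character(table[[dialect$patient_column]])
    hit <- hit & (is.na(pid) | !nzchar(pid) | pid %in% patient_allowlist)
  }
  table[hit, , drop = FALSE]
}

# Merge long-format records that share a result_id (a test reported across
# several rows): statuses must agree (conflicts are kept as first-seen and
# flagged), mutation rows are unioned with duplicate locations collapsed,
# preferring a non-none specific.
merge_duplicate_results <- function(records) {
  if (nrow(records) == 0L) {
    return(list(records = records, conflicts = character()))
  }
  conflicts <- character()
  split_idx <- split(seq_len(nrow(records)), records$result_id)
  keep <- logical(nrow(records))
  for (idx in split_idx) {
    st <- unique(records$status[idx])
    if (length(st) > 1L) {
      conflicts <- c(conflicts, records$result_id[idx[1L]])
      idx <- idx[records$status[idx] == records$status[idx[1L]]]
    }
    if (records$status[idx[1L]] == "identified") {
      ord <- idx[order(records$specific[idx] == "none")]
      ord <- ord[!duplicated(records$location[ord])]
      keep[ord] <- TRUE
    } else {
      keep[idx[1L]] <- TRUE
    }
  }
  out <- records[keep, , drop = FALSE]
  out <- out[order(match(out$result_id, records$result_id)), , drop = FALSE]
  list(records = out, conflicts = conflicts)
}

#' Run the full extraction pipeline on a filtered table
#'
#' Per row: strip RTF (when the dialect stores RTF bodies), normalize, split
#' into sections, extract the structured result, and flatten to long-format
#' records. Row-level failures become `unparseable` records — they never
#' abort the batch. Rows sharing a result identifier are merged; conflicting
#' statuses within one identifier are flagged as a data-quality warning.
#'
#' @param table Data frame of (already filtered) laboratory rows.
#' @param dialect An `egfr_dialect`.
#' @param lexicon An `egfr_lexicon`; defaults to the packaged EGFR lexicon.
#' @param grammar A `cfg_grammar`; defaults to the packaged grammar with
#'   status extensions.
#' @return List of class `extraction_run`:
#'   * `records` — long-format tibble (`result_id`, `patient_id`, `status`,
#'     `location`, `specific`, `source_section`), one row per mutation call
#'     for identified tests and one row otherwise, after merging duplicate
#'     result identifiers;
#'   * `summary` — an `extraction_summary` (see [summarize_extraction()]);
#'   * `rejects` — the unparseable records with their retained raw sentence;
#'   * `status_conflicts` — result ids whose rows disagreed on status.
#' @export
run_extraction <- function(table, dialect, lexicon = egfr_lexicon(),
                           grammar = egfr_grammar()) {
  stopifnot(is.data.frame(table), inherits(dialect, "egfr_dialect"))
  for (col in c(dialect$body_column, dialect$id_column)) {
    if (!col %in% names(table)) {
      stop("configured column absent from table: ", col, call. = FALSE)
    }
  }
  rec_list <- vector("list", nrow(table))
  rej_list <- list()
  for (i in seq_len(nrow(table))) {
    body <- as.character(table[[dialect$body_column]][i])
    if (is.na(body)) body <- ""
    text <- if (dialect$body_is_rtf && nzchar(body)) rtf_to_text(body)$text else body
    sr <- split_sections(normalize_text(text), dialect$headers)
    res <- extract_result(sr, lexicon, grammar, dialect)
    pid <- if (dialect$patient_column %in% names(table)) {
      as.character(table[[dialect$patient_column]][i])
    } else NA_character_
    rec_list[[i]] <- result_to_records(
      res, list(result_id = table[[dialect$id_column]][i], patient_id = pid))
    if (res$status == "unparseable") {
      rej_list[[length(rej_list) + 1L]] <- tibble::tibble(
        result_id = as.character(table[[dialect$id_column]][i]),
        raw_sentence = res$raw_sentence,
        reason = res$reason)
    }
  }
  empty_rec <- tibble::tibble(result_id = character(),
                              patient_id = character(), status = character(),
                              location = character(), specific = character(),
                              source_section = character())
  records <- dplyr::bind_rows(c(list(empty_rec), rec_list))
  merged <- merge_duplicate_results(records)
  rejects <- if (length(rej_list)) dplyr::bind_rows(rej_list) else
    tibble::tibble(result_id = character(), raw_sentence = character(),
                   reason = character())
  if (length(merged$conflicts)) {
    warning("conflicting statuses for result id(s): ",
            paste(merged$conflicts, collapse = ", "), call. = FALSE)
  }
  structure(list(records = merged$records,
                 summary = summarize_extraction(merged$records),
                 rejects = rejects,
                 status_conflicts = merged$conflicts),
            class = "extraction_run")
}

#' @export
print.extraction_run <- function(x, ...) {
  cat("<extraction_run>", nrow(x$records), "records\n")
  print(x$summary)
  invisible(x)
}

#' Summarize extracted EGFR records
#'
#' Tallies the status distribution over unique test results, the per-location
#' counts among identified results, the multi-location distribution (how many
#' identified results carry 2, 3, or 4+ locations), and the unordered
#' location-pair combination counts among multi-location results.
#'
#' @param records Long-format records as produced by [run_extraction()].
#' @return An object of class `extraction_summary`.
#' @export
summarize_extraction <- function(records) {
  statuses <- .egfr_statuses
  one_per_result <- records[!duplicated(records$result_id), , drop = FALSE]
  status_counts <- table(factor(one_per_result$status, levels = statuses))

  ident <- records[records$status == "identified" & !is.na(records$location), ,
                   drop = FALSE]
  location_counts <- table(factor(ident$location, levels = unname(.loc_label)))

  k_per_result <- table(table(ident$result_id))
  multi <- c(`1` = 0L, `2` = 0L, `3` = 0L, `4+` = 0L)
  for (k in names(k_per_result)) {
    key <- if (as.integer(k) >= 4L) "4+" else k
    multi[key] <- multi[key] + as.integer(k_per_result[[k]])
  }

  pair_counts <- tibble::tibble(location_a = character(),
                                location_b = character(), n = integer())
  if (nrow(ident)) {
    locs_by_result <- split(ident$location, ident$result_id)
    pairs <- list()
    for (locs in locs_by_result) {
      if (length(locs) < 2L) next
      locs <- sort(locs)
      cmb <- utils::combn(locs, 2L)
      for (j in seq_len(ncol(cmb))) {
        key <- paste(cmb[1L, j], cmb[2L, j], sep = "|")
        pairs[[key]] <- (pairs[[key]] %||% 0L) + 1L
      }
    }
    if (length(pairs)) {
      keys <- sort(names(pairs))
      parts <- strsplit(keys, "|", fixed = TRUE)
      pair_counts <- tibble::tibble(
        location_a = vapply(parts, `[[`, "", 1L),
        location_b = vapply(parts, `[[`, "", 2L),
        n = vapply(keys, function(k) as.integer(pairs[[k]]), integer(1),
                   USE.NAMES = FALSE))
      pair_counts <- pair_counts[order(-pair_counts$n, pair_counts$location_a), ]
    }
  }

  structure(list(status_counts = status_counts,
                 location_counts = location_counts,
                 multi_location = multi,
                 pair_counts = pair_counts,
                 n_rows = nrow(records),
                 n_unique_results = length(unique(records$result_id))),
            class = "extraction_summary")
}

#' @export
print.extraction_summary <- function(x, ...) {
  cat("<extraction_summary>", x$n_unique_results, "unique results\n")
  cat("status:\n"); print(x$status_counts)
  if (sum(x$location_counts)) {
    cat("locations among identified:\n"); print(x$location_counts)
    cat("locations per identified result:\n"); print(x$multi_location)
  }
  invisible(x)
}

#' Write extraction records to disk
#'
#' Long format writes one CSV row per record (RFC-4180 quoting, UTF-8);
#' `jsonl` writes one JSON object per unique test result with its mutation
#' calls nested. Output is byte-identical across runs on identical input.
#'
#' @param records Long-format records from [run_extraction()].
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(records, path)
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rid in unique(records$result_id)) {
    rows <- records[records$result_id == rid, , drop = FALSE]
    obj <- list(result_id = rid,
                patient_id = rows$patient_id[1L],
                status = rows$status[1L],
                source_section = rows$source_section[1L],
                mutations = if (rows$status[1L] == "identified") {
                  lapply(seq_len(nrow(rows)), function(i) {
                    list(location = rows$location[i], specific = rows$specific[i])
                  })
                } else list())
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con,
               useBytes = TRUE)
  }
  invisible(path)
}
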