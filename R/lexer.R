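#' Normalize report text
#'
#' Applies the minimal normalization used throughout the framework: lowercase,
#' strip leading/trailing whitespace, and collapse internal runs of spaces and
#' tabs to a single space. Newlines are preserved as line separators so that
#' section headers can still be recognized at line starts.
#'
#' `normalize_text()` is idempotent: applying it twice gives the same result.
#'
#' @param x Character vector of texts to normalize.
#' @return Character vector of the same length.
#' @examples
#' normalize_text("  Exon 19  ")
#' normalize_text("NOT   DETECTED")
#' @export
normalize_text <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (is.na(s)) return("")
    s <- tolower(s)
    lines <- strsplit(s, "\n", fixed = TRUE)[[1]]
    if (length(lines) == 0L) return("")
    lines <- trimws(gsub("[ \t\r\f\v]+", " ", lines))
    gsub("^\n+|\n+$", "", paste(lines, collapse = "\n"))
  }, character(1), USE.NAMES = FALSE)
}

#' Split a normalized report into named sections
#'
#' Laboratory reports carry their content under explicit section headers
#' (e.g. `"EGFR Mutation Assay:"`, or `"Result:"` in the northern dialect).
#' An exact, case-insensitive match of a header label at the start of a line
#' opens a new section; the section body runs to the next recognized header or
#' the end of the report. Text before the first recognized header is kept in
#' `residual`. Duplicate headers get suffixed keys (`label#2`, ...).
#'
#' @param text Normalized report text (see [normalize_text()]).
#' @param headers Character vector of header labels (including any trailing
#'   colon), e.g. `c("interpretation and comments:", "egfr mutation assay:",
#'   "note:", "comment:")`.
#' @return An object of class `sectioned_report`: list with `sections` (named
#'   list of body texts, in order of appearance) and `residual`.
#' @examples
#' sr <- split_sections(normalize_text("Result: Not Detected."), "result:")
#' sr$sections[["result:"]]
#' @export
split_sections <- function(text, headers) {
  stopifnot(is.character(text), length(text) == 1L,
            is.character(headers), length(headers) >= 1L)
  hs <- normalize_text(headers)
  hs <- hs[order(-nchar(hs))]  # longest first so no label shadows a longer one

  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- character()

  bodies <- list()
  inline <- logical()
  residual <- character()
  current <- NULL

  for (line in lines) {
    hit <- hs[startsWith(line, hs)]
    if (length(hit) > 0L) {
      label <- hit[[1L]]
      n_prev <- sum(sub("#[0-9]+$", "", names(bodies)) == label)
      if (n_prev > 0L) label <- paste0(label, "#", n_prev + 1L)
      rest <- trimws(substring(line, nchar(hit[[1L]]) + 1L))
      bodies[[label]] <- if (nzchar(rest)) rest else character()
      inline[[label]] <- nzchar(rest)
      current <- label
    } else if (is.null(current)) {
      residual <- c(residual, line)
    } else {
      bodies[[current]] <- c(bodies[[current]], line)
    }
  }

  structure(list(sections = lapply(bodies, paste, collapse = "\n"),
                 residual = paste(residual, collapse = "\n"),
                 inline = inline),
            class = "sectioned_report")
}

#' @export
print.sectioned_report <- function(x, ...) {
  cat("<sectioned_report>", length(x$sections), "section(s)\n")
  if (nzchar(x$residual)) cat("residual:", substr(x$residual, 1, 60), "\n")
  for (nm in names(x$sections)) {
    cat(" [", nm, "] ", substr(x$sections[[nm]], 1, 60), "\n", sep = "")
  }
  invisible(x)
}

# Reassemble the normalized input from a sectioned_report (used to verify
# that section splitting loses no text).
reconstruct_sections <- function(sr) {
  parts <- if (nzchar(sr$residual)) sr$residual else character()
  for (label in names(sr$sections)) {
    head_lab <- sub("#[0-9]+$", "", label)
    body <- sr$sections[[label]]
    if (isTRUE(sr$inline[[label]])) {
      parts <- c(parts, if (nzchar(body)) paste(head_lab, body) else head_lab)
    } else {
      parts <- c(parts, head_lab, if (nzchar(body)) body else NULL)
    }
  }
  paste(parts, collapse = "\n")
}

.lexicon_categories <- c("location", "result", "specific_result",
                         "conjunction", "status")

.location_symbols <- c("exon_19_location", "exon_20_location",
                       "t790m_location", "l858r_location", "l861q_location",
                       "g719x_location", "s768i_location")

symbol_category <- function(sym) {
  ifelse(sym == "conjunction", "conjunction",
  ifelse(grepl("_specific_result$", sym), "specific_result",
  ifelse(grepl("_result$", sym), "result",
  ifelse(grepl("_location$", sym), "location",
  ifelse(grepl("_status$", sym), "status", NA_character_)))))
}

#' Read a tokenization lexicon
#'
#' The lexicon maps normalized surface forms (possibly multi-word, e.g.
#' `"exon 19"` or `"not detected"`) to token symbols. The file format is
#' two-column tab-separated text — surface form, TAB, token symbol — with `#`
#' comments. The lexical category is inferred from the symbol's suffix
#' (`_location`, `_result`, `_specific_result`, `_status`) or the literal
#' symbol `conjunction`.
#'
#' @param path Path to a lexicon TSV file.
#' @return An object of class `egfr_lexicon`: list with `entries` (a tibble
#'   of surface/symbol/category), a fast lookup `map`, and `max_words`, the
#'   longest surface form in words.
#' @seealso [egfr_lexicon()] for the packaged default, [tokenize()].
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed lexicon line(s): ", paste(lines[bad], collapse = " | "),
         call. = FALSE)
  }
  surface <- normalize_text(vapply(parts, `[[`, "", 1L))
  symbol <- trimws(vapply(parts, `[[`, "", 2L))
  new_lexicon(surface, symbol)
}

new_lexicon <- function(surface, symbol) {
  if (anyDuplicated(surface)) {
    stop("duplicate lexicon surface form(s): ",
         paste(unique(surface[duplicated(surface)]), collapse = ", "),
         call. = FALSE)
  }
  category <- symbol_category(symbol)
  if (anyNA(category)) {
    stop("cannot infer category for symbol(s): ",
         paste(symbol[is.na(category)], collapse = ", "), call. = FALSE)
  }
  loc <- symbol[category == "location"]
  bad_loc <- setdiff(loc, .location_symbols)
  if (length(bad_loc)) {
    stop("unknown location symbol(s): ", paste(bad_loc, collapse = ", "),
         call. = FALSE)
  }
  map <- stats::setNames(symbol, surface)
  structure(list(entries = tibble::tibble(surface = surface, symbol = symbol,
                                          category = category),
                 map = map,
                 max_words = max(lengths(strsplit(surface, " ", fixed = TRUE)))),
            class = "egfr_lexicon")
}

#' The packaged EGFR lexicon
#'
#' The reduced dictionary used to tokenize EGFR result sentences: the seven
#' assay locations (exon 19, exon 20, T790M, L858R, L861Q, G719X — covering
#' G719S/G719A/G719C, which the assay does not distinguish — and S768I),
#' result words (`identified`/`positive`/`detected`, `not detected`/
#' `negative`), specific results (deletion, insertion, and their inflections),
#' conjunctions (`and`, `,`), and test-status phrases (insufficient DNA, test
#' cancelled).
#'
#' @return An `egfr_lexicon` object.
#' @examples
#' lex <- egfr_lexicon()
#' tokenize("the deletions in exon 19 was identified", lex)$symbol
#' @export
egfr_lexicon <- function() {
  read_lexicon(system.file("extdata", "egfr_lexicon.tsv",
                           package = "egfrparse", mustWork = TRUE))
}

#' @export
print.egfr_lexicon <- function(x, ...) {
  cat("<egfr_lexicon>", nrow(x$entries), "surface forms,",
      length(unique(x$entries$symbol)), "symbols\n")
  print(table(x$entries$category))
  invisible(x)
}

#' Tokenize a normalized sentence against a lexicon
#'
#' Scans left to right with longest-match lookup of lexicon surface forms
#' (multi-word entries allowed, so `"exon 19"` is never tokenized as a bare
#' `"exon"`). Words that match no lexicon entry — intermediary English — are
#' ignored. Punctuation is split off so that the comma conjunction is found
#' even when attached to a word.
#'
#' @param text A normalized character string (see [normalize_text()]).
#' @param lexicon An `egfr_lexicon`.
#' @return A tibble with one row per token: `symbol`, `category`, `surface`
#'   (the matched source text), and `start`/`end` character offsets (0-based,
#'   half-open) into `text`.
#' @examples
#' tokenize("exon 19 and t790m mutations identified", egfr_lexicon())
#' @export
tokenize <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1L,
            inherits(lexicon, "egfr_lexicon"))
  empty <- tibble::tibble(symbol = character(), category = character(),
                          surface = character(),
                          start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) return(empty)

  m <- gregexpr("[^\\s.,;:()\"]+|[.,;:()]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  n <- length(starts)

  sym_out <- character(n)
  surf_out <- character(n)
  s_out <- integer(n)
  e_out <- integer(n)
  n_tok <- 0L

  i <- 1L
  maxw <- lexicon$max_words
  while (i <= n) {
    advanced <- FALSE
    for (k in seq.int(min(maxw, n - i + 1L), 1L)) {
      surf <- substr(text, starts[i], ends[i + k - 1L])
      sym <- lexicon$map[surf]
      if (!is.na(sym)) {
        n_tok <- n_tok + 1L
        sym_out[n_tok] <- sym
        surf_out[n_tok] <- surf
        s_out[n_tok] <- starts[i] - 1L           # 0-based
        e_out[n_tok] <- ends[i + k - 1L]         # half-open
        i <- i + k
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }

  idx <- seq_len(n_tok)
  tibble::tibble(symbol = unname(sym_out[idx]),
                 category = symbol_category(sym_out[idx]),
                 surface = surf_out[idx],
                 start = s_out[idx], end = e_out[idx])
}
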