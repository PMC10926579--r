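#' Convert a Rich Text Format report body to plain text
#'
#' Laboratory exports in the southern-dialect layout carry the report body in
#' Rich Text Format (RTF). `rtf_to_text()` removes RTF markup — control words,
#' group braces, and non-content "destination" groups such as the font table —
#' and decodes character escapes, leaving the readable report text. Paragraph
#' and line breaks (`\par`, `\line`) become single newlines. Input that does
#' not start with the RTF group opener `{\rtf` is passed through unchanged.
#'
#' Formatting removal is deliberately lossy: unknown control words are dropped
#' silently, and whitespace produced by stripping is preserved as-is (collapsing
#' is the normalizer's job, see [normalize_text()]).
#'
#' @param raw A length-1 character string: the raw report body, which may or
#'   may not be RTF.
#' @param encoding Encoding assumed for `\'hh` hex escapes. Defaults to
#'   Windows-1252, the dominant dialect for clinical RTF exports.
#' @param skip_destinations Character vector of destination group control words
#'   whose whole group is dropped. Any group opened with the ignorable marker
#'   `\*` is always dropped.
#'
#' @return An object of class `plain_text`: a list with elements
#'   * `text` — the stripped text (no control words, no braces),
#'   * `had_rtf` — `TRUE` if RTF stripping was applied,
#'   * `problems` — character vector of recoverable defects found
#'     (unbalanced braces, truncated escapes); empty when the input was clean.
#'
#' @examples
#' rtf_to_text("{\\rtf1\\ansi EGFR Mutation Assay: Not Detected\\par}")$text
#' rtf_to_text("Result: Not Detected")$had_rtf
#' @export
rtf_to_text <- function(raw,
                        encoding = "CP1252",
                        skip_destinations = c("fonttbl", "colortbl",
                                              "stylesheet", "info", "pict")) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  if (!nzchar(raw)) stop("`raw` must be a non-empty string", call. = FALSE)

  if (!grepl("^[ \t\r\n]*\\{\\\\rtf", raw)) {
    return(structure(list(text = raw, had_rtf = FALSE, problems = character()),
                     class = "plain_text"))
  }

  toks <- .rtf_scan(raw)
  problems <- character()

  # group state stack: each frame is c(skip, uc); pend counts \u fallback
  # characters still to swallow in the current group
  skip <- FALSE
  uc <- 1L
  pend <- 0L
  stack <- list()
  just_opened <- FALSE
  out <- character(length(toks))
  n_out <- 0L

  emit <- function(s) {
    n_out <<- n_out + 1L
    out[n_out] <<- s
  }

  for (tok in toks) {
    first <- substr(tok, 1L, 1L)
    if (first == "{") {
      stack[[length(stack) + 1L]] <- list(skip = skip, uc = uc, pend = pend)
      pend <- 0L
      just_opened <- TRUE
      next
    }
    if (first == "}") {
      if (length(stack) == 0L) {
        problems <- c(problems, "unbalanced braces: extra '}'")
      } else {
        st <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        skip <- st$skip
        uc <- st$uc
        pend <- st$pend
      }
      just_opened <- FALSE
      next
    }
    if (first == "\\") {
      c2 <- substr(tok, 2L, 2L)
      if (c2 == "'") {
        # hex escape
        hex <- substr(tok, 3L, 4L)
        if (pend > 0L) {
          pend <- pend - 1L  # escape counts as one \u fallback character
        } else if (nchar(hex) < 2L) {
          problems <- c(problems, paste0("truncated hex escape '", tok, "'"))
        } else if (!skip) {
          emit(.decode_hex_byte(hex, encoding))
        }
        just_opened <- FALSE
        next
      }
      if (c2 == "u" && grepl("^\\\\u-?[0-9]", tok)) {
        cp <- as.integer(sub("^\\\\u(-?[0-9]+).*$", "\\1", tok))
        if (cp < 0L) cp <- cp + 65536L
        if (!skip && pend == 0L) emit(intToUtf8(cp))
        pend <- pend + uc
        just_opened <- FALSE
        next
      }
      if (grepl("^\\\\[a-zA-Z]", tok)) {
        word <- sub("^\\\\([a-zA-Z]+).*$", "\\1", tok)
        arg <- sub("^\\\\[a-zA-Z]+(-?[0-9]*).*$", "\\1", tok)
        if (just_opened && (word %in% skip_destinations)) skip <- TRUE
        if (word == "uc" && nzchar(arg)) uc <- as.integer(arg)
        if (!skip && word %in% c("par", "line", "sect", "page")) emit("\n")
        if (!skip && word == "tab") emit("\t")
        # every other control word is formatting and is dropped
        just_opened <- FALSE
        next
      }
      # control symbol
      if (c2 == "*") {
        if (just_opened) skip <- TRUE
        just_opened <- FALSE
        next
      }
      if (!skip && pend == 0L) {
        sym <- switch(c2,
                      "{" = "{", "}" = "}", "\\" = "\\",
                      "~" = " ", "_" = "-", "\n" = "\n", "\r" = "\n",
                      "-" = "",
                      "")
        if (nzchar(sym)) emit(sym)
      } else if (pend > 0L) {
        pend <- pend - 1L
      }
      just_opened <- FALSE
      next
    }
    # plain text run: raw newlines are markup whitespace in RTF, drop them
    txt <- gsub("[\r\n]", "", tok)
    if (pend > 0L) {
      k <- min(pend, nchar(txt))
      txt <- substr(txt, k + 1L, nchar(txt))
      pend <- pend - k
    }
    if (!skip && nzchar(txt)) emit(txt)
    just_opened <- FALSE
  }

  if (length(stack) > 0L) {
    problems <- c(problems, "unbalanced braces: unclosed group")
  }
  structure(list(text = paste0(out[seq_len(n_out)], collapse = ""),
                 had_rtf = TRUE,
                 problems = unique(problems)),
            class = "plain_text")
}

#' @export
print.plain_text <- function(x, ...) {
  cat("<plain_text>", if (x$had_rtf) "(stripped from RTF)" else "(passthrough)", "\n")
  if (length(x$problems)) cat("problems:", paste(x$problems, collapse = "; "), "\n")
  cat(x$text, "\n")
  invisible(x)
}

# Split raw RTF into scanner tokens: hex escapes, \uN, control words
# (with their optional numeric argument and delimiter space), control
# symbols, braces, and plain-text runs.
.rtf_scan <- function(raw) {
  pat <- paste0(
    "\\\\'[0-9a-fA-F]{0,2}",          # hex escape (possibly truncated)
    "|\\\\u-?[0-9]+ ?",               # unicode escape
    "|\\\\[a-zA-Z]+(-?[0-9]+)? ?",    # control word
    "|\\\\[^a-zA-Z]",                 # control symbol
    "|[{}]",                          # group braces
    "|[^\\\\{}]+"                     # text run
  )
  m <- gregexpr(pat, raw, perl = TRUE)[[1]]
  regmatches(raw, list(m))[[1]]
}

.decode_hex_byte <- function(hex, encoding) {
  b <- as.raw(strtoi(hex, 16L))
  res <- iconv(rawToChar(b), from = encoding, to = "UTF-8")
  if (is.na(res)) "" else res
}

#' Wrap plain report text in a minimal RTF envelope
#'
#' Produces a small, valid RTF document (font table, color table, one plain
#' paragraph per input line) around arbitrary report text, escaping the RTF
#' special characters. Used by the synthetic report generator for the
#' southern-dialect exports; `rtf_to_text()` on the result recovers the input
#' text exactly.
#'
#' @param text Plain report text; lines separated by `"\n"`.
#' @return A length-1 character string holding the RTF document.
#' @examples
#' body <- "EGFR Mutation Assay:\nNot Detected."
#' identical(rtf_to_text(rtf_wrap(body))$text, body)
#' @export
rtf_wrap <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  esc <- gsub("\\", "\\\\", text, fixed = TRUE)
  esc <- gsub("{", "\\{", esc, fixed = TRUE)
  esc <- gsub("}", "\\}", esc, fixed = TRUE)
  lines <- strsplit(esc, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  paste0(
    "{\\rtf1\\ansi\\ansicpg1252\\deff0",
    "{\\fonttbl{\\f0\\fswiss Arial;}}",
    "{\\colortbl ;\\red0\\green0\\blue0;}\n",
    "\\f0\\fs20 ",
    paste0(lines, collapse = "\\par\n"),
    "}"
  )
}
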