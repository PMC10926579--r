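#' Read a context-free grammar from its declarative file format
#'
#' A context-free grammar is the 4-tuple (V, \eqn{\Sigma}, R, S): variables,
#' terminals, production rules, and a start symbol. The file format is
#' line-oriented:
#'
#' ```
#' # comment
#' Lhs -> Alt1 | Alt2 | ...
#' ```
#'
#' Alternatives are whitespace-separated symbols. Terminals are single-quoted
#' (`'identified_result'`), unquoted symbols are variables, `EPSILON` denotes
#' the empty production, and `ANY` is a wildcard terminal matching any single
#' token (for grammar variants with an unrecognized-modifier slot). Repeated
#' lines with the same left-hand side append alternatives; the first rule's
#' left-hand side is the start symbol. Rule order in the file fixes the
#' canonical-derivation tie-break used by [parse_tokens()].
#'
#' @param source Path to a grammar file, or a character vector of grammar
#'   lines.
#' @return An object of class `cfg_grammar` with elements `variables`,
#'   `terminals`, `rules` (list of `lhs`/`rhs` in file order), `start`, and
#'   precomputed tables used by the parser. Grammar objects are immutable;
#'   to parse with modified rules, load a new grammar.
#' @examples
#' g <- read_grammar(c("S -> 'a' | 'a' S"))
#' g$terminals
#' @export
read_grammar <- function(source) {
  stopifnot(is.character(source))
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE, encoding = "UTF-8")
  } else {
    source
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty grammar source", call. = FALSE)

  lhs_all <- character()
  rhs_all <- list()   # each element: character vector of raw symbols
  for (line in lines) {
    if (!grepl("->", line, fixed = TRUE)) {
      stop("grammar line without '->': ", line, call. = FALSE)
    }
    sides <- strsplit(line, "->", fixed = TRUE)[[1]]
    lhs <- trimws(sides[[1L]])
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", lhs)) {
      stop("invalid rule left-hand side: '", lhs, "'", call. = FALSE)
    }
    alts <- strsplit(trimws(sides[[2L]]), "|", fixed = TRUE)[[1]]
    for (alt in alts) {
      syms <- strsplit(trimws(alt), "[ \t]+")[[1]]
      syms <- syms[nzchar(syms)]
      if (length(syms) == 0L) {
        stop("empty alternative for '", lhs, "' (use EPSILON)", call. = FALSE)
      }
      if (any(syms == "EPSILON")) {
        if (length(syms) != 1L) {
          stop("EPSILON must stand alone in an alternative", call. = FALSE)
        }
        syms <- character()
      }
      lhs_all <- c(lhs_all, lhs)
      rhs_all <- c(rhs_all, list(syms))
    }
  }
  new_grammar(lhs_all, rhs_all)
}

new_grammar <- function(lhs_all, rhs_all) {
  variables <- unique(lhs_all)
  is_quoted <- function(s) grepl("^'.*'$", s)
  terminals <- character()
  rules <- vector("list", length(lhs_all))
  for (r in seq_along(lhs_all)) {
    rhs <- character(0)
    kind <- character(0)
    for (s in rhs_all[[r]]) {
      if (s == "ANY") {
        rhs <- c(rhs, "ANY"); kind <- c(kind, "any")
      } else if (is_quoted(s)) {
        t <- substr(s, 2L, nchar(s) - 1L)
        terminals <- union(terminals, t)
        rhs <- c(rhs, t); kind <- c(kind, "terminal")
      } else {
        if (!(s %in% variables)) {
          stop("undefined symbol '", s, "' on the right-hand side of '",
               lhs_all[[r]], "'", call. = FALSE)
        }
        rhs <- c(rhs, s); kind <- c(kind, "variable")
      }
    }
    rules[[r]] <- list(lhs = lhs_all[[r]], rhs = rhs, kind = kind)
  }
  clash <- intersect(variables, terminals)
  if (length(clash)) {
    stop("symbol(s) both variable and terminal: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }

  # integer encoding for the parser: variables 1..nv, terminals negative,
  # ANY = 0
  nv <- length(variables)
  enc <- function(rule) {
    vapply(seq_along(rule$rhs), function(i) {
      switch(rule$kind[i],
             variable = match(rule$rhs[i], variables),
             terminal = -match(rule$rhs[i], terminals),
             any = 0L)
    }, integer(1))
  }
  rhs_enc <- lapply(rules, enc)
  lhs_enc <- match(lhs_all, variables)
  rules_by_lhs <- lapply(seq_len(nv), function(v) which(lhs_enc == v))

  # nullable fixpoint
  nullable <- logical(nv)
  repeat {
    changed <- FALSE
    for (r in seq_along(rules)) {
      v <- lhs_enc[r]
      if (!nullable[v]) {
        e <- rhs_enc[[r]]
        if (length(e) == 0L || all(e > 0L & nullable[pmax(e, 1L)])) {
          nullable[v] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  structure(list(variables = variables,
                 terminals = terminals,
                 rules = rules,
                 start = lhs_all[[1L]],
                 lhs_enc = lhs_enc,
                 rhs_enc = rhs_enc,
                 rules_by_lhs = rules_by_lhs,
                 nullable = nullable),
            class = "cfg_grammar")
}

#' @export
print.cfg_grammar <- function(x, ...) {
  cat("<cfg_grammar> start:", x$start, "\n")
  cat("V =", paste(x$variables, collapse = ", "), "\n")
  cat("Sigma =", paste(x$terminals, collapse = ", "), "\n")
  for (r in x$rules) {
    rhs <- if (length(r$rhs) == 0L) "EPSILON" else {
      paste(ifelse(r$kind == "terminal", paste0("'", r$rhs, "'"), r$rhs),
            collapse = " ")
    }
    cat(" ", r$lhs, "->", rhs, "\n")
  }
  invisible(x)
}

#' The packaged EGFR result-sentence grammar
#'
#' Loads the grammar of EGFR result sentences: a start symbol deriving
#' location phrases joined by conjunctions and closed by a result word, with
#' optional specific results (deletion/insertion) attached on either side of a
#' location. With `extensions = TRUE` (the default) the grammar also accepts
#' the test-status sentence forms "insufficient DNA" and "test cancelled",
#' which the simplified core grammar cannot represent — disabling them
#' reproduces the failure mode in which cancelled tests are not extractable.
#'
#' @param extensions Include the insufficient-DNA / cancelled status
#'   productions?
#' @return A `cfg_grammar`.
#' @examples
#' g <- egfr_grammar()
#' parse_tokens(c("exon_19_location", "identified_result"), g)$accepted
#' @export
egfr_grammar <- function(extensions = TRUE) {
  f <- if (extensions) "egfr.cfg" else "egfr_core.cfg"
  read_grammar(system.file("extdata", f, package = "egfrparse",
                           mustWork = TRUE))
}

#' Enumerate the short strings of a grammar's language
#'
#' Computes, by derivation closure (a fixed-point over the production rules,
#' independent of any parsing algorithm), every terminal string of at most
#' `max_len` tokens derivable from the start symbol. Used as a brute-force
#' membership oracle against which the chart parser is checked.
#'
#' @param grammar A `cfg_grammar` without `ANY` wildcard elements.
#' @param max_len Maximum string length in tokens.
#' @return Sorted character vector; each element is a space-joined token
#'   string. The empty string is included when the start symbol is nullable.
#' @export
language_strings <- function(grammar, max_len) {
  stopifnot(inherits(grammar, "cfg_grammar"), max_len >= 0L)
  if (any(vapply(grammar$rules, function(r) any(r$kind == "any"), logical(1)))) {
    stop("language_strings() does not support ANY wildcard grammars",
         call. = FALSE)
  }
  n_tok <- function(s) ifelse(nzchar(s), lengths(strsplit(s, " ", fixed = TRUE)), 0L)
  join <- function(a, b) {
    out <- as.vector(outer(a, b, function(x, y) {
      ifelse(nzchar(x) & nzchar(y), paste(x, y), paste0(x, y))
    }))
    unique(out[n_tok(out) <= max_len])
  }
  nv <- length(grammar$variables)
  L <- rep(list(character()), nv)
  repeat {
    changed <- FALSE
    for (r in seq_along(grammar$rules)) {
      e <- grammar$rhs_enc[[r]]
      rule <- grammar$rules[[r]]
      strs <- ""
      ok <- TRUE
      for (i in seq_along(e)) {
        part <- if (e[i] > 0L) L[[e[i]]] else rule$rhs[i]
        if (length(part) == 0L) { ok <- FALSE; break }
        strs <- join(strs, part)
        if (length(strs) == 0L) { ok <- FALSE; break }
      }
      if (!ok) next
      v <- grammar$lhs_enc[r]
      new <- setdiff(strs, L[[v]])
      if (length(new)) {
        L[[v]] <- c(L[[v]], new)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(L[[match(grammar$start, grammar$variables)]])
}
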