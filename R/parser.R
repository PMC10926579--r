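#' Parse a token sequence with a context-free grammar
#'
#' An Earley chart parser: handles the left recursion and ambiguity present in
#' the result-sentence grammar (e.g. `S -> S Conjunction Location`), and
#' terminates on every input. When the token sequence is in the grammar's
#' language the canonical parse tree is returned (ties among derivations
#' broken by lowest rule index, then leftmost expansion with shortest-first
#' spans); otherwise the rejection records the 0-based index of the first
#' token at which no partial derivation survives (`length(tokens)` when the
#' input is a viable prefix that simply ends too early).
#'
#' @param tokens Character vector of terminal symbols (e.g. the `symbol`
#'   column of [tokenize()] output). Symbols outside the grammar's terminal
#'   alphabet are a contract violation and raise an error naming the symbol.
#' @param grammar A `cfg_grammar` from [read_grammar()] or [egfr_grammar()].
#' @return An object of class `cfg_parse`: list with `accepted` (logical),
#'   `tree` (a `parse_tree`, or `NULL` on rejection), `failure_index`
#'   (0-based, `NA` on acceptance), and `tokens`.
#' @examples
#' g <- egfr_grammar()
#' p <- parse_tokens(c("deletion_specific_result", "exon_19_location",
#'                     "identified_result"), g)
#' p$accepted
#' tree_leaves(p$tree)
#' @export
parse_tokens <- function(tokens, grammar) {
  stopifnot(inherits(grammar, "cfg_grammar"))
  tokens <- as.character(tokens)
  tok_enc <- -match(tokens, grammar$terminals)
  if (anyNA(tok_enc)) {
    has_any <- any(vapply(grammar$rules, function(r) any(r$kind == "any"),
                          logical(1)))
    if (!has_any) {
      stop("token symbol(s) outside the grammar's terminal alphabet: ",
           paste(unique(tokens[is.na(tok_enc)]), collapse = ", "),
           call. = FALSE)
    }
    # wildcard grammars admit out-of-alphabet tokens; give each a private
    # code no terminal element can equal, so only ANY matches it
    unk <- which(is.na(tok_enc))
    tok_enc[unk] <- -(length(grammar$terminals) +
                        match(tokens[unk], unique(tokens[unk])))
  }
  n <- length(tokens)
  nv <- length(grammar$variables)
  nr <- length(grammar$rules)
  rhs_len <- lengths(grammar$rhs_enc)
  maxd <- max(rhs_len, 1L)

  # item id: (r, d, o) -> offset into per-set seen vector
  id_of <- function(r, d, o) ((r - 1L) * (maxd + 1L) + d) * (n + 1L) + o + 1L
  id_space <- nr * (maxd + 1L) * (n + 1L) + n + 2L

  sets <- vector("list", n + 2L)       # each: int matrix rows (r, d, o)
  seen <- vector("list", n + 2L)
  counts <- integer(n + 2L)
  for (k in seq_len(n + 1L)) {
    sets[[k]] <- matrix(0L, nrow = 64L, ncol = 3L)
    seen[[k]] <- logical(id_space)
  }
  add <- function(k, r, d, o) {
    id <- id_of(r, d, o)
    if (seen[[k + 1L]][id]) return(invisible())
    seen[[k + 1L]][id] <<- TRUE
    m <- counts[k + 1L] + 1L
    if (m > nrow(sets[[k + 1L]])) {
      sets[[k + 1L]] <<- rbind(sets[[k + 1L]],
                               matrix(0L, nrow = nrow(sets[[k + 1L]]), ncol = 3L))
    }
    sets[[k + 1L]][m, ] <<- c(r, d, o)
    counts[k + 1L] <<- m
  }

  completed <- array(FALSE, dim = c(nv, n + 1L, n + 1L))  # [var, i+1, j+1]

  start_v <- match(grammar$start, grammar$variables)
  for (r in grammar$rules_by_lhs[[start_v]]) add(0L, r, 0L, 0L)

  failure_index <- NA_integer_
  for (k in 0:n) {
    if (counts[k + 1L] == 0L) {
      failure_index <- k - 1L
      break
    }
    p <- 1L
    while (p <= counts[k + 1L]) {
      it <- sets[[k + 1L]][p, ]
      r <- it[1L]; d <- it[2L]; o <- it[3L]
      if (d < rhs_len[r]) {
        e <- grammar$rhs_enc[[r]][d + 1L]
        if (e > 0L) {
          for (r2 in grammar$rules_by_lhs[[e]]) add(k, r2, 0L, k)
          if (grammar$nullable[e]) add(k, r, d + 1L, o)
        } else if (k < n && (e == 0L || e == tok_enc[k + 1L])) {
          add(k + 1L, r, d + 1L, o)
        }
      } else {
        v <- grammar$lhs_enc[r]
        completed[v, o + 1L, k + 1L] <- TRUE
        src <- sets[[o + 1L]]
        for (q in seq_len(counts[o + 1L])) {
          r2 <- src[q, 1L]; d2 <- src[q, 2L]
          if (d2 < rhs_len[r2] && grammar$rhs_enc[[r2]][d2 + 1L] == v) {
            add(k, r2, d2 + 1L, src[q, 3L])
          }
        }
      }
      p <- p + 1L
    }
  }

  accepted <- is.na(failure_index) && completed[start_v, 1L, n + 1L]
  if (n == 0L) accepted <- grammar$nullable[start_v]

  if (!accepted) {
    if (is.na(failure_index)) failure_index <- n
    return(structure(list(accepted = FALSE, tree = NULL,
                          failure_index = failure_index, tokens = tokens),
                     class = "cfg_parse"))
  }

  tree <- .build_tree(start_v, 0L, n, grammar, tokens, tok_enc, completed,
                      character())
  structure(list(accepted = TRUE, tree = tree, failure_index = NA_integer_,
                 tokens = tokens),
            class = "cfg_parse")
}

#' @export
print.cfg_parse <- function(x, ...) {
  if (x$accepted) {
    cat("<cfg_parse> accepted:", paste(x$tokens, collapse = " "), "\n")
    print(x$tree)
  } else {
    cat("<cfg_parse> rejected at token index", x$failure_index, ":",
        paste(x$tokens, collapse = " "), "\n")
  }
  invisible(x)
}

.leaf <- function(label) {
  structure(list(label = label, terminal = TRUE, children = list()),
            class = "parse_tree")
}
.node <- function(label, children) {
  structure(list(label = label, terminal = FALSE, children = children),
            class = "parse_tree")
}

# Canonical-tree construction over the chart of completed Earley items.
# `path` guards against same-(variable, span) recursion, which can only occur
# through epsilon-padding derivations; a minimal derivation never needs it.
.build_tree <- function(v, i, j, grammar, tokens, tok_enc, completed, path) {
  key <- paste0(v, ":", i, ":", j)
  if (key %in% path) return(NULL)
  path2 <- c(path, key)
  derivable <- function(e, a, b) {
    if (a == b) grammar$nullable[e] else completed[e, a + 1L, b + 1L]
  }
  for (r in grammar$rules_by_lhs[[v]]) {
    e <- grammar$rhs_enc[[r]]
    match_from <- function(idx, a) {
      if (idx > length(e)) {
        if (a == j) return(list()) else return(NULL)
      }
      el <- e[idx]
      if (el <= 0L) {  # terminal or ANY
        if (a < j && (el == 0L || el == tok_enc[a + 1L])) {
          rest <- match_from(idx + 1L, a + 1L)
          if (!is.null(rest)) return(c(list(.leaf(tokens[a + 1L])), rest))
        }
        return(NULL)
      }
      for (b in a:j) {
        if (derivable(el, a, b)) {
          child <- .build_tree(el, a, b, grammar, tokens, tok_enc, completed,
                               path2)
          if (!is.null(child)) {
            rest <- match_from(idx + 1L, b)
            if (!is.null(rest)) return(c(list(child), rest))
          }
        }
      }
      NULL
    }
    kids <- match_from(1L, i)
    if (!is.null(kids)) return(.node(grammar$variables[v], kids))
  }
  NULL
}

#' @export
print.parse_tree <- function(x, ..., indent = 0) {
  pad <- strrep("  ", indent)
  if (x$terminal) {
    cat(pad, "'", x$label, "'\n", sep = "")
  } else {
    cat(pad, x$label, if (length(x$children) == 0L) "  (epsilon)" else "", "\n",
        sep = "")
    for (ch in x$children) print(ch, indent = indent + 1)
  }
  invisible(x)
}

#' Terminal leaves of a parse tree
#'
#' The left-to-right terminal leaf sequence of a parse tree equals the parsed
#' token sequence; the leaves carry the extracted test result.
#'
#' @param tree A `parse_tree`.
#' @return Character vector of terminal symbols in source order.
#' @export
tree_leaves <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$terminal) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE) %||% character()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a parse tree against a grammar
#'
#' Checks soundness: every internal node is labeled with a grammar variable
#' and its ordered children labels match the right-hand side of one of that
#' variable's rules (the empty child list requires an epsilon rule); terminal
#' leaves carry terminal symbols; and, when `tokens` is given, the
#' left-to-right leaf sequence equals `tokens`.
#'
#' @param tree A `parse_tree`.
#' @param grammar A `cfg_grammar`.
#' @param tokens Optional token vector the tree should yield.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_parse_tree <- function(tree, grammar, tokens = NULL) {
  check <- function(node) {
    if (node$terminal) {
      if (!(node$label %in% grammar$terminals)) {
        stop("leaf label not a terminal: ", node$label, call. = FALSE)
      }
      return(invisible(TRUE))
    }
    if (!(node$label %in% grammar$variables)) {
      stop("internal node label not a variable: ", node$label, call. = FALSE)
    }
    kid_labels <- vapply(node$children, `[[`, "", "label")
    kid_term <- vapply(node$children, `[[`, NA, "terminal")
    ok <- FALSE
    for (r in grammar$rules) {
      if (r$lhs != node$label) next
      if (length(r$rhs) != length(kid_labels)) next
      if (length(r$rhs) == 0L) { ok <- TRUE; break }
      kinds <- ifelse(kid_term, "terminal", "variable")
      if (all(r$rhs == kid_labels | r$kind == "any") &&
          all(r$kind == kinds | r$kind == "any")) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("children of '", node$label, "' (",
           paste(kid_labels, collapse = " "), ") match no rule",
           call. = FALSE)
    }
    for (ch in node$children) check(ch)
    invisible(TRUE)
  }
  check(tree)
  if (!is.null(tokens) && !identical(tree_leaves(tree), as.character(tokens))) {
    stop("leaf sequence does not equal the token sequence", call. = FALSE)
  }
  invisible(TRUE)
}

#' Enumerate all parse trees of a token sequence
#'
#' Exhaustive (guarded) derivation enumeration, used to check that extraction
#' is invariant across the derivations of an ambiguous sentence. Only
#' practical for short token sequences.
#'
#' @inheritParams parse_tokens
#' @param max_trees Stop after this many trees.
#' @return List of `parse_tree` objects (empty if the sequence is rejected).
#' @export
all_parse_trees <- function(tokens, grammar, max_trees = 100L) {
  tokens <- as.character(tokens)
  p <- parse_tokens(tokens, grammar)
  if (!p$accepted) return(list())
  n <- length(tokens)
  tok_enc <- -match(tokens, grammar$terminals)
  if (anyNA(tok_enc)) {
    unk <- which(is.na(tok_enc))
    tok_enc[unk] <- -(length(grammar$terminals) +
                        match(tokens[unk], unique(tokens[unk])))
  }

  enum_var <- function(v, i, j, path) {
    key <- paste0(v, ":", i, ":", j)
    if (key %in% path) return(list())
    path2 <- c(path, key)
    trees <- list()
    for (r in grammar$rules_by_lhs[[v]]) {
      e <- grammar$rhs_enc[[r]]
      seqs <- enum_seq(e, 1L, i, j, path2)
      for (kids in seqs) {
        trees[[length(trees) + 1L]] <- .node(grammar$variables[v], kids)
        if (length(trees) >= max_trees) return(trees)
      }
    }
    trees
  }
  enum_seq <- function(e, idx, a, j, path) {
    if (idx > length(e)) {
      if (a == j) return(list(list())) else return(list())
    }
    el <- e[idx]
    res <- list()
    if (el <= 0L) {
      ok <- a < j && (el == 0L || el == tok_enc[a + 1L])
      if (ok) {
        for (rest in enum_seq(e, idx + 1L, a + 1L, j, path)) {
          res[[length(res) + 1L]] <- c(list(.leaf(tokens[a + 1L])), rest)
        }
      }
      return(res)
    }
    for (b in a:j) {
      subs <- enum_var(el, a, b, path)
      if (length(subs) == 0L) next
      rests <- enum_seq(e, idx + 1L, b, j, path)
      for (s in subs) for (rest in rests) {
        res[[length(res) + 1L]] <- c(list(s), rest)
      }
    }
    res
  }

  start_v <- match(grammar$start, grammar$variables)
  enum_var(start_v, 0L, n, character())
}
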