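#' @title A tree-pattern mini-language over constituency parses
#' @description
#' A small tgrep-style language sufficient to express clause-level
#' extraction patterns. A pattern is anchored at one node and constrains
#' it through relations to other nodes:
#'
#' * node term: a bare label literal (`NP`, `VBZ`) matched exactly, or a
#'   `/regex/` matched against the node label (word leaves have their
#'   token as label, so regexes also match tokens); Perl syntax, so
#'   `(?i)` gives case-insensitive matching
#' * relations: `<` immediate child, `<<` proper descendant, `<:` sole
#'   child, `$` following sibling, `.` immediately precedes (leaf
#'   adjacency)
#' * `!` before a relation negates it; `and` conjoins either additional
#'   relations on the same anchor or whole patterns that must hold at
#'   the same anchor node
#' * `=name` after a term declares a named capture
#'
#' Example: `VP < (VBZ=trig <: /^phosphorylat/) and VP < NP=arg` matches
#' a VP with a VBZ child whose word starts with "phosphorylat" and an NP
#' child, capturing both.
#' @name tree_pattern
NULL

#' Compile a tree-pattern expression
#'
#' @param expr pattern string in the mini-language (see [tree_pattern])
#' @return an object of class `tree_pattern` holding the compiled AST
#' @export
compile_pattern <- function(expr) {
  toks <- tp_lex(expr)
  st <- tp_parse_conj(toks, 1L, expr)
  if (st$pos <= length(toks)) {
    tp_err(expr, toks[[st$pos]]$at, "unexpected trailing input")
  }
  # the same capture name may appear in several conjuncts (it must then
  # bind the same node in any one match)
  caps <- unique(tp_captures(st$node))
  structure(list(expression = expr, ast = st$node, captures = caps),
            class = "tree_pattern")
}

#' @export
print.tree_pattern <- function(x, ...) {
  cat("<tree_pattern> ", x$expression, "\n", sep = "")
  invisible(x)
}

tp_err <- function(expr, at, msg) {
  stop("pattern syntax error at position ", at, ": ", msg,
       "\n  in: ", expr, call. = FALSE)
}

# lexer -------------------------------------------------------------------

tp_lex <- function(expr) {
  toks <- list()
  i <- 1L; n <- nchar(expr)
  push <- function(type, value, at) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, at = at)
  }
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    two <- substr(expr, i, i + 1L)
    if (two %in% c("<<", "<:")) { push("op", two, i); i <- i + 2L; next }
    if (ch %in% c("<", "$", ".")) { push("op", ch, i); i <- i + 1L; next }
    if (ch == "!") { push("neg", ch, i); i <- i + 1L; next }
    if (ch == "(") { push("lparen", ch, i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ch, i); i <- i + 1L; next }
    if (ch == "/") {
      j <- i + 1L
      while (j <= n && substr(expr, j, j) != "/") {
        if (substr(expr, j, j) == "\\") j <- j + 1L
        j <- j + 1L
      }
      if (j > n) tp_err(expr, i, "unterminated /regex/")
      push("regex", substr(expr, i + 1L, j - 1L), i)
      i <- j + 1L
      next
    }
    if (ch == "=") {
      m <- regmatches(substr(expr, i, n),
                      regexpr("^=[A-Za-z][A-Za-z0-9_]*", substr(expr, i, n)))
      if (!length(m)) tp_err(expr, i, "expected capture name after '='")
      push("capture", substr(m, 2L, nchar(m)), i)
      i <- i + nchar(m)
      next
    }
    m <- regmatches(substr(expr, i, n),
                    regexpr("^[A-Za-z0-9_*?^-]+", substr(expr, i, n)))
    if (!length(m)) tp_err(expr, i, paste0("unexpected character '", ch, "'"))
    if (m == "and") push("and", m, i) else push("label", m, i)
    i <- i + nchar(m)
  }
  toks
}

# parser ------------------------------------------------------------------

tp_peek <- function(toks, pos) if (pos <= length(toks)) toks[[pos]] else NULL

tp_parse_conj <- function(toks, pos, expr) {
  st <- tp_parse_pattern(toks, pos, expr)
  pats <- list(st$node)
  pos <- st$pos
  while (!is.null(t <- tp_peek(toks, pos)) && t$type == "and") {
    st <- tp_parse_pattern(toks, pos + 1L, expr)
    pats[[length(pats) + 1L]] <- st$node
    pos <- st$pos
  }
  node <- if (length(pats) == 1L) pats[[1L]] else list(type = "conj", pats = pats)
  list(node = node, pos = pos)
}

tp_parse_pattern <- function(toks, pos, expr) {
  st <- tp_parse_unit(toks, pos, expr)
  node <- st$node
  pos <- st$pos
  rels <- list()
  repeat {
    t <- tp_peek(toks, pos)
    neg <- FALSE
    if (!is.null(t) && t$type == "neg") {
      neg <- TRUE
      t <- tp_peek(toks, pos + 1L)
      if (is.null(t) || t$type != "op") {
        tp_err(expr, toks[[pos]]$at, "'!' must precede a relation operator")
      }
      pos <- pos + 1L
    }
    if (is.null(t) || t$type != "op") break
    op <- t$value
    st <- tp_parse_operand(toks, pos + 1L, expr)
    rels[[length(rels) + 1L]] <- list(neg = neg, op = op, target = st$node)
    pos <- st$pos
  }
  if (node$type == "conj") {
    if (length(rels)) tp_err(expr, toks[[pos - 1L]]$at,
                             "relations cannot attach to a parenthesized conjunction")
  } else {
    node$rels <- c(node$rels, rels)
  }
  list(node = node, pos = pos)
}

tp_parse_operand <- function(toks, pos, expr) {
  t <- tp_peek(toks, pos)
  if (is.null(t)) tp_err(expr, nchar(expr), "expected operand")
  if (t$type == "lparen") {
    st <- tp_parse_conj(toks, pos + 1L, expr)
    t2 <- tp_peek(toks, st$pos)
    if (is.null(t2) || t2$type != "rparen") {
      tp_err(expr, t$at, "unbalanced '(' in pattern")
    }
    return(list(node = st$node, pos = st$pos + 1L))
  }
  tp_parse_term(toks, pos, expr)
}

tp_parse_unit <- function(toks, pos, expr) {
  t <- tp_peek(toks, pos)
  if (is.null(t)) tp_err(expr, nchar(expr), "expected a node term")
  if (t$type == "lparen") return(tp_parse_operand(toks, pos, expr))
  tp_parse_term(toks, pos, expr)
}

tp_parse_term <- function(toks, pos, expr) {
  t <- tp_peek(toks, pos)
  if (is.null(t) || !(t$type %in% c("label", "regex"))) {
    tp_err(expr, if (is.null(t)) nchar(expr) else t$at,
           "expected a label or /regex/ term")
  }
  node <- list(type = "pat",
               term = list(kind = t$type, value = t$value, capture = NULL),
               rels = list())
  pos <- pos + 1L
  t2 <- tp_peek(toks, pos)
  if (!is.null(t2) && t2$type == "capture") {
    node$term$capture <- t2$value
    pos <- pos + 1L
  }
  list(node = node, pos = pos)
}

tp_captures <- function(node) {
  if (node$type == "conj") {
    return(unlist(lapply(node$pats, tp_captures)) %||% character())
  }
  out <- if (!is.null(node$term$capture)) node$term$capture else character()
  for (r in node$rels) out <- c(out, tp_captures(r$target))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# matcher -----------------------------------------------------------------

tp_term_ok <- function(idx, i, term) {
  if (term$kind == "label") {
    identical(idx$label[i], term$value)
  } else {
    grepl(term$value, idx$label[i], perl = TRUE)
  }
}

tp_candidates <- function(idx, i, op) {
  switch(op,
    "<"  = idx$children[[i]],
    "<<" = idx_descendants(idx, i),
    "<:" = { k <- idx$children[[i]]; if (length(k) == 1L) k else integer() },
    "$"  = {
      p <- idx$parent[i]
      if (is.na(p)) integer() else {
        sibs <- idx$children[[p]]
        sibs[sibs > i & seq_along(sibs) > match(i, sibs)]
      }
    },
    "."  = {
      nxt <- idx$last_leaf[i] + 1L
      which(idx$first_leaf == nxt & idx$last_leaf >= nxt)
    },
    stop("unknown relation operator: ", op)
  )
}

# Returns a list of bindings (each a named integer vector capture -> id),
# empty list if no match. A match with no captures yields list(integer()).
tp_match_at <- function(idx, i, node) {
  if (node$type == "conj") {
    acc <- list(integer())
    for (p in node$pats) {
      bs <- tp_match_at(idx, i, p)
      if (!length(bs)) return(list())
      acc <- tp_cross(acc, bs)
    }
    return(acc)
  }
  if (!tp_term_ok(idx, i, node$term)) return(list())
  base <- integer()
  if (!is.null(node$term$capture)) {
    base <- stats::setNames(i, node$term$capture)
  }
  acc <- list(base)
  for (r in node$rels) {
    cand <- tp_candidates(idx, i, r$op)
    if (r$neg) {
      hit <- FALSE
      for (j in cand) {
        if (length(tp_match_at(idx, j, r$target))) { hit <- TRUE; break }
      }
      if (hit) return(list())
    } else {
      step <- list()
      for (j in cand) {
        bs <- tp_match_at(idx, j, r$target)
        if (length(bs)) step <- c(step, bs)
      }
      if (!length(step)) return(list())
      acc <- tp_cross(acc, step)
    }
  }
  acc
}

tp_cross <- function(as, bs) {
  out <- vector("list", length(as) * length(bs))
  k <- 0L
  for (a in as) for (b in bs) {
    k <- k + 1L
    out[[k]] <- c(a, b)
  }
  out
}

#' Match a compiled pattern everywhere in a tree
#'
#' Tests the pattern at every node in pre-order and returns one
#' `tree_match` per distinct (anchor, capture bindings) combination, in
#' document order of the anchor node.
#'
#' @param pattern a `tree_pattern` from [compile_pattern()], or a string
#' @param tree a `parse_tree`, or a prebuilt index from [tree_index()]
#' @return a list of `tree_match` objects with fields `anchor` (node id),
#'   `bindings` (named list of `parse_tree` nodes) and `ids` (named
#'   integer vector of node ids)
#' @export
match_all <- function(pattern, tree) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  idx <- if (inherits(tree, "parse_tree")) tree_index(tree) else tree
  out <- list()
  seen <- character()
  for (i in seq_along(idx$label)) {
    bs <- tp_match_at(idx, i, pattern$ast)
    for (b in bs) {
      if (anyDuplicated(names(b))) {
        # duplicated capture names must agree on the bound node
        ok <- all(vapply(unique(names(b)), function(nm) {
          length(unique(b[names(b) == nm])) == 1L
        }, logical(1)))
        if (!ok) next
      }
      b <- b[unique(names(b))]
      key <- paste(i, paste(names(b), b, sep = "=", collapse = ","))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- structure(
        list(anchor = i,
             ids = b,
             bindings = stats::setNames(lapply(b, function(j) idx$nodes[[j]]),
                                        names(b))),
        class = "tree_match")
    }
  }
  out
}
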