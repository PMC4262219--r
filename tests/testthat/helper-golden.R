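# Shared fixtures for the test suite: hand-built gold parse trees for
# the worked examples, an independent brute-force tree-matcher oracle,
# and random tree/pattern generators for property tests.

golden_specs <- function() {
  parse_trigger_spec(paste(
    fixture_spec_text(),
    "",
    "trigger: dimerize",
    "relation: Binding",
    "frame: NP0/NP1",
    "type: NP0 = GGP|protein_part",
    "type: NP1 = GGP|protein_part",
    "role: NP0 = theme",
    "role: NP1 = theme",
    "direction: non-directional",
    "",
    "trigger: express",
    "relation: Transcription",
    "frame: NP0/NP1",
    "type: NP0 = GGP",
    "type: NP1 = GGP|rna",
    "role: NP0 = agent",
    "role: NP1 = theme",
    "guard: NP1 ~ mRNA",
    "direction: directional",
    sep = "\n"))
}

golden_patterns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- compile_specs(golden_specs())
    cache
  }
})

# build a one-sentence document with pre-annotated mentions located by
# their surface strings
golden_doc <- function(sentence, parse, mention_texts, links = list()) {
  tree <- read_bracketed(parse, sentence)
  mentions <- list()
  for (k in seq_along(mention_texts)) {
    at <- regexpr(mention_texts[k], sentence, fixed = TRUE)
    stopifnot(at > 0)
    mentions[[k]] <- patrex:::new_entity_mention(
      c(at - 1L, at - 1L + attr(at, "match.length")),
      mention_texts[k], "GGP", "preannotated", id = paste0("T", k))
  }
  make_document(sentence,
                list(list(text = sentence, start = 0L, tree = tree)),
                mentions, links)
}

event_summary <- function(events) {
  vapply(events, function(e) {
    th <- sort(vapply(e$args$theme, function(m) m$text, character(1)))
    ag <- sort(vapply(e$args$agent, function(m) m$text, character(1)))
    paste0(e$relation, "(", e$trigger_form,
           ": theme=", paste(th, collapse = "+"),
           if (length(ag)) paste0(", agent=", paste(ag, collapse = "+")),
           ")")
  }, character(1))
}

# ---- independent brute-force matcher oracle ------------------------------
# Evaluates a compiled pattern AST at every node of a plain parse_tree by
# direct recursion, without the package's index-based engine.

oracle_anchors <- function(expr, tree) {
  ast <- compile_pattern(expr)$ast
  # enumerate nodes with explicit parent/sibling bookkeeping
  nodes <- list()
  walk <- function(node, parent_id) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(node = node, parent = parent_id, kids = integer())
    if (!is_leaf(node)) {
      for (ch in node$children) {
        cid <- walk(ch, id)
        nodes[[id]]$kids <<- c(nodes[[id]]$kids, cid)
      }
    }
    id
  }
  walk(tree, NA_integer_)
  # leaf order
  leaf_order <- integer(length(nodes))
  cnt <- 0L
  for (i in seq_along(nodes)) {
    if (is_leaf(nodes[[i]]$node)) { cnt <- cnt + 1L; leaf_order[i] <- cnt }
  }
  span_leaves <- function(i) {
    if (is_leaf(nodes[[i]]$node)) return(c(leaf_order[i], leaf_order[i]))
    ks <- nodes[[i]]$kids
    c(span_leaves(ks[1])[1], span_leaves(ks[length(ks)])[2])
  }
  term_ok <- function(i, term) {
    lab <- nodes[[i]]$node$label
    if (term$kind == "label") identical(lab, term$value)
    else grepl(term$value, lab, perl = TRUE)
  }
  descendants <- function(i) {
    ks <- nodes[[i]]$kids
    out <- ks
    for (k in ks) out <- c(out, descendants(k))
    out
  }
  holds <- function(i, pat) {
    if (pat$type == "conj") return(all(vapply(pat$pats, function(p)
      holds(i, p), logical(1))))
    if (!term_ok(i, pat$term)) return(FALSE)
    for (r in pat$rels) {
      cand <- switch(r$op,
        "<" = nodes[[i]]$kids,
        "<<" = descendants(i),
        "<:" = if (length(nodes[[i]]$kids) == 1L) nodes[[i]]$kids else integer(),
        "$" = {
          p <- nodes[[i]]$parent
          if (is.na(p)) integer() else {
            sibs <- nodes[[p]]$kids
            sibs[seq_along(sibs) > match(i, sibs)]
          }
        },
        "." = {
          me <- span_leaves(i)
          which(vapply(seq_along(nodes), function(j)
            span_leaves(j)[1] == me[2] + 1L, logical(1)))
        })
      any_hit <- any(vapply(cand, function(j) holds(j, r$target), logical(1)))
      if (r$neg && any_hit) return(FALSE)
      if (!r$neg && !any_hit) return(FALSE)
    }
    TRUE
  }
  which(vapply(seq_along(nodes), function(i) holds(i, ast), logical(1)))
}

# random small trees for matcher property tests
random_tree <- function(max_depth = 4L) {
  labels <- c("S", "NP", "VP", "PP", "X")
  pre <- c("NN", "VB", "IN", "DT")
  words <- c("alpha", "beta", "gamma", "delta")
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.35) {
      return(new_parse_tree(sample(pre, 1),
                            children = list({
                              w <- sample(words, 1)
                              new_parse_tree(w, token = w)
                            })))
    }
    n <- sample(1:3, 1)
    new_parse_tree(sample(labels, 1),
                   children = lapply(seq_len(n), function(i)
                     build(depth + 1L)))
  }
  tree <- build(1L)
  leaves <- patrex:::collect_leaves(tree)
  sent <- paste(vapply(leaves, function(l) l$token, character(1)),
                collapse = " ")
  patrex:::align_spans(tree, sent)
}

oracle_patterns <- c(
  "NP", "NP < NN", "S << /^V/", "NP <: NN", "NP $ VP", "NN . VB",
  "NP !< NN", "VP < NP and VP < /^V/", "S < (NP < NN) and S < VP",
  "/^(NP|VP)$/ << /alpha/", "NP !<< /beta/", "X < /^NN$/"
)

# enumerative oracle for the approximate span rule: try every extension
# of the gold span by zero or one token on each side and test containment
oracle_approx <- function(pred, gold, tokens) {
  starts <- vapply(tokens, `[`, numeric(1), 1)
  ends <- vapply(tokens, `[`, numeric(1), 2)
  left_opts <- gold[1]
  prev <- which(ends <= gold[1])
  if (length(prev)) left_opts <- c(left_opts, starts[prev[which.max(ends[prev])]])
  right_opts <- gold[2]
  nxt <- which(starts >= gold[2])
  if (length(nxt)) right_opts <- c(right_opts, ends[nxt[which.min(starts[nxt])]])
  for (a in left_opts) for (b in right_opts) {
    if (pred[1] >= a && pred[2] <= b) return(TRUE)
  }
  FALSE
}

random_layout <- function() {
  n <- sample(3:12, 1)
  gaps <- sample(1:3, n, replace = TRUE)
  lens <- sample(1:8, n, replace = TRUE)
  starts <- cumsum(c(0, (lens + gaps)[-n]))
  tokens <- lapply(seq_len(n), function(i) c(starts[i], starts[i] + lens[i]))
  total <- starts[n] + lens[n]
  a <- sample(0:(total - 1), 1)
  b <- sample((a + 1):total, 1)
  g1 <- sample(0:(total - 1), 1)
  g2 <- sample((g1 + 1):total, 1)
  list(tokens = tokens, pred = c(a, b), gold = c(g1, g2))
}
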