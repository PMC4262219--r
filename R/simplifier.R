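#' @title Sentence simplification by tree surgery
#' @description
#' Complex constructs -- coordinations, full and reduced relative
#' clauses, appositions, and parenthesized elements -- hide the simple
#' clause shapes that lexico-syntactic patterns match. The simplifier
#' detects these constructs in a parse and emits simplified sentence
#' variants: one variant per conjunct for a coordination, a
#' clause-removed variant plus a "referent + clause" sentence for a
#' relative clause, a referent-only variant plus an in-place
#' substitution for appositions and parentheticals. Variants are
#' produced by tree surgery on the input parse (no re-parsing), each
#' with a per-character offset map back to the original sentence so
#' extracted spans can be reported in original coordinates.
#' @name simplifier
NULL

.rel_pronouns <- c("which", "who", "that", "whom", "whose")
.determiners <- c("the", "a", "an", "this", "these", "that", "those",
                  "its", "their", "one", "two", "three")

new_construct <- function(kind, anchor, parts, referent = NA_integer_) {
  structure(list(kind = kind, anchor = anchor, parts = parts,
                 referent = referent),
            class = "construct")
}

#' Detect complex constructs in a parse tree
#'
#' Finds all coordinations, full and reduced relative clauses,
#' appositions and parenthesized elements, including nested ones.
#' Appositions require the second noun phrase to begin with a determiner
#' or a number and must not be conjuncts of a coordination.
#'
#' @param tree a `parse_tree` (or prebuilt index)
#' @return list of `construct` objects; `anchor`, `parts` and `referent`
#'   are node ids into `tree_index(tree)`
#' @export
detect_constructs <- function(tree) {
  idx <- if (inherits(tree, "parse_tree")) tree_index(tree) else tree
  out <- list()
  for (i in seq_along(idx$label)) {
    if (!is.na(idx$token[i])) next
    kids <- idx$children[[i]]
    labs <- idx$label[kids]

    # ---- coordination
    ccpos <- which(labs == "CC")
    if (length(ccpos)) {
      cls <- label_class(labs)
      subst <- which(!labs %in% c("CC", ",", ":", "CONJP", "``", "''") &
                       cls != "other")
      before <- subst[subst < ccpos[1L]]
      if (length(before) && length(subst) >= 2L) {
        ref_cls <- cls[before[length(before)]]
        conj <- subst[cls[subst] == ref_cls]
        if (length(conj) >= 2L) {
          out[[length(out) + 1L]] <-
            new_construct("coordination", i, as.list(kids[conj]))
        }
      }
    }

    # ---- relative clauses and appositions hang off NPs
    if (idx$label[i] %in% c("NP", "NX", "NML")) {
      for (k in seq_along(kids)) {
        kid <- kids[k]
        ref <- ref_before(idx, kids, k)
        if (idx$label[kid] == "SBAR") {
          fl <- idx$leaves[idx$first_leaf[kid]]
          if (tolower(idx$token[fl]) %in% .rel_pronouns && !is.na(ref)) {
            out[[length(out) + 1L]] <-
              new_construct("relative_clause_full", i, list(kid), ref)
          }
        }
        if (idx$label[kid] == "VP" && !is.na(ref)) {
          first_pre <- idx$parent[idx$leaves[idx$first_leaf[kid]]]
          if (idx$label[first_pre] %in% c("VBN", "VBG")) {
            out[[length(out) + 1L]] <-
              new_construct("relative_clause_reduced", i, list(kid), ref)
          }
        }
      }
      # apposition: NP , NP(det/number-initial) with no CC among the kids
      if (!any(labs == "CC")) {
        npk <- which(labs == "NP")
        if (length(npk) >= 2L) {
          for (j in npk[-1L]) {
            prev <- j - 1L
            if (prev < 1L || labs[prev] != ",") next
            first <- which(npk < j)
            if (!length(first)) next
            ref <- kids[npk[first[length(first)]]]
            app <- kids[j]
            fl <- idx$leaves[idx$first_leaf[app]]
            ftok <- tolower(idx$token[fl])
            fpre <- idx$label[idx$parent[fl]]
            if (ftok %in% .determiners || fpre == "CD" ||
                grepl("^[0-9]", ftok)) {
              out[[length(out) + 1L]] <-
                new_construct("apposition", i, list(app), ref)
            }
          }
        }
      }
    }

    # ---- parenthesized elements
    ktoks <- vapply(kids, function(k) {
      tk <- leaf_token(idx, k)
      if (is.na(tk)) "" else tk
    }, character(1))
    open <- which(ktoks %in% c("(", "[", "{", "-LRB-", "-LSB-", "-LCB-") |
                    labs %in% c("-LRB-", "-LSB-", "-LCB-"))
    if (length(open)) {
      for (o in open) {
        close <- which(seq_along(kids) > o &
                         (labs %in% c("-RRB-", "-RSB-", "-RCB-") |
                            ktoks %in% c(")", "]", "}", "-RRB-", "-RSB-",
                                         "-RCB-")))
        if (!length(close)) next
        cl <- close[1L]
        if (cl - o < 2L) next
        content <- kids[(o + 1L):(cl - 1L)]
        ref <- ref_before(idx, kids, o)
        out[[length(out) + 1L]] <-
          new_construct("parenthetical", i,
                        c(as.list(content),
                          list(brackets = kids[c(o, cl)])), ref)
        break  # one bracketed group per node is enough per pass
      }
    }
  }
  out
}

leaf_or_na <- function(k, idx) {
  tk <- leaf_token(idx, k)
  if (is.na(tk)) NA_character_ else tk
}

# token of a preterminal (single word child) or a word leaf, else NA
leaf_token <- function(idx, k) {
  if (!is.na(idx$token[k])) return(idx$token[k])
  kk <- idx$children[[k]]
  if (length(kk) == 1L && !is.na(idx$token[kk])) return(idx$token[kk])
  NA_character_
}

label_class <- function(labs) {
  ifelse(labs %in% c("NP", "NX", "NML", "NN", "NNS", "NNP", "NNPS"), "np",
  ifelse(labs == "VP", "vp",
  ifelse(grepl("^VB", labs), "vb",
  ifelse(labs %in% c("S", "SBAR"), "s",
  ifelse(labs %in% c("ADJP", "JJ"), "adj", "other")))))
}

ref_before <- function(idx, kids, k) {
  if (k <= 1L) return(NA_integer_)
  before <- kids[seq_len(k - 1L)]
  nps <- before[idx$label[before] %in% c("NP", "NX", "NML")]
  if (!length(nps)) NA_integer_ else nps[length(nps)]
}

# ---- variants ------------------------------------------------------------

new_variant <- function(text, tree, offset_map, provenance = character(),
                        attachment_choice = NA_character_) {
  structure(list(text = text, tree = tree, offset_map = offset_map,
                 provenance = provenance,
                 attachment_choice = attachment_choice),
            class = "sentence_variant")
}

#' @export
print.sentence_variant <- function(x, ...) {
  cat("<variant> '", x$text, "'",
      if (length(x$provenance)) paste0("  [", paste(x$provenance,
                                                    collapse = " > "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Wrap a sentence and its parse as the identity variant
#' @param tree a `parse_tree` with spans into `sentence`
#' @param sentence the original sentence text
#' @return a `sentence_variant` whose offset map is the identity
#' @export
identity_variant <- function(tree, sentence) {
  new_variant(sentence, tree, seq_len(nchar(sentence)) - 1L)
}

# Rebuild a variant from a surgered tree whose leaf spans still point
# into the parent variant's coordinates; glue leaves have NA spans.
variant_from_tree <- function(tree, parent, provenance,
                              attachment_choice = NA_character_) {
  leaves <- collect_leaves(tree)
  toks <- vapply(leaves, function(l) l$token, character(1))
  text <- paste(toks, collapse = " ")
  omap <- rep(NA_integer_, nchar(text))
  pos <- 0L
  spans <- vector("list", length(leaves))
  for (k in seq_along(leaves)) {
    n <- nchar(toks[k])
    spans[[k]] <- c(pos, pos + n)
    l <- leaves[[k]]
    if (!is.na(l$start)) {
      src <- seq.int(l$start, length.out = min(n, l$end - l$start)) + 1L
      dst <- seq.int(pos + 1L, length.out = length(src))
      omap[dst] <- parent$offset_map[src]
    }
    pos <- pos + n + 1L
  }
  k <- 0L
  respan <- function(node) {
    if (is_leaf(node)) {
      k <<- k + 1L
      node$start <- spans[[k]][1L]; node$end <- spans[[k]][2L]
      return(node)
    }
    node$children <- lapply(node$children, respan)
    node$start <- node$children[[1L]]$start
    node$end <- node$children[[length(node$children)]]$end
    node
  }
  tree <- respan(tree)
  new_variant(text, tree, omap, c(parent$provenance, provenance),
              attachment_choice)
}

collect_leaves <- function(tree) {
  if (is_leaf(tree)) return(list(tree))
  do.call(c, lapply(tree$children, collect_leaves))
}

# Copy a tree applying surgery operations keyed by pre-order node ids:
# delete (drop the subtree) and replace (substitute another subtree).
# Returns NULL if everything under a node was deleted.
surgery <- function(tree, delete = integer(), replace = list()) {
  counter <- new.env(parent = emptyenv()); counter$k <- 0L
  walk <- function(node) {
    counter$k <- counter$k + 1L
    id <- counter$k
    rep <- replace[[as.character(id)]]
    del <- id %in% delete
    if (!is_leaf(node)) {
      kids <- lapply(node$children, walk)  # keep the id numbering aligned
      if (del) return(NULL)
      if (!is.null(rep)) return(rep)
      kids <- kids[!vapply(kids, is.null, logical(1))]
      if (!length(kids)) return(NULL)
      node$children <- kids
      return(node)
    }
    if (del) return(NULL)
    if (!is.null(rep)) return(rep)
    node
  }
  walk(tree)
}

glue_leaf <- function(token, pos_label) {
  new_parse_tree(pos_label,
                 children = list(new_parse_tree(token, token = token)))
}

# adjacent comma children of `parent_kids` around position `at`
comma_neighbors <- function(idx, parent, node) {
  kids <- idx$children[[parent]]
  at <- match(node, kids)
  out <- integer()
  if (!is.na(at)) {
    if (at > 1L && idx$label[kids[at - 1L]] == ",") out <- c(out, kids[at - 1L])
    if (at < length(kids) && idx$label[kids[at + 1L]] == ",") {
      out <- c(out, kids[at + 1L])
    }
  }
  out
}

# rewrite one construct into child variants
rewrite_construct <- function(v, con, idx) {
  tree <- v$tree
  out <- list()
  if (con$kind == "coordination") {
    conj <- unlist(con$parts)
    kids <- idx$children[[con$anchor]]
    glue_ids <- kids[idx$label[kids] %in% c("CC", ",", "CONJP")]
    for (c1 in conj) {
      del <- c(setdiff(conj, c1), glue_ids)
      t2 <- surgery(tree, delete = del)
      if (is.null(t2)) next
      out[[length(out) + 1L]] <-
        variant_from_tree(t2, v, "coordination")
    }
  } else if (con$kind %in% c("relative_clause_full",
                             "relative_clause_reduced")) {
    sbar <- con$parts[[1L]]
    del <- c(sbar, comma_neighbors(idx, con$anchor, sbar))
    t2 <- surgery(tree, delete = del)
    if (!is.null(t2)) {
      out[[length(out) + 1L]] <- variant_from_tree(t2, v, "relative_clause")
    }
    t3 <- relative_clause_sentence(idx, con)
    if (!is.null(t3)) {
      out[[length(out) + 1L]] <- variant_from_tree(t3, v, "relative_clause")
    }
  } else if (con$kind == "apposition") {
    app <- con$parts[[1L]]
    del <- c(app, comma_neighbors(idx, con$anchor, app))
    t2 <- surgery(tree, delete = del)
    if (!is.null(t2)) {
      out[[length(out) + 1L]] <- variant_from_tree(t2, v, "apposition")
    }
    # appositive replaces the referent in place
    del2 <- c(con$referent, comma_neighbors(idx, con$anchor, app))
    t3 <- surgery(tree, delete = del2)
    if (!is.null(t3)) {
      out[[length(out) + 1L]] <- variant_from_tree(t3, v, "apposition")
    }
  } else if (con$kind == "parenthetical") {
    br <- con$parts$brackets
    content <- unlist(con$parts[names(con$parts) != "brackets"])
    t2 <- surgery(tree, delete = c(br, content))
    if (!is.null(t2)) {
      out[[length(out) + 1L]] <- variant_from_tree(t2, v, "parenthetical")
    }
    if (!is.na(con$referent)) {
      t3 <- surgery(tree, delete = c(br, con$referent))
      if (!is.null(t3)) {
        out[[length(out) + 1L]] <- variant_from_tree(t3, v, "parenthetical")
      }
    }
  }
  out
}

# build "referent + relative clause" as its own sentence
relative_clause_sentence <- function(idx, con) {
  sbar <- con$parts[[1L]]
  ref_tree <- idx$nodes[[con$referent]]
  if (con$kind == "relative_clause_reduced") {
    vp <- idx$nodes[[sbar]]
    first_pre <- idx$label[idx$parent[idx$leaves[idx$first_leaf[sbar]]]]
    if (first_pre == "VBN") {
      vp <- new_parse_tree("VP", list(glue_leaf("was", "VBD"), vp))
    }
    return(new_parse_tree("S", list(ref_tree, vp)))
  }
  kids <- idx$children[[sbar]]
  s <- kids[idx$label[kids] == "S"]
  if (!length(s)) return(NULL)
  sk <- idx$children[[s[1L]]]
  vpk <- which(idx$label[sk] == "VP")
  if (!length(vpk)) return(NULL)
  before <- sk[seq_len(vpk[1L] - 1L)]
  if (any(idx$label[before] == "NP")) return(NULL)  # object relative
  body <- lapply(sk[vpk[1L]:length(sk)], function(j) idx$nodes[[j]])
  adv <- before[idx$label[before] %in% c("ADVP", "PP")]
  pre <- lapply(adv, function(j) idx$nodes[[j]])
  new_parse_tree("S", c(list(ref_tree), pre, body))
}

#' Simplify a sentence into a set of variants
#'
#' Recursively expands the detected constructs: the result includes the
#' original sentence itself, every partially simplified sentence, and
#' the fully simplified ones, deduplicated by surface text. Expansion is
#' capped at `max_variants` variants (with a warning on truncation).
#'
#' @param tree a `parse_tree`
#' @param constructs result of [detect_constructs()] on the same tree
#' @param sentence the original sentence text; reconstructed from the
#'   leaves if missing
#' @param max_variants cap on the number of emitted variants
#' @return list of `sentence_variant`, the original first; deterministic
#'   order
#' @export
simplify <- function(tree, constructs = detect_constructs(tree),
                     sentence = NULL, max_variants = 64L) {
  if (is.null(sentence)) {
    leaves <- collect_leaves(tree)
    sentence <- paste(vapply(leaves, function(l) l$token, character(1)),
                      collapse = " ")
    tree <- align_spans(tree, sentence)
  }
  v0 <- identity_variant(tree, sentence)
  out <- list(v0)
  seen <- v0$text
  queue <- list(v0)
  truncated <- FALSE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    idx <- tree_index(v$tree)
    cs <- if (identical(v$text, sentence) && identical(v$tree, tree)) {
      constructs
    } else {
      detect_constructs(idx)
    }
    if (!length(cs)) next
    cs <- order_constructs(idx, cs)
    rewrites <- rewrite_construct(v, cs[[1L]], idx)
    for (r in rewrites) {
      if (r$text %in% seen) next
      if (length(out) >= max_variants) { truncated <- TRUE; break }
      seen <- c(seen, r$text)
      out[[length(out) + 1L]] <- r
      queue[[length(queue) + 1L]] <- r
    }
    if (truncated) break
  }
  if (truncated) {
    warning("simplification truncated at ", max_variants, " variants")
  }
  out
}

order_constructs <- function(idx, cs) {
  starts <- vapply(cs, function(c) idx$start[c$anchor], integer(1))
  ends <- vapply(cs, function(c) idx$end[c$anchor], integer(1))
  cs[order(starts, -ends)]
}

#' Produce alternative attachment readings
#'
#' Attachment ambiguities are not resolved; instead one variant per
#' reading is produced and the extractor's type checks select among
#' them. Handled shapes: a relative clause after "NP1 prep NP2" (attach
#' to NP1 vs NP2), a prepositional phrase after "NP1 and NP2" (attach to
#' the coordination vs the last conjunct), and "Adj NP1 and NP2" (the
#' adjective distributes over the second conjunct or not).
#'
#' @param tree a `parse_tree`
#' @param sentence original sentence text (reconstructed if missing)
#' @return list of `sentence_variant` (possibly empty), not including
#'   the original
#' @export
attachment_alternatives <- function(tree, sentence = NULL) {
  if (is.null(sentence)) {
    leaves <- collect_leaves(tree)
    sentence <- paste(vapply(leaves, function(l) l$token, character(1)),
                      collapse = " ")
    tree <- align_spans(tree, sentence)
  }
  v0 <- identity_variant(tree, sentence)
  idx <- tree_index(tree)
  out <- list()
  for (i in seq_along(idx$label)) {
    if (idx$label[i] != "NP") next
    kids <- idx$children[[i]]
    labs <- idx$label[kids]
    # --- "NP1 prep NP2" + SBAR at the outer level -> attach low
    if (length(kids) >= 2L && labs[1L] == "NP" &&
        any(labs == "SBAR")) {
      inner <- kids[1L]
      ik <- idx$children[[inner]]
      if (length(ik) >= 2L && idx$label[ik[1L]] == "NP" &&
          any(idx$label[ik] == "PP")) {
        pp <- ik[idx$label[ik] == "PP"][1L]
        ppk <- idx$children[[pp]]
        np2 <- ppk[idx$label[ppk] == "NP"]
        sbar <- kids[labs == "SBAR"][1L]
        if (length(np2)) {
          # move the SBAR inside: NP2 -> (NP NP2 SBAR)
          rep <- list()
          rep[[as.character(np2[1L])]] <-
            new_parse_tree("NP", list(idx$nodes[[np2[1L]]],
                                      idx$nodes[[sbar]]))
          t2 <- surgery(tree, delete = c(sbar,
                                         comma_neighbors(idx, i, sbar)),
                        replace = rep)
          if (!is.null(t2)) {
            out[[length(out) + 1L]] <-
              variant_from_tree(t2, v0, "attachment",
                                attachment_choice = "rc_low")
          }
        }
      }
    }
    # --- "NP1 and NP2" + PP: attach the PP to the last conjunct
    if (length(kids) >= 2L && labs[1L] == "NP" && any(labs == "PP")) {
      inner <- kids[1L]
      ik <- idx$children[[inner]]
      if (any(idx$label[ik] == "CC")) {
        last_np <- ik[idx$label[ik] == "NP"]
        pp <- kids[labs == "PP"][1L]
        if (length(last_np) >= 2L) {
          ln <- last_np[length(last_np)]
          rep <- list()
          rep[[as.character(ln)]] <-
            new_parse_tree("NP", list(idx$nodes[[ln]], idx$nodes[[pp]]))
          t2 <- surgery(tree, delete = pp, replace = rep)
          if (!is.null(t2)) {
            out[[length(out) + 1L]] <-
              variant_from_tree(t2, v0, "attachment",
                                attachment_choice = "pp_low")
          }
        }
      }
    }
    # --- "Adj NP1 and NP2": distributed reading "Adj NP2"
    if (any(labs == "CC")) {
      npk <- kids[idx$label[kids] %in% c("NP", "NX", "NML")]
      if (length(npk) >= 2L) {
        first <- npk[1L]
        fk <- idx$children[[first]]
        adj <- fk[idx$label[fk] %in% c("JJ", "VBN", "VBG")]
        if (length(adj)) {
          last <- npk[length(npk)]
          rep <- list()
          rep[[as.character(i)]] <-
            new_parse_tree("NP", c(lapply(adj, function(a) idx$nodes[[a]]),
                                   list(idx$nodes[[last]])))
          t2 <- surgery(tree, replace = rep)
          if (!is.null(t2)) {
            out[[length(out) + 1L]] <-
              variant_from_tree(t2, v0, "attachment",
                                attachment_choice = "adj_distributed")
          }
        }
      }
    }
  }
  out
}

#' Map a span in a variant back to original coordinates
#'
#' @param variant a `sentence_variant`
#' @param span 0-based half-open character interval in the variant
#' @return 0-based half-open interval in the original sentence covering
#'   the same surface tokens
#' @export
map_span <- function(variant, span) {
  stopifnot(span[2] > span[1], span[1] >= 0,
            span[2] <= length(variant$offset_map))
  src <- variant$offset_map[(span[1] + 1L):span[2]]
  src <- src[!is.na(src)]
  if (!length(src)) {
    stop("span [", span[1], ",", span[2],
         ") covers only inserted glue; no original counterpart")
  }
  c(min(src), max(src) + 1L)
}
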