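#' @title BioNLP-ST standoff I/O and approximate-match evaluation
#' @description
#' Reads and writes BioNLP-ST standoff annotation: `.txt` raw text,
#' `.a1` pre-annotated entities (`T1<TAB>Protein 0 5<TAB>JNK`), and
#' `.a2` event annotations (trigger `T` lines, event `E` lines, and
#' `* Equiv` lines). Predictions are scored with the approximate
#' recursive matching criterion: a predicted span counts as correct if
#' it is entirely contained in the gold span extended by one token to
#' the left and one to the right; events match when the types match and
#' trigger and arguments match role-wise under that span rule.
#' @name standoff_eval
NULL

#' Read a standoff-annotated document
#'
#' @param txt document text (single string)
#' @param a1 entity lines (string or character vector), or NULL
#' @param a2 event lines (string or character vector), or NULL
#' @return a `gold_set`: list with `entities`, `events`,
#'   `equiv_classes` (list of lists of T ids), `triggers`
#' @export
read_standoff <- function(txt, a1 = NULL, a2 = NULL) {
  entities <- if (is.null(a1)) list() else read_a1(a1)
  names(entities) <- vapply(entities, function(m) m$id, character(1))
  triggers <- list()
  events <- list()
  equiv <- list()
  if (!is.null(a2)) {
    lines <- a2
    if (length(lines) == 1L && grepl("\n", lines)) {
      lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
    }
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (startsWith(f[1], "T")) {
        ann <- strsplit(f[2], " ", fixed = TRUE)[[1]]
        triggers[[f[1]]] <- list(id = f[1], type = ann[1],
                                 span = c(as.integer(ann[2]),
                                          as.integer(ann[3])),
                                 text = if (length(f) >= 3) f[3] else "")
      } else if (startsWith(f[1], "E")) {
        parts <- strsplit(f[2], " ", fixed = TRUE)[[1]]
        head <- strsplit(parts[1], ":", fixed = TRUE)[[1]]
        args <- list()
        for (p in parts[-1]) {
          kv <- strsplit(p, ":", fixed = TRUE)[[1]]
          args[[length(args) + 1L]] <- list(role = kv[1], ref = kv[2])
        }
        events[[f[1]]] <- list(id = f[1], type = head[1],
                               trigger = head[2], args = args)
      } else if (f[1] == "*") {
        parts <- strsplit(f[2], " ", fixed = TRUE)[[1]]
        if (parts[1] == "Equiv") {
          equiv[[length(equiv) + 1L]] <- parts[-1]
        }
      }
    }
  }
  # resolve references and convert to event objects
  ev_objs <- list()
  for (e in events) {
    tr <- triggers[[e$trigger]]
    if (is.null(tr)) stop("dangling trigger reference ", e$trigger,
                          " in event ", e$id)
    themes <- list(); agents <- list()
    for (a in e$args) {
      ref <- entities[[a$ref]]
      if (is.null(ref)) stop("dangling argument reference ", a$ref,
                             " in event ", e$id)
      role <- tolower(sub("[0-9]+$", "", a$role))
      if (role == "theme") themes <- c(themes, list(ref))
      else if (role %in% c("cause", "agent")) agents <- c(agents, list(ref))
    }
    ev_objs[[length(ev_objs) + 1L]] <-
      new_event(e$type, tr$span, tr$text, themes, agents)
  }
  structure(list(text = txt, entities = unname(entities), events = ev_objs,
                 equiv_classes = equiv, triggers = triggers,
                 entity_ids = entities),
            class = "gold_set")
}

#' Serialize events to .a2 content
#'
#' Emits `T` lines for event triggers (numbered after the entities in
#' `entities`) and `E` lines for events, with themes as `Theme`,
#' `Theme2`, ... and agents as `Cause`. All event arguments must be
#' pre-annotated entities carrying their `.a1` ids. `read(write(x))`
#' round-trips.
#'
#' @param events list of `event`
#' @param text document text (for trigger surface strings)
#' @param entities the pre-annotated entity mentions (for id numbering)
#' @return character vector of .a2 lines
#' @export
write_a2 <- function(events, text = "", entities = list()) {
  next_t <- length(entities) + 1L
  tlines <- character(); elines <- character()
  tid_by_span <- list()
  for (k in seq_along(events)) {
    e <- events[[k]]
    tkey <- paste(e$relation, e$trigger_span[1], e$trigger_span[2])
    tid <- tid_by_span[[tkey]]
    if (is.null(tid)) {
      tid <- paste0("T", next_t); next_t <- next_t + 1L
      tid_by_span[[tkey]] <- tid
      surface <- if (nzchar(text)) {
        substr(text, e$trigger_span[1] + 1L, e$trigger_span[2])
      } else e$trigger_form
      tlines <- c(tlines, paste0(tid, "\t", e$relation, " ",
                                 e$trigger_span[1], " ", e$trigger_span[2],
                                 "\t", surface))
    }
    args <- character()
    for (j in seq_along(e$args$theme)) {
      m <- e$args$theme[[j]]
      if (is.na(m$id)) stop("event argument without an entity id: '",
                            m$text, "'")
      role <- if (j == 1L) "Theme" else paste0("Theme", j)
      args <- c(args, paste0(role, ":", m$id))
    }
    for (m in e$args$agent) {
      if (is.na(m$id)) stop("event argument without an entity id: '",
                            m$text, "'")
      args <- c(args, paste0("Cause:", m$id))
    }
    elines <- c(elines, paste0("E", k, "\t", e$relation, ":", tid, " ",
                               paste(args, collapse = " ")))
  }
  c(tlines, elines)
}

#' Approximate span matching
#'
#' Extends the gold span by one token to the left and one to the right
#' and tests whether the predicted span is entirely contained in the
#' extension: with predicted span (a1, b1) and extended gold span
#' (a2, b2), the spans match iff a1 >= a2 and b1 <= b2.
#'
#' @param pred predicted 0-based half-open character interval
#' @param gold gold interval
#' @param tokens matrix or list of token spans (each a length-2 vector)
#'   covering the document; "one word" is defined by these boundaries
#' @return logical
#' @export
approx_span_match <- function(pred, gold, tokens) {
  if (is.matrix(tokens)) {
    tokens <- lapply(seq_len(nrow(tokens)), function(i) tokens[i, ])
  }
  starts <- vapply(tokens, `[`, numeric(1), 1L)
  ends <- vapply(tokens, `[`, numeric(1), 2L)
  left <- which(ends <= gold[1])
  lo <- if (length(left)) starts[max(left)] else gold[1]
  right <- which(starts >= gold[2])
  hi <- if (length(right)) ends[min(right)] else gold[2]
  pred[1] >= lo && pred[2] <= hi
}

event_matches <- function(pred, gold, tokens) {
  if (!identical(pred$relation, gold$relation)) return(FALSE)
  if (!approx_span_match(pred$trigger_span, gold$trigger_span, tokens)) {
    return(FALSE)
  }
  role_match <- function(pm, gm) {
    if (length(pm) != length(gm)) return(FALSE)
    if (!length(pm)) return(TRUE)
    # one-to-one assignment, greedy with backtracking over small sets
    perms <- perm_indices(length(gm))
    for (pp in perms) {
      ok <- TRUE
      for (i in seq_along(pm)) {
        if (!approx_span_match(pm[[i]]$span, gm[[pp[i]]]$span, tokens)) {
          ok <- FALSE; break
        }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  role_match(pred$args$theme, gold$args$theme) &&
    role_match(pred$args$agent, gold$args$agent)
}

perm_indices <- function(n) {
  if (n == 1L) return(list(1L))
  if (n == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perm_indices(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[rest])
    }
  }
  out
}

# expand a gold event by its equivalence classes: one copy per choice of
# equivalent entity for each argument in an equiv class
expand_equiv <- function(event, gold) {
  if (!length(gold$equiv_classes)) return(list(event))
  variants <- list(event)
  slots <- list()
  for (role in c("theme", "agent")) {
    for (j in seq_along(event$args[[role]])) {
      m <- event$args[[role]][[j]]
      for (cls in gold$equiv_classes) {
        ids <- cls
        members <- gold$entity_ids[ids]
        if (any(vapply(members, function(x) {
          !is.null(x) && identical(x$span, m$span)
        }, logical(1)))) {
          slots[[length(slots) + 1L]] <- list(role = role, j = j,
                                              members = members)
        }
      }
    }
  }
  for (sl in slots) {
    nv <- list()
    for (v in variants) {
      for (mem in sl$members) {
        v2 <- v
        v2$args[[sl$role]][[sl$j]] <- mem
        nv[[length(nv) + 1L]] <- v2
      }
    }
    variants <- nv
  }
  variants
}

#' Score predicted events against a gold set
#'
#' Gold events are expanded by their equivalence classes (an event whose
#' argument belongs to an n-member class is counted n times). Matching
#' is greedy one-to-one in document order. Precision, recall and
#' F-score are reported per relation and in total; an empty denominator
#' yields 0 by convention.
#'
#' @param pred list of predicted `event`
#' @param gold a `gold_set` from [read_standoff()]
#' @param tokens token spans of the document (list of length-2 vectors);
#'   defaults to whitespace tokens of the gold text
#' @return an `eval_result`: list with `per_relation` data.frame and
#'   `total` row
#' @export
evaluate <- function(pred, gold, tokens = NULL) {
  if (is.null(tokens)) tokens <- whitespace_tokens(gold$text)
  gold_exp <- list()
  for (e in gold$events) gold_exp <- c(gold_exp, expand_equiv(e, gold))
  matched_gold <- rep(FALSE, length(gold_exp))
  matched_pred <- rep(FALSE, length(pred))
  for (i in seq_along(pred)) {
    for (j in seq_along(gold_exp)) {
      if (matched_gold[j]) next
      if (event_matches(pred[[i]], gold_exp[[j]], tokens)) {
        matched_gold[j] <- TRUE
        matched_pred[i] <- TRUE
        break
      }
    }
  }
  rels <- sort(unique(c(
    vapply(pred, function(e) e$relation, character(1)),
    vapply(gold_exp, function(e) e$relation, character(1)))))
  rows <- lapply(c(rels, "Total"), function(r) {
    pi <- if (r == "Total") seq_along(pred) else {
      which(vapply(pred, function(e) e$relation == r, logical(1)))
    }
    gi <- if (r == "Total") seq_along(gold_exp) else {
      which(vapply(gold_exp, function(e) e$relation == r, logical(1)))
    }
    tp <- sum(matched_pred[pi])
    fp <- length(pi) - tp
    fn <- sum(!matched_gold[gi])
    p <- if (length(pi)) tp / length(pi) else 0
    rec <- if (length(gi)) sum(matched_gold[gi]) / length(gi) else 0
    f1 <- if (p + rec > 0) 2 * p * rec / (p + rec) else 0
    data.frame(relation = r, tp = tp, fp = fp, fn = fn,
               precision = p, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(per_relation = tab[tab$relation != "Total", ],
                 total = tab[tab$relation == "Total", ]),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  tab <- rbind(x$per_relation, x$total)
  tab$precision <- sprintf("%.4f", tab$precision)
  tab$recall <- sprintf("%.4f", tab$recall)
  tab$f1 <- sprintf("%.4f", tab$f1)
  print(tab, row.names = FALSE)
  invisible(x)
}

whitespace_tokens <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(list())
  lens <- attr(m, "match.length")
  lapply(seq_along(m), function(i) c(m[i] - 1L, m[i] - 1L + lens[i]))
}

# ---- document reading ----------------------------------------------------

#' Read a document bundle: text, sentence parses, entities
#'
#' @param txt document text (single string)
#' @param parses character vector of bracketed parses, one per sentence
#' @param offsets data.frame or matrix with sentence `start`,`end`
#'   columns (0-based half-open, in document coordinates); if NULL,
#'   sentences are assumed newline-separated in order
#' @param a1 entity annotation lines, or NULL
#' @param links external coreference link lines, or NULL
#' @return a document list for [extract_document()]
#' @export
read_document <- function(txt, parses, offsets = NULL, a1 = NULL,
                          links = NULL) {
  if (is.null(offsets)) {
    offsets <- newline_offsets(txt, length(parses))
  }
  offsets <- as.matrix(offsets)
  sentences <- list()
  for (i in seq_along(parses)) {
    st <- as.integer(offsets[i, 1]); en <- as.integer(offsets[i, 2])
    stext <- substr(txt, st + 1L, en)
    tree <- tryCatch(read_bracketed(parses[i], stext),
                     error = function(e) {
                       warning("sentence ", i, ": ", conditionMessage(e))
                       NULL
                     })
    sentences[[i]] <- list(text = stext, start = st, tree = tree)
  }
  mentions <- if (is.null(a1)) list() else read_a1(a1)
  ext <- if (is.null(links)) list() else read_coref_links(links, txt)
  make_document(txt, sentences, mentions, ext)
}

newline_offsets <- function(txt, n) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < n) stop("fewer text lines than parses")
  start <- 0L
  out <- matrix(0L, nrow = n, ncol = 2L)
  for (i in seq_len(n)) {
    out[i, ] <- c(start, start + nchar(lines[i]))
    start <- start + nchar(lines[i]) + 1L
  }
  out
}
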