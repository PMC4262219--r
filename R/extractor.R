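#' @title Matching lexico-syntactic patterns and assembling events
#' @description
#' The extractor runs generated lexico-syntactic patterns over (variant)
#' parse trees. Each raw tree-pattern match is validated structurally
#' (verb-group head selection with auxiliary skipping, voice, nominal
#' head checks), the captured noun phrase is typed and checked against
#' the trigger specification's slot constraint and lexical guards, and
#' surviving matches become trigger-argument pairs with all spans mapped
#' back to original sentence coordinates. Adverbial and
#' adjective-nominal adjuncts between trigger and argument are skipped
#' by construction: arguments are located as constituents, not by
#' adjacency.
#' @name extractor
NULL

new_pair <- function(relation, trigger_span, trigger_form, slot, role, arg,
                     direction, spec, provenance = character()) {
  structure(list(relation = relation, trigger_span = as.integer(trigger_span),
                 trigger_form = trigger_form, slot = as.integer(slot),
                 role = role, arg = arg, direction = direction,
                 spec = spec, provenance = provenance),
            class = "trigger_arg_pair")
}

#' @export
print.trigger_arg_pair <- function(x, ...) {
  cat("<pair> ", x$relation, ": <", x$trigger_form, "@[", x$trigger_span[1],
      ",", x$trigger_span[2], "), '", x$arg$text, "' ", x$role, ">\n",
      sep = "")
  invisible(x)
}

slot_of <- function(spec, i) {
  for (s in spec$slots) if (s$index == i) return(s)
  NULL
}

role_of <- function(spec, i) {
  r <- spec$roles[[as.character(i)]]
  if (is.null(r)) "theme" else r
}

# soft-failing semantic types: uninformative phrases that referential
# linking may later rewrite into proper entities
.linkable_types <- c("class_noun", "other")

#' Extract trigger-argument pairs from one sentence variant
#'
#' @param variant a `sentence_variant` (use [identity_variant()] for the
#'   unsimplified sentence)
#' @param patterns list of `lexsyn_pattern` from [generate_patterns()]
#' @param mentions pre-annotated mentions in original sentence
#'   coordinates
#' @return list of `trigger_arg_pair`; spans are in original sentence
#'   coordinates. Pairs whose theme must be recovered from another
#'   trigger in the sentence carry `deferred = TRUE`.
#' @export
extract_sentence <- function(variant, patterns, mentions = list()) {
  idx <- tree_index(variant$tree)
  toks <- tolower(idx$token[idx$leaves])
  out <- list()
  for (p in patterns) {
    surf <- tolower(p$form$surface)
    present <- if (p$template_id == "N8") {
      any(endsWith(toks, paste0("-", surf)))
    } else {
      surf %in% toks
    }
    if (!present) next
    d <- .template_defs[[p$template_id]]
    for (m in match_all(p$tree_pattern, idx)) {
      cands <- d$post(idx, m$ids)
      for (cd in cands %||% list()) {
        out <- c(out, realize_candidate(cd, p, d, idx, variant, mentions))
      }
    }
  }
  dedup_pairs(out)
}

realize_candidate <- function(cd, p, d, idx, variant, mentions) {
  spec <- p$spec
  slot <- slot_of(spec, p$slot)
  if (is.null(slot)) return(list())
  trig_var <- c(idx$start[cd$trig], idx$end[cd$trig])
  trig_orig <- try(map_span(variant, trig_var), silent = TRUE)
  if (inherits(trig_orig, "try-error")) return(list())
  base <- function(arg_mention, deferred = FALSE) {
    pr <- new_pair(spec$relation, trig_orig, idx$token[cd$trig], p$slot,
                   role_of(spec, p$slot), arg_mention, spec$direction, spec,
                   provenance = c(p$template_id, variant$provenance))
    pr$deferred <- deferred
    pr
  }

  if (!is.na(cd$defer)) {
    return(list(base(NULL, deferred = TRUE)))
  }
  if (isTRUE(cd$hyphen)) {
    tok <- idx$token[cd$trig]
    left_len <- nchar(tok) - nchar(p$form$surface) - 1L
    if (left_len <= 0L) return(list())
    arg_var <- c(idx$start[cd$trig], idx$start[cd$trig] + left_len)
    arg_orig <- try(map_span(variant, arg_var), silent = TRUE)
    if (inherits(arg_orig, "try-error")) return(list())
    men <- NULL
    for (mm in mentions) if (spans_overlap(arg_orig, mm$span)) men <- mm
    if (is.null(men)) {
      men <- new_entity_mention(arg_orig, substr(tok, 1L, left_len),
                                head_lookup(substr(tok, 1L, left_len)))
    }
    if (!pair_type_ok(men, slot)) return(list())
    if (!guard_ok(spec, p$slot, substr(tok, 1L, left_len))) return(list())
    return(list(base(men)))
  }

  arg_nodes <- cd$arg
  if (isTRUE(d$expand)) {
    kids <- idx$children[[cd$arg]]
    conj <- kids[idx$label[kids] %in% c("NP", "NX", "NML")]
    if (any(idx$label[kids] == "CC") && length(conj) >= 2L) {
      arg_nodes <- conj
    }
  }
  out <- list()
  for (an in arg_nodes) {
    men <- variant_mention(idx, an, variant, mentions)
    if (is.null(men)) next
    if (!pair_type_ok(men, slot)) next
    if (!guard_ok(spec, p$slot, idx_yield(idx, an))) next
    out[[length(out) + 1L]] <- base(men)
  }
  out
}

# Type a noun phrase inside a variant tree, resolving the head against
# pre-annotated mentions in original coordinates.
variant_mention <- function(idx, an, variant, mentions) {
  h <- np_head_leaf(idx, an)
  if (is.na(h)) h <- idx$leaves[idx$last_leaf[an]]
  hs <- try(map_span(variant, c(idx$start[h], idx$end[h])), silent = TRUE)
  if (inherits(hs, "try-error")) return(NULL)
  for (m in mentions) if (spans_overlap(hs, m$span)) return(m)
  span <- try(map_span(variant, c(idx$start[an], idx$end[an])),
              silent = TRUE)
  if (inherits(span, "try-error")) return(NULL)
  ty <- head_lookup(idx$token[h])
  # "X mRNA": the inner pre-annotated mention names the transcribed gene
  if (ty == "rna") {
    for (m in mentions) {
      if (m$span[1] >= span[1] && m$span[2] <= span[2]) return(m)
    }
  }
  new_entity_mention(span, idx_yield(idx, an), ty)
}

# hard type check: informative mismatches are dropped; uninformative
# phrases pass through for later referential linking
pair_type_ok <- function(mention, slot) {
  satisfies(mention, slot) ||
    (mention$source == "heuristic" && mention$sem_type %in% .linkable_types)
}

guard_ok <- function(spec, slot_index, arg_text) {
  for (g in spec$guards) {
    if (g$slot != slot_index) next
    toks <- strsplit(tolower(arg_text), "[^A-Za-z0-9]+")[[1]]
    if (!tolower(g$word) %in% toks) return(FALSE)
  }
  TRUE
}

dedup_pairs <- function(pairs) {
  if (!length(pairs)) return(pairs)
  key <- vapply(pairs, pair_key, character(1))
  pairs[!duplicated(key)]
}

pair_key <- function(p) {
  paste(p$relation, p$trigger_span[1], p$trigger_span[2], p$role,
        if (is.null(p$arg)) "deferred" else paste(p$arg$span[1],
                                                  p$arg$span[2]))
}

#' Resolve homonymous trigger readings at one occurrence
#'
#' When several specifications share a trigger form (e.g. "express" for
#' gene expression, transcription and localization), the type checks and
#' lexical guards decide among them: if a guarded specification fired at
#' a trigger occurrence, the unguarded specifications with the same root
#' are suppressed there; otherwise all surviving readings are proposed.
#'
#' @param pairs list of `trigger_arg_pair` from one sentence or document
#' @return filtered pair list
#' @export
disambiguate_homonyms <- function(pairs) {
  if (!length(pairs)) return(pairs)
  occ <- vapply(pairs, function(p) paste(p$trigger_span[1], p$trigger_span[2]),
                character(1))
  keep <- rep(TRUE, length(pairs))
  guarded_spec <- vapply(pairs, function(p) length(p$spec$guards) > 0L,
                         logical(1))
  on_guarded_slot <- vapply(pairs, function(p) {
    any(vapply(p$spec$guards, function(g) g$slot == p$slot, logical(1)))
  }, logical(1))
  for (o in unique(occ)) {
    at <- which(occ == o)
    # a guarded reading is active at this occurrence only if a pair on
    # its guarded slot matched (the guard word co-occurred)
    active <- at[guarded_spec[at] & on_guarded_slot[at]]
    roots_g <- unique(vapply(pairs[active], function(p) p$spec$root,
                             character(1)))
    for (k in at) {
      p <- pairs[[k]]
      if (!guarded_spec[k] && p$spec$root %in% roots_g) {
        keep[k] <- FALSE  # guarded reading wins over the default one
      }
      if (guarded_spec[k] && !p$spec$relation %in%
            vapply(pairs[active], function(q) q$spec$relation, character(1))) {
        keep[k] <- FALSE  # guard unsatisfied: the reading is inactive
      }
    }
  }
  pairs[keep]
}

#' Extraction configuration
#'
#' @param simplify apply sentence simplification and attachment
#'   alternatives
#' @param link apply referential relation linking
#' @param max_variants cap on simplification variants per sentence
#' @param require_annotated_args keep only events whose arguments are
#'   pre-annotated mentions (required for standoff output)
#' @return a config list
#' @export
extract_config <- function(simplify = TRUE, link = TRUE,
                           max_variants = 128L,
                           require_annotated_args = TRUE) {
  list(simplify = simplify, link = link, max_variants = max_variants,
       require_annotated_args = require_annotated_args)
}

#' Extract events from a parsed document
#'
#' Runs the full pipeline per sentence: construct detection,
#' simplification, attachment alternatives, pattern matching on every
#' variant, span mapping back to document coordinates, recovery of
#' deferred null-argument themes, referential relation linking, homonym
#' disambiguation, and combination of pairs into deduplicated events.
#'
#' @param doc a document as returned by [read_document()] or
#'   [make_document()]: a list with `text`, `sentences` (each with
#'   `text`, `start`, `tree`), `mentions`, and optional `links`
#'   (external coreference links)
#' @param patterns list of `lexsyn_pattern`
#' @param config an [extract_config()]
#' @return list of `event` objects with spans in document coordinates
#' @export
extract_document <- function(doc, patterns, config = extract_config()) {
  all_pairs <- list()
  for (sent in doc$sentences) {
    if (is.null(sent$tree)) {
      warning("sentence without a readable parse skipped: '",
              substr(sent$text, 1, 40), "'")
      next
    }
    local_mentions <- shift_mentions(doc$mentions, sent$start, sent$text)
    variants <- list(identity_variant(sent$tree, sent$text))
    if (config$simplify) {
      variants <- simplify(sent$tree, sentence = sent$text,
                           max_variants = config$max_variants)
      for (av in attachment_alternatives(sent$tree, sent$text)) {
        variants <- c(variants, list(av))
        sub <- simplify(av$tree, sentence = av$text,
                        max_variants = config$max_variants)
        for (sv in sub[-1L]) {
          variants <- c(variants, list(compose_variant(sv, av)))
        }
      }
    }
    pairs <- list()
    for (v in variants) {
      pairs <- c(pairs, extract_sentence(v, patterns, local_mentions))
    }
    pairs <- resolve_deferred(pairs)
    pairs <- dedup_pairs(pairs)
    # shift to document coordinates
    pairs <- lapply(pairs, function(p) {
      p$trigger_span <- p$trigger_span + sent$start
      p$arg$span <- p$arg$span + sent$start
      p
    })
    all_pairs <- c(all_pairs, pairs)
  }

  if (config$link) {
    parsed <- Filter(function(s) !is.null(s$tree), doc$sentences)
    links <- detect_links(lapply(parsed, doc_tree_global, doc = doc),
                          doc$mentions)
    links <- register_external_coref(doc$links %||% list(), links)
    resolved <- list()
    for (p in all_pairs) {
      resolved <- c(resolved, resolve_pair(p, links, slot_of(p$spec, p$slot)))
    }
    all_pairs <- dedup_pairs(resolved)
  }

  all_pairs <- disambiguate_homonyms(all_pairs)
  if (config$require_annotated_args) {
    all_pairs <- Filter(function(p) is_informative(p$arg), all_pairs)
  }
  # precision guard: no surviving pair may violate its slot constraint
  all_pairs <- Filter(function(p) {
    satisfies(p$arg, slot_of(p$spec, p$slot))
  }, all_pairs)
  dedup_events(pairs_to_events(all_pairs))
}

doc_tree_global <- function(sent, doc) {
  shift_tree(sent$tree, sent$start)
}

shift_tree <- function(tree, by) {
  tree$start <- tree$start + by
  tree$end <- tree$end + by
  if (!is_leaf(tree)) tree$children <- lapply(tree$children, shift_tree, by = by)
  tree
}

shift_mentions <- function(mentions, start, sent_text) {
  end <- start + nchar(sent_text)
  out <- list()
  for (m in mentions) {
    if (m$span[1] >= start && m$span[2] <= end) {
      m$span <- m$span - start
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

compose_variant <- function(child, parent) {
  omap <- child$offset_map
  keep <- !is.na(omap)
  omap[keep] <- parent$offset_map[omap[keep] + 1L]
  child$offset_map <- omap
  child$provenance <- c(parent$provenance, child$provenance)
  child
}

# a deferred null-argument trigger takes its theme from a theme pair of
# another trigger occurrence in the same sentence
resolve_deferred <- function(pairs) {
  deferred <- Filter(function(p) isTRUE(p$deferred), pairs)
  if (!length(deferred)) return(pairs)
  normal <- Filter(function(p) !isTRUE(p$deferred), pairs)
  out <- normal
  for (dp in deferred) {
    slot <- slot_of(dp$spec, dp$slot)
    for (np in normal) {
      if (np$role != "theme") next
      if (identical(np$trigger_span, dp$trigger_span)) next
      if (!satisfies(np$arg, slot) &&
          !np$arg$sem_type %in% .linkable_types) next
      p <- dp
      p$arg <- np$arg
      p$deferred <- FALSE
      p$provenance <- c(p$provenance, "deferred_theme")
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

dedup_events <- function(events) {
  if (!length(events)) return(events)
  key <- vapply(events, function(e) {
    th <- sort(vapply(e$args$theme, function(m) paste(m$span[1], m$span[2]),
                      character(1)))
    ag <- sort(vapply(e$args$agent, function(m) paste(m$span[1], m$span[2]),
                      character(1)))
    paste(e$relation, e$trigger_span[1], e$trigger_span[2],
          paste(th, collapse = ";"), paste(ag, collapse = ";"))
  }, character(1))
  events[!duplicated(key)]
}

#' Build the full pattern set for a list of trigger specifications
#'
#' @param specs list of `trigger_spec` (e.g. from [parse_trigger_spec()])
#' @return list of `lexsyn_pattern`
#' @export
compile_specs <- function(specs) {
  out <- list()
  for (spec in specs) {
    forms <- derive_trigger_forms(spec$root, spec$affixes)
    frame <- select_frame(spec)
    out <- c(out, generate_patterns(spec, forms, frame))
  }
  out
}

#' Assemble a document object from its parts
#'
#' @param text full document text
#' @param sentences list of lists with `text`, `start` (0-based offset
#'   of the sentence in `text`) and `tree` (a `parse_tree` aligned to
#'   the sentence text)
#' @param mentions pre-annotated mentions in document coordinates
#' @param links optional externally supplied `ref_link` list
#' @return a document list suitable for [extract_document()]
#' @export
make_document <- function(text, sentences, mentions = list(),
                          links = list()) {
  list(text = text, sentences = sentences, mentions = mentions,
       links = links)
}
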