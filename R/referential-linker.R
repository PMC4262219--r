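#' @title Referential relation detection and recursive argument linking
#' @description
#' A pattern often captures an argument phrase that is not itself an
#' informative named entity ("the earliest genes", "a membrane
#' glycoprotein", "the protein"). Referential relations link such
#' phrases to the entities that interpret them: part-whole ("the Prf1
#' locus" names a part of Prf1), member-collection ("adhesion molecules
#' including integrin alpha, ..."), hyponymy ("acts as", "is identified
#' as", copular and appositive constructions), and relative-pronoun
#' coreference. General pronominal anaphora is deliberately not
#' detected here: an external resolver can contribute links through
#' [register_external_coref()].
#'
#' Given the document's link set, [resolve_pair()] recursively rewrites
#' a trigger-argument pair whose argument is uninformative into one
#' pair per reachable informative mention, using a visited set so the
#' search terminates on any link graph, including cyclic ones.
#' @name referential_linker
NULL

.link_kinds <- c("part_whole", "member_collection", "hyponymy",
                 "apposition", "relpronoun_coref")

new_ref_link <- function(kind, source, target) {
  stopifnot(kind %in% .link_kinds)
  if (identical(source$span, target$span)) {
    stop("referential link must connect two distinct spans")
  }
  structure(list(kind = kind, source = source, target = target),
            class = "ref_link")
}

#' @export
print.ref_link <- function(x, ...) {
  cat("<link> ", x$kind, ": '", x$source$text, "' -> '", x$target$text,
      "'\n", sep = "")
  invisible(x)
}

.member_cues <- c("including", "include", "includes")
.part_keywords <- c("locus", "loci", "promoter", "promoters", "domain",
                    "domains", "residue", "residues", "site", "sites",
                    "region", "regions", "subunit", "subunits",
                    "terminus", "termini", "motif", "motifs")
.copulas <- c("is", "are", "was", "were", "be", "been", "being")

np_mention <- function(idx, np, sem_type = NA_character_,
                       preannotated = list()) {
  span <- c(idx$start[np], idx$end[np])
  if (is.na(sem_type)) {
    m <- type_np(sub_index(idx, np), preannotated)
    sem_type <- m$sem_type
  }
  new_entity_mention(span, idx_yield(idx, np), sem_type)
}

# a view of the index rooted at node n, for type_np-style helpers
sub_index <- function(idx, n) {
  tree_index(idx$nodes[[n]])
}

#' Detect referential relations in a parsed sentence or document
#'
#' Finds part-whole links (part-keyword noun phrases containing a
#' pre-annotated mention, and "NP contains NP" predications),
#' member-collection links ("such as", "including", "e.g." lists, and
#' "one/some of NP" partitives), hyponymy links ("acts as", "is
#' identified as", copular "X is a Y" and appositive constructions),
#' and relative-pronoun coreference.
#'
#' @param trees list of `parse_tree` (one per sentence, spans in
#'   document coordinates)
#' @param mentions pre-annotated `entity_mention` list (document
#'   coordinates)
#' @return list of `ref_link`
#' @export
detect_links <- function(trees, mentions = list()) {
  if (inherits(trees, "parse_tree")) trees <- list(trees)
  out <- list()
  for (tree in trees) {
    idx <- tree_index(tree)
    out <- c(out, detect_links_idx(idx, mentions))
  }
  out
}

detect_links_idx <- function(idx, mentions) {
  out <- list()
  add <- function(kind, source, target) {
    if (identical(source$span, target$span)) return(invisible())
    out[[length(out) + 1L]] <<- new_ref_link(kind, source, target)
  }

  nps <- which(idx$label %in% c("NP", "NX", "NML"))
  for (np in nps) {
    h <- np_head_leaf(idx, np)
    if (is.na(h)) next
    htok <- tolower(idx$token[h])

    # (i) part-whole by part keyword: "the Prf1 locus" -> Prf1
    if (htok %in% .part_keywords) {
      span <- c(idx$start[np], idx$end[np])
      for (m in mentions) {
        if (m$span[1] >= span[1] && m$span[2] <= span[2] &&
            m$span[2] <= idx$start[h]) {
          add("part_whole",
              new_entity_mention(span, idx_yield(idx, np),
                                 part_type(htok)), m)
        }
      }
    }

    # (ii) member-collection: "NP including/such as NP (, NP)*"
    kids <- idx$children[[np]]
    coll <- kids[idx$label[kids] %in% c("NP", "NX", "NML")]
    for (pp in kids[idx$label[kids] %in% c("PP", "VP")]) {
      cue <- mc_cue(idx, pp)
      if (!cue) next
      if (!length(coll)) next
      coll_m <- np_mention(idx, coll[1L], preannotated = mentions)
      for (mem in list_member_nps(idx, pp)) {
        add("member_collection", mention_at(idx, mem, mentions), coll_m)
      }
    }
    # partitive "one/some/each/all of NP"
    if (htok %in% c("one", "some", "several", "each", "all", "members",
                    "member")) {
      for (pp in kids[idx$label[kids] == "PP"]) {
        ppk <- idx$children[[pp]]
        ins <- ppk[idx$label[ppk] == "IN"]
        if (!length(ins)) next
        if (tolower(leaf_token(idx, ins[1L])) != "of") next
        obj <- ppk[idx$label[ppk] == "NP"]
        if (!length(obj)) next
        base <- idx$parent[idx$parent[h]]
        mem_node <- if (!is.na(base) &&
                        idx$label[base] %in% c("NP", "NX", "NML")) base else np
        add("member_collection",
            np_mention(idx, mem_node, "class_noun"),
            np_mention(idx, obj[1L], preannotated = mentions))
      }
    }

    # (iii) hyponymy inside an NP: "a nuclear factor identified as X"
    for (vp in kids[idx$label[kids] == "VP"]) {
      ch <- vg_chain(idx, vp)
      if (is.na(ch$head)) next
      if (!tolower(idx$token[ch$head]) %in%
          c("identified", "known", "described", "defined")) next
      as_np <- hypo_as_np(idx, ch$head_vp)
      if (is.na(as_np)) next
      base <- kids[idx$label[kids] %in% c("NP", "NX", "NML")]
      if (!length(base)) next
      add("hyponymy", mention_at(idx, as_np, mentions),
          mention_at(idx, base[1L], mentions))
    }

    # (iv) apposition (also a hyponymy carrier)
    # handled through the simplifier's construct detector
  }

  for (con in detect_constructs(idx)) {
    if (con$kind == "apposition" && !is.na(con$referent)) {
      add("apposition",
          mention_at(idx, con$parts[[1L]], mentions),
          mention_at(idx, con$referent, mentions))
    }
    if (con$kind == "relative_clause_full" && !is.na(con$referent)) {
      prn <- idx$leaves[idx$first_leaf[con$parts[[1L]]]]
      add("relpronoun_coref",
          new_entity_mention(c(idx$start[prn], idx$end[prn]),
                             idx$token[prn], "other"),
          mention_at(idx, con$referent, mentions))
    }
  }

  # (iii) hyponymy by predication: "X acts as Y", "X is identified as Y",
  # copular "X is a Y" / inverted "One of ... is X"
  for (s in which(idx$label == "S")) {
    kids <- idx$children[[s]]
    vps <- kids[idx$label[kids] == "VP"]
    subj <- subject_of(idx, s)
    if (!length(vps) || is.na(subj)) next
    vp <- vps[1L]
    ch <- vg_chain(idx, vp)
    if (is.na(ch$head)) next
    hw <- tolower(idx$token[ch$head])
    vkids <- idx$children[[ch$head_vp]]
    pred_np <- vkids[idx$label[vkids] == "NP"]
    as_pp <- hypo_as_np(idx, ch$head_vp)
    if (hw %in% c("acts", "act", "acted", "serves", "serve", "served",
                  "functions", "function", "functioned", "identified",
                  "known", "described") && !is.na(as_pp)) {
      add("hyponymy", mention_at(idx, subj, mentions),
          mention_at(idx, as_pp, mentions))
    } else if (hw %in% .copulas && length(pred_np)) {
      lhs <- mention_at(idx, subj, mentions)
      rhs <- mention_at(idx, pred_np[1L], mentions)
      # the named-entity side is the hyponym of the generic side
      if (rhs$source == "preannotated" && lhs$source != "preannotated") {
        add("hyponymy", rhs, lhs)
      } else if (lhs$source == "preannotated" &&
                 rhs$source != "preannotated") {
        add("hyponymy", lhs, rhs)
      }
    }
  }

  # "NP_whole contains NP_part" predication
  for (vp in which(idx$label == "VP")) {
    ch <- vg_chain(idx, vp)
    if (is.na(ch$head)) next
    if (!tolower(idx$token[ch$head]) %in%
        c("contains", "contain", "contained", "comprises", "comprise",
          "comprised")) next
    s <- nearest_ancestor(idx, vp, "S")
    if (is.na(s)) next
    subj <- subject_of(idx, s)
    vkids <- idx$children[[ch$head_vp]]
    obj <- vkids[idx$label[vkids] == "NP"]
    if (is.na(subj) || !length(obj)) next
    add("part_whole", mention_at(idx, obj[1L], mentions),
        mention_at(idx, subj, mentions))
  }

  out
}

part_type <- function(htok) {
  if (htok %in% c("locus", "loci", "promoter", "promoters")) "gene_part"
  else "protein_part"
}

mention_at <- function(idx, n, mentions) {
  span <- c(idx$start[n], idx$end[n])
  for (m in mentions) {
    if (identical(as.integer(m$span), as.integer(span))) return(m)
  }
  # a pre-annotated mention that is the head of this phrase stands for it
  h <- np_head_leaf(idx, n)
  if (!is.na(h)) {
    hspan <- c(idx$start[h], idx$end[h])
    for (m in mentions) {
      if (spans_overlap(hspan, m$span)) return(m)
    }
  }
  np_mention(idx, n, preannotated = mentions)
}

# the NP object of an "as" preposition inside a verb phrase, or NA
hypo_as_np <- function(idx, vp) {
  kids <- idx$children[[vp]]
  for (pp in kids[idx$label[kids] == "PP"]) {
    ppk <- idx$children[[pp]]
    ins <- ppk[idx$label[ppk] %in% c("IN", "RB")]
    if (!length(ins)) next
    if (tolower(leaf_token(idx, ins[1L])) != "as") next
    obj <- ppk[idx$label[ppk] == "NP"]
    if (length(obj)) return(obj[1L])
  }
  NA_integer_
}

mc_cue <- function(idx, pp) {
  kids <- idx$children[[pp]]
  first <- idx$leaves[idx$first_leaf[pp]]
  tok1 <- tolower(idx$token[first])
  if (tok1 %in% .member_cues) return(TRUE)
  if (tok1 == "such") {
    nxt <- idx$first_leaf[pp] + 1L
    if (nxt <= length(idx$leaves) &&
        tolower(idx$token[idx$leaves[nxt]]) == "as") {
      return(TRUE)
    }
  }
  if (tok1 %in% c("e.g.", "eg")) return(TRUE)
  FALSE
}

list_member_nps <- function(idx, pp) {
  obj <- idx_descendants(idx, pp)
  obj <- obj[idx$label[obj] == "NP"]
  if (!length(obj)) return(integer())
  top <- obj[1L]
  kids <- idx$children[[top]]
  inner <- kids[idx$label[kids] %in% c("NP", "NX", "NML")]
  if (length(inner) >= 2L) inner else top
}

#' Validate and merge externally produced coreference links
#'
#' Links from an external anaphora resolver (pronoun or definite-NP
#' coreference) are merged with the detected link set. Spans must be
#' well-formed, non-identical intervals.
#'
#' @param links list of `ref_link` (usually `relpronoun_coref` kind)
#' @param link_set existing list of links to merge into
#' @return the merged link list
#' @export
register_external_coref <- function(links, link_set = list()) {
  for (l in links) {
    if (!inherits(l, "ref_link")) stop("external link is not a ref_link")
    if (any(is.na(l$source$span)) || any(is.na(l$target$span)) ||
        l$source$span[2] <= l$source$span[1] ||
        l$target$span[2] <= l$target$span[1]) {
      stop("malformed span in external coreference link")
    }
  }
  c(link_set, links)
}

#' Read external coreference links from a tab-separated file
#'
#' Columns: source_start, source_end, target_start, target_end, kind.
#'
#' @param lines character vector of lines (or a single string)
#' @param text document text used to fill the mention surface strings
#' @return list of `ref_link`
#' @export
read_coref_links <- function(lines, text = "") {
  if (length(lines) == 1L && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed coreference link line: ", ln)
    sp <- as.integer(f[1:4])
    grab <- function(a, b) {
      if (nzchar(text)) substr(text, a + 1L, b) else ""
    }
    new_ref_link(f[5],
                 new_entity_mention(sp[1:2], grab(sp[1], sp[2]), "other"),
                 new_entity_mention(sp[3:4], grab(sp[3], sp[4]), "other"))
  })
}

# substitutions allowed per link kind, given that the current phrase
# matches one endpoint: collection -> member, hypernym -> hyponym,
# apposition both ways, part -> whole, pronoun -> referent
link_next <- function(link, span) {
  out <- list()
  src <- link$source; tgt <- link$target
  if (link$kind == "member_collection" && spans_overlap(span, tgt$span)) {
    out <- c(out, list(src))
  } else if (link$kind == "hyponymy" && spans_overlap(span, tgt$span)) {
    out <- c(out, list(src))
  } else if (link$kind == "apposition") {
    if (spans_overlap(span, tgt$span)) out <- c(out, list(src))
    if (spans_overlap(span, src$span)) out <- c(out, list(tgt))
  } else if (link$kind == "part_whole" && spans_overlap(span, src$span)) {
    out <- c(out, list(tgt))
  } else if (link$kind == "relpronoun_coref" &&
             spans_overlap(span, src$span)) {
    out <- c(out, list(tgt))
  }
  out
}

is_informative <- function(mention) {
  identical(mention$source, "preannotated")
}

#' Resolve a trigger-argument pair through referential links
#'
#' If the pair's argument is already an informative named entity
#' (a pre-annotated mention) the pair is returned unchanged. Otherwise
#' all referential links whose substitutable endpoint overlaps the
#' argument are followed recursively (collection to member, hypernym to
#' hyponym, apposition in both directions, part to whole, pronoun to
#' referent), collecting every reachable informative mention; one
#' rewritten pair is returned per reachable entity that satisfies the
#' slot's type constraint. A visited set over spans guarantees
#' termination on cyclic link graphs. If nothing informative is
#' reachable the original pair is returned: resolution never drops a
#' pair.
#'
#' @param pair a `trigger_arg_pair`
#' @param links list of `ref_link`
#' @param slot the `arg_slot` the argument must satisfy (optional)
#' @return list of `trigger_arg_pair`
#' @export
resolve_pair <- function(pair, links, slot = NULL) {
  if (is_informative(pair$arg)) return(list(pair))
  if (!length(links)) return(list(pair))
  found <- list()
  visited <- character()
  key <- function(sp) paste(sp[1], sp[2])
  frontier <- list(pair$arg$span)
  visited <- key(pair$arg$span)
  while (length(frontier)) {
    sp <- frontier[[1L]]; frontier <- frontier[-1L]
    for (l in links) {
      for (nxt in link_next(l, sp)) {
        k <- key(nxt$span)
        if (k %in% visited) next
        visited <- c(visited, k)
        if (is_informative(nxt) &&
            (is.null(slot) || satisfies(nxt, slot))) {
          found[[length(found) + 1L]] <- nxt
        }
        frontier[[length(frontier) + 1L]] <- nxt$span
      }
    }
  }
  if (!length(found)) return(list(pair))
  lapply(unique_mentions(found), function(m) {
    p <- pair
    p$arg <- m
    p$provenance <- c(p$provenance, "referential_link")
    p
  })
}
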