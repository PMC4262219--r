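#' @title Constituency parse trees with character spans
#' @description
#' Parse trees are plain recursive lists of class `parse_tree`. Interior
#' nodes carry a phrase or POS `label` and an ordered list of `children`;
#' word nodes are leaves whose `label` equals their `token`. A preterminal
#' such as `(VBZ phosphorylates)` therefore becomes an interior `VBZ` node
#' with a single word-leaf child. Every node carries a 0-based half-open
#' character interval `[start, end)` into the source sentence.
#' @name parse_tree
NULL

new_parse_tree <- function(label, children = list(), token = NULL,
                           start = NA_integer_, end = NA_integer_) {
  stopifnot(is.character(label), length(label) == 1L)
  structure(
    list(label = label, children = children, token = token,
         start = as.integer(start), end = as.integer(end)),
    class = "parse_tree"
  )
}

#' Test whether a node is a word leaf
#' @param x a `parse_tree` node
#' @return logical
#' @export
is_leaf <- function(x) !is.null(x$token)

#' @export
print.parse_tree <- function(x, ...) {
  cat(deparse_tree(x), "\n")
  invisible(x)
}

#' Render a tree back to bracketed notation
#' @param x a `parse_tree`
#' @return a single string in Penn Treebank bracketed format
#' @export
deparse_tree <- function(x) {
  if (is_leaf(x)) return(x$token)
  paste0("(", x$label, " ",
         paste(vapply(x$children, deparse_tree, character(1)), collapse = " "),
         ")")
}

# PTB bracket escapes used for literal brackets in tokens
.ptb_unescape <- c("-LRB-" = "(", "-RRB-" = ")", "-LSB-" = "[",
                   "-RSB-" = "]", "-LCB-" = "{", "-RCB-" = "}")

unescape_token <- function(tok) {
  hit <- unname(.ptb_unescape[tok])
  if (is.na(hit)) tok else hit
}

#' Read a Penn Treebank bracketed parse
#'
#' Parses a bracketed constituency parse and aligns its word leaves
#' left-to-right against the raw sentence text, assigning each node a
#' 0-based half-open character span. Word tokens must occur in the
#' sentence in order, separated only by whitespace; `-LRB-`-style escape
#' tokens are matched against their literal bracket characters.
#'
#' @param text bracketed parse string, e.g. `"(S (NP (NNP JNK)) ...)"`
#' @param sentence the raw sentence text the leaves align to
#' @return a `parse_tree` with character spans on every node
#' @examples
#' tr <- read_bracketed(
#'   "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
#'   "JNK phosphorylates NFAT4")
#' tr$start; tr$end
#' @export
read_bracketed <- function(text, sentence) {
  toks <- lex_brackets(text)
  st <- parse_brackets(toks)
  if (st$pos <= length(toks)) {
    stop("unbalanced brackets: trailing input after complete parse")
  }
  align_spans(st$tree, sentence)
}

lex_brackets <- function(text) {
  # split into "(", ")" and atoms
  text <- gsub("\\(", " ( ", text)
  text <- gsub("\\)", " ) ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

parse_brackets <- function(toks, pos = 1L) {
  if (pos > length(toks)) stop("unbalanced brackets: unexpected end of input")
  if (toks[pos] != "(") stop("expected '(' at token ", pos)
  pos <- pos + 1L
  if (pos > length(toks) || toks[pos] %in% c("(", ")")) {
    stop("missing node label at token ", pos)
  }
  label <- toks[pos]
  pos <- pos + 1L
  children <- list()
  repeat {
    if (pos > length(toks)) stop("unbalanced brackets: missing ')'")
    if (toks[pos] == ")") {
      pos <- pos + 1L
      break
    }
    if (toks[pos] == "(") {
      st <- parse_brackets(toks, pos)
      children[[length(children) + 1L]] <- st$tree
      pos <- st$pos
    } else {
      # word leaf: label and token are the word itself
      children[[length(children) + 1L]] <-
        new_parse_tree(toks[pos], token = toks[pos])
      pos <- pos + 1L
    }
  }
  if (length(children) == 0L) stop("empty constituent '", label, "'")
  list(tree = new_parse_tree(label, children), pos = pos)
}

align_spans <- function(tree, sentence) {
  chars <- strsplit(sentence, "")[[1]]
  pos <- 0L # 0-based cursor
  walk <- function(node) {
    if (is_leaf(node)) {
      surface <- unescape_token(node$token)
      while (pos < length(chars) && grepl("^\\s$", chars[pos + 1L])) {
        pos <<- pos + 1L
      }
      n <- nchar(surface)
      got <- substr(sentence, pos + 1L, pos + n)
      if (!identical(got, surface)) {
        stop("token alignment error: expected '", surface,
             "' at offset ", pos, " but sentence has '", got, "'")
      }
      node$start <- pos
      node$end <- pos + n
      pos <<- pos + n
      return(node)
    }
    node$children <- lapply(node$children, walk)
    node$start <- node$children[[1L]]$start
    node$end <- node$children[[length(node$children)]]$end
    node
  }
  walk(tree)
}

#' Flatten a tree into an index of nodes
#'
#' Produces a flat, vectorized view of a `parse_tree` used by the matcher,
#' the simplifier and the extractor: per-node label/token/span vectors,
#' parent and child ids, and leaf-order bookkeeping. Node ids are
#' pre-order positions (root = 1).
#'
#' @param tree a `parse_tree`
#' @return a list with components `label`, `token`, `start`, `end`,
#'   `parent`, `children` (list of integer vectors), `nodes` (the original
#'   subtree objects), `first_leaf`, `last_leaf` (leaf-order indices) and
#'   `leaves` (node ids of word leaves in order)
#' @export
tree_index <- function(tree) {
  env <- new.env(parent = emptyenv())
  env$label <- character(); env$token <- character()
  env$start <- integer(); env$end <- integer()
  env$parent <- integer(); env$children <- list()
  env$nodes <- list()
  env$first_leaf <- integer(); env$last_leaf <- integer()
  env$leaves <- integer()
  add <- function(node, parent_id) {
    id <- length(env$label) + 1L
    env$label[id] <- node$label
    env$token[id] <- if (is_leaf(node)) node$token else NA_character_
    env$start[id] <- node$start; env$end[id] <- node$end
    env$parent[id] <- parent_id
    env$children[[id]] <- integer()
    env$nodes[[id]] <- node
    if (is_leaf(node)) {
      env$leaves <- c(env$leaves, id)
      k <- length(env$leaves)
      env$first_leaf[id] <- k; env$last_leaf[id] <- k
    } else {
      kid_ids <- integer(length(node$children))
      for (j in seq_along(node$children)) {
        kid_ids[j] <- add(node$children[[j]], id)
      }
      env$children[[id]] <- kid_ids
      env$first_leaf[id] <- env$first_leaf[kid_ids[1L]]
      env$last_leaf[id] <- env$last_leaf[kid_ids[length(kid_ids)]]
    }
    id
  }
  add(tree, NA_integer_)
  as.list(env)
}

idx_descendants <- function(idx, i) {
  out <- integer()
  stack <- idx$children[[i]]
  while (length(stack)) {
    j <- stack[1L]; stack <- stack[-1L]
    out <- c(out, j)
    stack <- c(idx$children[[j]], stack)
  }
  out
}

idx_ancestors <- function(idx, i) {
  out <- integer()
  p <- idx$parent[i]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- idx$parent[p]
  }
  out
}

idx_leaf_tokens <- function(idx) idx$token[idx$leaves]

# yield of a node as a single string (tokens joined by spaces)
idx_yield <- function(idx, i) {
  fl <- idx$first_leaf[i]; ll <- idx$last_leaf[i]
  paste(idx$token[idx$leaves[fl:ll]], collapse = " ")
}

# ---- verb group head selection ------------------------------------------

.aux_words <- c("be", "am", "is", "are", "was", "were", "been", "being",
                "have", "has", "had", "having", "do", "does", "did",
                "can", "could", "may", "might", "must", "shall", "should",
                "will", "would", "to", "not", "n't")

.be_words <- c("be", "am", "is", "are", "was", "were", "been", "being")

# raising / ECM carriers treated as transparent for head selection: the
# semantic head of "is known to bind" is "bind"
.raising_words <- c("known", "shown", "found", "thought", "reported",
                    "seem", "seems", "seemed", "appear", "appears",
                    "appeared", "likely", "unlikely", "able")

verb_pre_re <- "^(VB[DGNPZ]?|MD|AUX|TO)$"

# Follow the dependent-auxiliary chain downward from a verbal projection,
# collecting verb words level by level; the head is the last main verb.
# Returns list(head = leaf id or NA, chain = character words, head_pos = tag)
vg_chain <- function(idx, vp) {
  chain_words <- character()
  chain_tags <- character()
  cur <- vp
  repeat {
    kids <- idx$children[[cur]]
    vkids <- kids[grepl(verb_pre_re, idx$label[kids])]
    for (v in vkids) {
      w <- idx$children[[v]]
      if (length(w) == 1L && !is.na(idx$token[w])) {
        chain_words <- c(chain_words, idx$token[w])
        chain_tags <- c(chain_tags, idx$label[v])
      }
    }
    vps <- kids[idx$label[kids] == "VP"]
    if (length(vps)) { cur <- vps[length(vps)]; next }
    # subject-less S complement (to-infinitives under raising verbs)
    scand <- kids[idx$label[kids] == "S"]
    desc <- NA_integer_
    for (s in scand) {
      sk <- idx$children[[s]]
      svp <- sk[idx$label[sk] == "VP"]
      if (!length(svp)) next
      before <- sk[seq_len(which(sk == svp[1L]) - 1L)]
      subj <- before[idx$label[before] == "NP"]
      if (!length(subj)) { desc <- svp[1L]; break }
    }
    if (!is.na(desc)) { cur <- desc; next }
    # raising adjectives: "is likely to bind"
    adjp <- kids[idx$label[kids] == "ADJP"]
    hop <- NA_integer_
    for (a in adjp) {
      ak <- idx$children[[a]]
      head_j <- ak[grepl("^(JJ|VBN|VBG)$", idx$label[ak])]
      hw <- if (length(head_j)) idx$token[idx$children[[head_j[1L]]][1L]] else ""
      if (!tolower(hw) %in% .raising_words) next
      for (s in ak[idx$label[ak] == "S"]) {
        sk <- idx$children[[s]]
        svp <- sk[idx$label[sk] == "VP"]
        if (length(svp)) { hop <- svp[1L]; break }
      }
      if (!is.na(hop)) break
    }
    if (!is.na(hop)) { cur <- hop; next }
    break
  }
  # head: rightmost verb preterminal of the final projection
  kids <- idx$children[[cur]]
  vkids <- kids[grepl("^(VB[DGNPZ]?|MD)$", idx$label[kids])]
  if (length(vkids)) {
    v <- vkids[length(vkids)]
    leaf <- idx$children[[v]][1L]
    return(list(head = leaf, chain = chain_words, head_tag = idx$label[v],
                head_vp = cur))
  }
  # fall back to the last collected non-auxiliary verb
  main <- which(!(tolower(chain_words) %in% .aux_words))
  if (length(main)) {
    # relocate the leaf id of that word (search within vp subtree)
    w <- chain_words[main[length(main)]]
    tg <- chain_tags[main[length(main)]]
    cand <- idx_descendants(idx, vp)
    cand <- cand[!is.na(idx$token[cand]) & idx$token[cand] == w]
    if (length(cand)) {
      return(list(head = cand[length(cand)], chain = chain_words,
                  head_tag = tg, head_vp = vp))
    }
  }
  list(head = NA_integer_, chain = chain_words, head_tag = NA_character_,
       head_vp = cur)
}

# passive iff the head is a past participle preceded by a be-auxiliary
vg_passive <- function(ch) {
  !is.na(ch$head_tag) && ch$head_tag == "VBN" &&
    any(tolower(ch$chain) %in% .be_words)
}

#' Select the head of a consecutive verb group
#'
#' Descends through nested verbal projections (auxiliaries, modals,
#' infinitival `to`, and raising carriers such as "known" or "likely")
#' and returns the last main verb, which is the semantic head of the
#' whole verb group: the head of "is known to bind" is "bind".
#'
#' @param vp a `parse_tree` node for a verbal projection (usually `VP`)
#' @return the word-leaf `parse_tree` of the head verb
#' @export
verb_group_head <- function(vp) {
  idx <- tree_index(vp)
  ch <- vg_chain(idx, 1L)
  if (is.na(ch$head)) stop("no verb leaf found in verbal projection")
  idx$nodes[[ch$head]]
}

# ---- nominal head selection ----------------------------------------------

nominal_leaf_re <- "^(NN|NNS|NNP|NNPS|PRP|CD|JJ)$"

# Head word of an NP: descend through the rightmost nominal child.
# Returns the word leaf id, or NA.
np_head_leaf <- function(idx, np) {
  cur <- np
  repeat {
    kids <- idx$children[[cur]]
    if (!length(kids)) return(if (!is.na(idx$token[cur])) cur else NA_integer_)
    # parenthetical material never supplies the head
    br <- which(idx$label[kids] %in% c("-LRB-", "-LSB-", "-LCB-", "PRN"))
    if (length(br) && br[1L] > 1L) kids <- kids[seq_len(br[1L] - 1L)]
    # rightmost nominal child, phrasal or preterminal, by position
    nom <- kids[idx$label[kids] %in% c("NP", "NX", "NML") |
                  grepl("^(NN|NNS|NNP|NNPS|PRP|CD)$", idx$label[kids])]
    if (length(nom)) {
      last <- nom[length(nom)]
      if (idx$label[last] %in% c("NP", "NX", "NML")) { cur <- last; next }
      return(idx$children[[last]][1L])
    }
    # fall back: rightmost adjectival/leaf-bearing child
    pre <- kids[grepl(nominal_leaf_re, idx$label[kids])]
    if (length(pre)) {
      v <- pre[length(pre)]
      return(idx$children[[v]][1L])
    }
    return(NA_integer_)
  }
}
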