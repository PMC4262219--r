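#' @title Synthetic document generator
#' @description
#' Generates documents (text, gold constituency parses, pre-annotated
#' entities, gold events) that exercise every pattern template,
#' simplification construct and referential link type, so the whole
#' pipeline can be tested end to end without any corpus. Each sentence
#' is built compositionally from a base template realization ("<E1>
#' phosphorylates <E2>", "binding of <E1> to <E2>", ...) whose gold tree
#' is constructed alongside the text, then optionally complicated by an
#' operator (theme coordination, relative-clause wrapping, apposition,
#' parenthetical, member-collection or hyponymy constructions) that
#' transforms text, tree and gold jointly, so gold events are known by
#' construction. Entity names are synthetic (PROT1, PROT2, ...) to avoid
#' accidental lexicon hits; trees are never produced by a parser.
#' @name fixtures
NULL

tkx <- function(tag, word) {
  new_parse_tree(tag, children = list(new_parse_tree(word, token = word)))
}
phx <- function(label, ...) new_parse_tree(label, children = list(...))
npx <- function(name) phx("NP", tkx("NNP", name))
period <- function() tkx(".", ".")

#' Built-in trigger specifications for the synthetic documents
#'
#' @return spec file content (single string) covering the six relation
#'   types used by the generator
#' @export
fixture_spec_text <- function() {
paste(
"trigger: phosphorylate",
"relation: Phosphorylation",
"frame: NP0/NP1",
"type: NP0 = GGP",
"type: NP1 = GGP|protein_part",
"role: NP0 = agent",
"role: NP1 = theme",
"direction: directional",
"affixes: -ion, under-, hyper-",
"",
"trigger: express",
"relation: Gene_expression",
"frame: NP0/NP1",
"type: NP0 = GGP",
"type: NP1 = GGP|gene",
"role: NP0 = agent",
"role: NP1 = theme",
"direction: directional",
"affixes: -ion, over-, co-, non-, re-",
"",
"trigger: transcribe",
"relation: Transcription",
"frame: NP0/NP1",
"type: NP0 = GGP",
"type: NP1 = GGP|rna",
"role: NP0 = agent",
"role: NP1 = theme",
"direction: directional",
"affixes: -tion",
"",
"trigger: cleave",
"relation: Protein_catabolism",
"frame: NP0/NP1",
"type: NP0 = GGP",
"type: NP1 = GGP|protein_part",
"role: NP0 = agent",
"role: NP1 = theme",
"direction: directional",
"affixes: -age",
"",
"trigger: degrade",
"relation: Protein_catabolism",
"frame: NP0/NP1",
"type: NP0 = GGP",
"type: NP1 = GGP|protein_part",
"role: NP0 = agent",
"role: NP1 = theme",
"direction: directional",
"affixes: -tion",
"",
"trigger: bind",
"relation: Binding",
"frame: NP0/NP1",
"type: NP0 = GGP|protein_part",
"type: NP1 = GGP|protein_part",
"role: NP0 = theme",
"role: NP1 = theme",
"direction: non-directional",
"affixes: DNA-",
"",
"trigger: interact",
"relation: Binding",
"frame: NP0/NP1",
"type: NP0 = GGP|protein_part",
"type: NP1 = GGP|protein_part",
"role: NP0 = theme",
"role: NP1 = theme",
"direction: non-directional",
"affixes: -ion",
"",
"trigger: secrete",
"relation: Localization",
"frame: NP0/NP1",
"type: NP0 = GGP",
"type: NP1 = GGP",
"role: NP0 = agent",
"role: NP1 = theme",
"direction: directional",
"affixes: -ion",
"",
"trigger: accumulate",
"relation: Localization",
"frame: NP1",
"type: NP1 = GGP",
"role: NP1 = theme",
"direction: directional",
"affixes: -ation",
sep = "\n")
}

gold_ev <- function(relation, trigger_word, themes, agents = character()) {
  list(relation = relation, trigger_word = trigger_word,
       themes = themes, agents = agents)
}

# Each builder: function(e) with e = entity name vector, returning
# list(tree, gold, theme = name of the standalone theme entity NP (or
# NA), ops = complication ops applicable to this sentence shape)
.theme_ops <- c("coordinate_theme", "insert_apposition",
                "insert_parenthetical", "insert_member_collection",
                "insert_hyponymy_cue")

fixture_builders <- function() {
  list(
  V1 = function(e) list(
    tree = phx("S", npx(e[1]),
               phx("VP", tkx("VBZ", "phosphorylates"), npx(e[2])),
               period()),
    gold = list(gold_ev("Phosphorylation", "phosphorylates", e[2], e[1])),
    theme = e[2], ops = .theme_ops),
  V2 = function(e) list(
    tree = phx("S", npx(e[1]),
               phx("VP", tkx("VBZ", "expresses"),
                   phx("ADVP", tkx("RB", "abundantly")), npx(e[2])),
               period()),
    gold = list(gold_ev("Gene_expression", "expresses", e[2], e[1])),
    theme = e[2], ops = .theme_ops),
  V3 = function(e) list(
    tree = phx("S", npx(e[2]),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "phosphorylated"))),
               period()),
    gold = list(gold_ev("Phosphorylation", "phosphorylated", e[2])),
    theme = e[2], ops = c(.theme_ops, "wrap_relative_clause")),
  V4 = function(e) list(
    tree = phx("S", npx(e[2]),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "cleaved"),
                       phx("PP", tkx("IN", "by"), npx(e[1])))),
               period()),
    gold = list(gold_ev("Protein_catabolism", "cleaved", e[2], e[1])),
    theme = e[2], ops = c(.theme_ops, "wrap_relative_clause")),
  V5 = function(e) list(
    tree = phx("S", npx(e[1]),
               phx("VP", tkx("VBZ", "interacts"),
                   phx("PP", tkx("IN", "with"), npx(e[2]))),
               period()),
    gold = list(gold_ev("Binding", "interacts", c(e[1], e[2]))),
    theme = NA_character_, ops = character()),
  V6 = function(e) list(
    tree = phx("S",
               phx("NP", npx(e[1]), tkx("CC", "and"), npx(e[2])),
               phx("VP", tkx("VBP", "interact")),
               period()),
    gold = list(gold_ev("Binding", "interact", c(e[1], e[2]))),
    theme = NA_character_, ops = character()),
  V7 = function(e) list(
    tree = phx("S", npx(e[2]),
               phx("VP", tkx("VBZ", "accumulates")),
               period()),
    gold = list(gold_ev("Localization", "accumulates", e[2])),
    theme = e[2], ops = c("coordinate_theme", "insert_apposition")),
  N1 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("NN", "phosphorylation")),
                   phx("PP", tkx("IN", "of"), npx(e[2]))),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "detected"))),
               period()),
    gold = list(gold_ev("Phosphorylation", "phosphorylation", e[2])),
    theme = e[2], ops = .theme_ops),
  N2 = function(e) list(
    tree = phx("S",
               phx("NP", tkx("NNP", e[2]), tkx("NN", "degradation")),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "observed"))),
               period()),
    gold = list(gold_ev("Protein_catabolism", "degradation", e[2])),
    theme = NA_character_, ops = character()),
  N3 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("NN", "expression")),
                   phx("PP", tkx("IN", "of"), npx(e[2])),
                   phx("PP", tkx("IN", "by"), npx(e[1]))),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "observed"))),
               period()),
    gold = list(gold_ev("Gene_expression", "expression", e[2], e[1])),
    theme = e[2], ops = c("coordinate_theme")),
  N4 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("NNP", e[2]), tkx("POS", "'s")),
                   tkx("NN", "phosphorylation")),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "detected"))),
               period()),
    gold = list(gold_ev("Phosphorylation", "phosphorylation", e[2])),
    theme = NA_character_, ops = character()),
  N5 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("NN", "binding")),
                   phx("PP", tkx("IN", "of"), npx(e[1])),
                   phx("PP", tkx("TO", "to"), npx(e[2]))),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "observed"))),
               period()),
    gold = list(gold_ev("Binding", "binding", c(e[1], e[2]))),
    theme = NA_character_, ops = character()),
  N6 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("DT", "the"),
                             tkx("NN", "interaction")),
                   phx("PP", tkx("IN", "between"),
                       phx("NP", npx(e[1]), tkx("CC", "and"), npx(e[2])))),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "studied"))),
               period()),
    gold = list(gold_ev("Binding", "interaction", c(e[1], e[2]))),
    theme = NA_character_, ops = character()),
  N7 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("NNP", e[1]), tkx("NN", "binding")),
                   phx("PP", tkx("TO", "to"), npx(e[2]))),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "detected"))),
               period()),
    gold = list(gold_ev("Binding", "binding", c(e[1], e[2]))),
    theme = NA_character_, ops = character()),
  N8 = function(e) list(
    tree = phx("S",
               phx("NP", tkx("DT", "the"),
                   tkx("JJ", paste0(e[2], "-binding")),
                   tkx("NN", "activity")),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "measured"))),
               period()),
    gold = list(gold_ev("Binding", paste0(e[2], "-binding"), e[2])),
    theme = NA_character_, ops = character()),
  N9 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("NN", "degradation")),
                   phx("PP", tkx("IN", "of"), npx(e[2])),
                   phx("PP", tkx("IN", "by"), npx(e[1]))),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "observed"))),
               period()),
    gold = list(gold_ev("Protein_catabolism", "degradation", e[2], e[1])),
    theme = e[2], ops = c("coordinate_theme")),
  A1 = function(e) list(
    tree = phx("S",
               phx("NP", tkx("VBN", "phosphorylated"), tkx("NNP", e[2])),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "purified"))),
               period()),
    gold = list(gold_ev("Phosphorylation", "phosphorylated", e[2])),
    theme = NA_character_, ops = character()),
  A2 = function(e) list(
    tree = phx("S",
               phx("NP", tkx("DT", "the"), tkx("VBG", "phosphorylating"),
                   tkx("NN", "enzyme")),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "purified"))),
               period()),
    gold = list(),  # an agent alone cannot form an event
    theme = NA_character_, ops = character()),
  A3 = function(e) list(
    tree = phx("S",
               phx("NP", phx("NP", tkx("VBG", "interacting"),
                             tkx("NNS", "proteins")),
                   phx("PP", tkx("JJ", "such"), tkx("IN", "as"),
                       phx("NP", npx(e[1]), tkx("CC", "and"), npx(e[2])))),
               phx("VP", tkx("VBD", "were"),
                   phx("VP", tkx("VBN", "studied"))),
               period()),
    gold = list(gold_ev("Binding", "interacting", c(e[1], e[2]))),
    theme = NA_character_, ops = character()),
  A4 = function(e) list(
    tree = phx("S", npx(e[2]),
               phx("VP", tkx("VBD", "was"),
                   phx("ADJP", tkx("VBN", "phosphorylated"))),
               period()),
    gold = list(gold_ev("Phosphorylation", "phosphorylated", e[2])),
    theme = e[2], ops = c("coordinate_theme", "insert_apposition")),
  Z1 = function(e) list(
    tree = phx("S", npx(e[1]),
               phx("VP", tkx("VBZ", "activates"), npx(e[2]),
                   phx("PP", tkx("IN", "via"),
                       phx("NP", tkx("NN", "phosphorylation")))),
               period()),
    gold = list(gold_ev("Phosphorylation", "phosphorylation", e[2])),
    theme = e[2], ops = c("coordinate_theme", "insert_parenthetical")),
  Z2 = function(e) list(
    tree = phx("S",
               phx("PP", tkx("IN", "Upon"),
                   phx("NP", tkx("NN", "secretion"))),
               tkx(",", ","), npx(e[2]),
               phx("VP", tkx("VBD", "was"),
                   phx("VP", tkx("VBN", "purified"))),
               period()),
    gold = list(gold_ev("Localization", "secretion", e[2])),
    theme = e[2], ops = c("coordinate_theme")),
  Z3 = function(e) list(
    tree = phx("S", npx(e[2]),
               phx("VP", tkx("VBZ", "undergoes"),
                   phx("NP", tkx("NN", "degradation"))),
               period()),
    gold = list(gold_ev("Protein_catabolism", "degradation", e[2])),
    theme = e[2], ops = c("coordinate_theme", "insert_apposition")),
  Z4 = function(e) list(
    tree = phx("S",
               phx("S", npx(e[1]),
                   phx("VP", tkx("VBZ", "cleaves"), npx(e[2]))),
               tkx("CC", "and"),
               phx("S", phx("NP", tkx("NN", "cleavage")),
                   phx("VP", tkx("VBD", "was"),
                       phx("VP", tkx("VBN", "detected")))),
               period()),
    gold = list(gold_ev("Protein_catabolism", "cleaves", e[2], e[1]),
                gold_ev("Protein_catabolism", "cleavage", e[2])),
    theme = NA_character_, ops = character()),
  Z5 = function(e) list(
    tree = phx("S", npx(e[1]),
               phx("VP",
                   phx("VP", tkx("VBD", "cleaved"), npx(e[2])),
                   tkx("CC", "and"),
                   phx("VP", tkx("VBD", "induced"),
                       phx("NP", tkx("NN", "degradation")))),
               period()),
    gold = list(gold_ev("Protein_catabolism", "cleaved", e[2], e[1]),
                gold_ev("Protein_catabolism", "degradation", e[2])),
    theme = NA_character_, ops = character()),
  Z6 = function(e) list(
    tree = phx("S", npx(e[2]),
               phx("VP", tkx("VBD", "resulted"),
                   phx("PP", tkx("IN", "in"),
                       phx("NP", tkx("NN", "secretion")))),
               period()),
    gold = list(gold_ev("Localization", "secretion", e[2])),
    theme = e[2], ops = c("coordinate_theme"))
  )
}

# ---- complication operators ---------------------------------------------

# replace the unique standalone entity NP (NP (NNP name)) by f(node)
replace_np <- function(tree, name, f) {
  if (is_leaf(tree)) return(tree)
  if (tree$label == "NP" && length(tree$children) == 1L) {
    k <- tree$children[[1L]]
    if (!is_leaf(k) && length(k$children) == 1L &&
        is_leaf(k$children[[1L]]) && k$children[[1L]]$token == name) {
      return(f(tree))
    }
  }
  tree$children <- lapply(tree$children, replace_np, name = name, f = f)
  tree
}

apply_op <- function(op, plan, extra) {
  th <- plan$theme
  if (op == "coordinate_theme") {
    plan$tree <- replace_np(plan$tree, th, function(np) {
      phx("NP", np, tkx("CC", "and"), npx(extra))
    })
    add <- list()
    for (g in plan$gold) {
      if (th %in% g$themes) {
        g2 <- g
        g2$themes[g2$themes == th] <- extra
        add <- c(add, list(g2))
      }
    }
    plan$gold <- c(plan$gold, add)
  } else if (op == "insert_apposition") {
    plan$tree <- replace_np(plan$tree, th, function(np) {
      phx("NP", np, tkx(",", ","),
          phx("NP", tkx("DT", "a"), tkx("JJ", "nuclear"),
              tkx("NN", "factor")),
          tkx(",", ","))
    })
  } else if (op == "insert_parenthetical") {
    plan$tree <- replace_np(plan$tree, th, function(np) {
      phx("NP", phx("NP", tkx("DT", "the"), tkx("NN", "complex")),
          tkx("-LRB-", "("), np, tkx("-RRB-", ")"))
    })
  } else if (op == "insert_member_collection") {
    plan$tree <- replace_np(plan$tree, th, function(np) {
      phx("NP", phx("NP", tkx("JJ", "several"), tkx("NNS", "proteins")),
          phx("PP", tkx("VBG", "including"),
              phx("NP", np, tkx("CC", "and"), npx(extra))))
    })
    add <- list()
    for (g in plan$gold) {
      if (th %in% g$themes) {
        g2 <- g
        g2$themes[g2$themes == th] <- extra
        add <- c(add, list(g2))
      }
    }
    plan$gold <- c(plan$gold, add)
  } else if (op == "insert_hyponymy_cue") {
    plan$tree <- replace_np(plan$tree, th, function(np) {
      phx("NP", phx("NP", tkx("DT", "a"), tkx("JJ", "nuclear"),
                    tkx("NN", "factor")),
          phx("VP", tkx("VBN", "identified"),
              phx("PP", tkx("IN", "as"), np)))
    })
  } else if (op == "wrap_relative_clause") {
    # (S subj VP .) -> (S (NP subj , (SBAR which (S VP)) ,) was studied .)
    kids <- plan$tree$children
    labs <- vapply(kids, function(k) k$label, character(1))
    si <- which(labs == "NP")[1L]
    vi <- which(labs == "VP")[1L]
    if (!is.na(si) && !is.na(vi)) {
      subj <- kids[[si]]
      vp <- kids[[vi]]
      plan$tree <- phx(
        "S",
        phx("NP", subj, tkx(",", ","),
            phx("SBAR", phx("WHNP", tkx("WDT", "which")), phx("S", vp)),
            tkx(",", ",")),
        phx("VP", tkx("VBD", "was"), phx("VP", tkx("VBN", "studied"))),
        period())
    }
  }
  plan
}

#' A fixture recipe
#'
#' @param seed integer RNG seed; a fixed seed makes the output
#'   byte-identical across runs
#' @param n_sentences number of sentences to generate
#' @param template_mix named numeric vector of weights over template
#'   ids; defaults to uniform over all 26
#' @param complication_ops which complication operators may be applied
#' @param complication_prob probability that an applicable operator is
#'   applied to a sentence
#' @param entity_vocab entity name pool
#' @return a `fixture_recipe` list
#' @export
fixture_recipe <- function(seed = 1L, n_sentences = 20L,
                           template_mix = NULL,
                           complication_ops = c(
                             "coordinate_theme", "wrap_relative_clause",
                             "insert_apposition", "insert_parenthetical",
                             "insert_member_collection",
                             "insert_hyponymy_cue"),
                           complication_prob = 0.7,
                           entity_vocab = paste0("PROT", 1:40)) {
  builders <- fixture_builders()
  if (is.null(template_mix)) {
    template_mix <- stats::setNames(rep(1 / length(builders),
                                        length(builders)),
                                    names(builders))
  }
  template_mix <- template_mix / sum(template_mix)
  structure(list(seed = as.integer(seed),
                 n_sentences = as.integer(n_sentences),
                 template_mix = template_mix,
                 complication_ops = complication_ops,
                 complication_prob = complication_prob,
                 entity_vocab = entity_vocab),
            class = "fixture_recipe")
}

#' Generate a synthetic document bundle
#'
#' @param recipe a [fixture_recipe()]
#' @return a list with `text` (document text, one sentence per line),
#'   `parses` (bracketed parses, one per sentence), `offsets` (sentence
#'   offset matrix), `a1` (entity lines), `a2` (gold event lines),
#'   `gold` (a `gold_set`), and `doc` (a document object ready for
#'   [extract_document()])
#' @export
generate_fixtures <- function(recipe = fixture_recipe()) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(recipe$seed)
  builders <- fixture_builders()
  tids <- names(recipe$template_mix)
  sent_plans <- list()
  for (i in seq_len(recipe$n_sentences)) {
    tid <- sample(tids, 1L, prob = recipe$template_mix)
    ents <- sample(recipe$entity_vocab, 3L)
    plan <- builders[[tid]](ents[1:2])
    plan$template <- tid
    ops <- intersect(plan$ops, recipe$complication_ops)
    if (length(ops) && stats::runif(1) < recipe$complication_prob) {
      op <- if (length(ops) == 1L) ops else sample(ops, 1L)
      plan <- apply_op(op, plan, ents[3L])
      plan$op <- op
    }
    sent_plans[[i]] <- plan
  }
  layout_bundle(sent_plans)
}

layout_bundle <- function(sent_plans) {
  sent_texts <- character(length(sent_plans))
  trees <- vector("list", length(sent_plans))
  offsets <- matrix(0L, nrow = length(sent_plans), ncol = 2L)
  start <- 0L
  mentions <- list()
  gold_events <- list()
  for (i in seq_along(sent_plans)) {
    plan <- sent_plans[[i]]
    leaves <- collect_leaves(plan$tree)
    toks <- vapply(leaves, function(l) l$token, character(1))
    stext <- paste(toks, collapse = " ")
    tree <- align_spans(plan$tree, stext)
    sent_texts[i] <- stext
    trees[[i]] <- tree
    offsets[i, ] <- c(start, start + nchar(stext))
    # token spans in document coordinates
    tok_spans <- token_spans(stext, start)
    # entity mentions: PROTn tokens and PROTn- prefixes
    name_span <- list()
    for (k in seq_along(toks)) {
      if (grepl("^PROT[0-9]+$", toks[k])) {
        mentions[[length(mentions) + 1L]] <- new_entity_mention(
          tok_spans[[k]], toks[k], "GGP", "preannotated")
        name_span[[toks[k]]] <- tok_spans[[k]]
      } else if (grepl("^PROT[0-9]+-", toks[k])) {
        nm <- sub("-.*$", "", toks[k])
        sp <- c(tok_spans[[k]][1], tok_spans[[k]][1] + nchar(nm))
        mentions[[length(mentions) + 1L]] <- new_entity_mention(
          sp, nm, "GGP", "preannotated")
        name_span[[nm]] <- sp
      }
    }
    for (g in plan$gold) {
      at <- which(tolower(toks) == tolower(g$trigger_word))[1L]
      if (is.na(at)) stop("trigger word '", g$trigger_word,
                          "' not found in generated sentence")
      gold_events[[length(gold_events) + 1L]] <- list(
        relation = g$relation, trigger_span = tok_spans[[at]],
        trigger_text = toks[at],
        themes = lapply(g$themes, function(nm) name_span[[nm]]),
        agents = lapply(g$agents, function(nm) name_span[[nm]]))
    }
    start <- start + nchar(stext) + 1L
  }
  text <- paste(sent_texts, collapse = "\n")
  # number the mentions and build .a1
  a1 <- character(length(mentions))
  for (k in seq_along(mentions)) {
    mentions[[k]]$id <- paste0("T", k)
    a1[k] <- paste0("T", k, "\tProtein ", mentions[[k]]$span[1], " ",
                    mentions[[k]]$span[2], "\t", mentions[[k]]$text)
  }
  span_id <- stats::setNames(
    vapply(mentions, function(m) m$id, character(1)),
    vapply(mentions, function(m) paste(m$span[1], m$span[2]), character(1)))
  find_mention <- function(sp) {
    mentions[[which(vapply(mentions, function(m) {
      identical(as.integer(m$span), as.integer(sp))
    }, logical(1)))[1L]]]
  }
  ev_objs <- lapply(gold_events, function(g) {
    new_event(g$relation, g$trigger_span, g$trigger_text,
              lapply(g$themes, find_mention),
              lapply(g$agents, find_mention))
  })
  a2 <- write_a2(ev_objs, text, mentions)
  parses <- vapply(trees, deparse_bracketed, character(1))
  sentences <- lapply(seq_along(trees), function(i) {
    list(text = sent_texts[i], start = offsets[i, 1], tree = trees[[i]])
  })
  gold <- read_standoff(text, a1, a2)
  list(text = text, parses = parses, offsets = offsets, a1 = a1, a2 = a2,
       gold = gold, doc = make_document(text, sentences, mentions))
}

token_spans <- function(stext, shift = 0L) {
  m <- gregexpr("\\S+", stext)[[1]]
  lens <- attr(m, "match.length")
  lapply(seq_along(m), function(i) {
    c(m[i] - 1L + shift, m[i] - 1L + lens[i] + shift)
  })
}

# bracketed serialization with PTB bracket escapes, round-trips through
# read_bracketed
deparse_bracketed <- function(x) {
  esc <- c("(" = "-LRB-", ")" = "-RRB-", "[" = "-LSB-", "]" = "-RSB-",
           "{" = "-LCB-", "}" = "-RCB-")
  walk <- function(node) {
    if (is_leaf(node)) {
      tok <- node$token
      hit <- esc[tok]
      return(if (is.na(hit)) tok else unname(hit))
    }
    paste0("(", node$label, " ",
           paste(vapply(node$children, walk, character(1)), collapse = " "),
           ")")
  }
  walk(x)
}
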