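#' @title The fixed inventory of pattern templates
#' @description
#' Each pattern template is an abstract element sequence (literals, one
#' trigger placeholder `V_tr`/`N_tr`/`Adj_tr`, and at most one argument
#' placeholder `NP_i`) plus constraints. Instantiated with a concrete
#' trigger form it yields a lexico-syntactic pattern: a compiled tree
#' pattern that anchors the trigger in a parse, together with a
#' structural validation step (verb-group head selection, voice,
#' nominal-head checks) and an argument recovery rule.
#'
#' The inventory holds 26 templates in four groups: 7 verbal, 9 nominal,
#' 4 adjectival and 6 null-argument (elliptical) templates. Verbal
#' templates realize active/passive clauses and prepositional
#' co-arguments; nominal templates realize arguments of process
#' nominalizations (of-phrases, compounds, possessives, by-phrases,
#' "between"/"to"/"with" phrases, hyphenated compounds); adjectival
#' templates realize participial modifiers and predicatives; and
#' null-argument templates recover an elided theme from the surrounding
#' clause ("via", "upon", light verbs, observation/cause/result frames).
#' @name pattern_library
NULL

tok_regex <- function(surface) {
  esc <- gsub("([][{}()*+?.\\^$|])", "\\\\\\1", surface)
  paste0("/^(?i)", esc, "$/")
}

.verb_pre <- "/^(VB[DGNPZ]?|MD)$/"
.nn_pre <- "/^NNS?$/"

# ---- structural helpers shared by template post-checks -------------------

# climb from a VP to the top of its consecutive verb group
tmpl_top_vp <- function(idx, vp) {
  cur <- vp
  repeat {
    p <- idx$parent[cur]
    if (is.na(p)) break
    if (idx$label[p] == "VP") { cur <- p; next }
    if (idx$label[p] == "S" || idx$label[p] == "ADJP") {
      pp <- idx$parent[p]
      if (!is.na(pp) && idx$label[pp] == "VP") {
        if (idx$label[p] == "S") {
          kids <- idx$children[[p]]
          vpos <- which(idx$label[kids] == "VP")
          if (length(vpos)) {
            before <- kids[seq_len(vpos[1L] - 1L)]
            if (!any(idx$label[before] == "NP")) { cur <- pp; next }
          }
        } else { cur <- pp; next }
      }
    }
    break
  }
  cur
}

tmpl_head_info <- function(idx, vp) {
  top <- tmpl_top_vp(idx, vp)
  vg_chain(idx, top)
}

tmpl_is_head <- function(idx, vp, trig) {
  ch <- tmpl_head_info(idx, vp)
  identical(ch$head, trig)
}

tmpl_active_head <- function(idx, vp, trig) {
  ch <- tmpl_head_info(idx, vp)
  identical(ch$head, trig) && !vg_passive(ch)
}

tmpl_passive_head <- function(idx, vp, trig) {
  ch <- tmpl_head_info(idx, vp)
  identical(ch$head, trig) && vg_passive(ch)
}

precedes <- function(idx, a, b) idx$end[a] <= idx$start[b]

np_head_is <- function(idx, np, trig) {
  h <- np_head_leaf(idx, np)
  !is.na(h) && identical(h, trig)
}

# the NP immediately containing the trigger's preterminal
trig_base <- function(idx, trig) {
  pre <- idx$parent[trig]
  idx$parent[pre]
}

# preceding nominal sibling of the trigger inside its base NP (compound
# modifier), or NA
left_compound <- function(idx, trig) {
  pre <- idx$parent[trig]
  base <- idx$parent[pre]
  if (is.na(base)) return(NA_integer_)
  kids <- idx$children[[base]]
  at <- match(pre, kids)
  if (is.na(at) || at == 1L) return(NA_integer_)
  before <- kids[seq_len(at - 1L)]
  nom <- before[idx$label[before] %in% c("NP", "NX", "NML", "NN", "NNS",
                                         "NNP", "NNPS")]
  if (!length(nom)) NA_integer_ else nom[length(nom)]
}

# a bare nominal trigger: no of-phrase argument and no compound modifier
np_bare <- function(idx, np, trig) {
  if (!is.na(left_compound(idx, trig))) return(FALSE)
  kids <- idx$children[[np]]
  for (pp in kids[idx$label[kids] == "PP"]) {
    ink <- idx$children[[pp]]
    inp <- ink[idx$label[ink] %in% c("IN", "TO")]
    if (length(inp)) {
      w <- tolower(idx$token[idx$children[[inp[1L]]][1L]])
      if (w == "of") return(FALSE)
    }
  }
  TRUE
}

nearest_ancestor <- function(idx, n, labels) {
  p <- idx$parent[n]
  while (!is.na(p)) {
    if (idx$label[p] %in% labels) return(p)
    p <- idx$parent[p]
  }
  NA_integer_
}

subject_of <- function(idx, s) {
  kids <- idx$children[[s]]
  vpos <- which(idx$label[kids] == "VP")
  stop_at <- if (length(vpos)) vpos[1L] else length(kids) + 1L
  nps <- kids[idx$label[kids] == "NP"]
  nps <- nps[match(nps, kids) < stop_at]
  if (!length(nps)) NA_integer_ else nps[length(nps)]
}

.observe_verbs <- c("observed", "detected", "seen", "noted", "reported",
                    "measured")

# accept a candidate; cand fields: trig, arg (node id or NA), plus flags
cand <- function(trig, arg = NA_integer_, hyphen = FALSE, defer = NA_character_) {
  list(trig = trig, arg = arg, hyphen = hyphen, defer = defer)
}

# ---- template definitions ------------------------------------------------

# Each definition: group, elements (documentation form of the beta
# sequence), slot (captured argument slot; NA for null-argument),
# dir_only / nondir_only, frames tag, expand (split a coordinated
# argument into one pair per conjunct), form_ok(form), expr(T) with T the
# trigger token regex, post(idx, ids) -> list of candidates.
.template_defs <- local({
  verb_form <- function(f) f$category %in% c("verb_finite", "verb_base")
  ppart_form <- function(f) f$category == "verb_ppart"
  nom_form <- function(f) f$category == "nominal" &&
    identical(f$nominal_class, "process")
  adj_past <- function(f) f$category == "adjectival" &&
    grepl("past participle|-ive|-tic|-al", f$derivation)
  adj_pres <- function(f) f$category == "adjectival" &&
    grepl("present participle", f$derivation)
  adj_any <- function(f) f$category == "adjectival"

  list(
    V1 = list(
      group = "verbal", elements = "NP_0 V_tr", slot = 0L,
      frames = "transitive", form_ok = verb_form,
      expr = function(T) paste0(
        "S=cl < NP=arg and S=cl < (VP=vp << (", .verb_pre, " < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!precedes(idx, ids["arg"], ids["vp"])) return(NULL)
        if (!tmpl_active_head(idx, ids[["vp"]], ids[["trig"]])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    V2 = list(
      group = "verbal", elements = "V_tr NP_1", slot = 1L,
      frames = "transitive", form_ok = verb_form,
      expr = function(T) paste0(
        "VP=vp < (", .verb_pre, " < ", T, "=trig) and VP=vp < NP=arg"),
      post = function(idx, ids) {
        if (!precedes(idx, ids["trig"], ids["arg"])) return(NULL)
        if (!tmpl_active_head(idx, ids[["vp"]], ids[["trig"]])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    V3 = list(
      group = "verbal", elements = "NP_1 be V_tr:ppart", slot = 1L,
      frames = "transitive", form_ok = ppart_form,
      expr = function(T) paste0(
        "S=cl < NP=arg and S=cl < (VP=vp << (/^VBN$/ < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!precedes(idx, ids["arg"], ids["vp"])) return(NULL)
        if (!tmpl_passive_head(idx, ids[["vp"]], ids[["trig"]])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    V4 = list(
      group = "verbal", elements = "be V_tr:ppart by NP_0", slot = 0L,
      frames = "transitive", form_ok = ppart_form,
      expr = function(T) paste0(
        "VP=vp < (/^VBN$/ < ", T, "=trig) and VP=vp < ",
        "(PP=pp < (IN < /^(?i)by$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!tmpl_passive_head(idx, ids[["vp"]], ids[["trig"]])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    V5 = list(
      group = "verbal", elements = "V_tr with|to NP_1", slot = 1L,
      frames = "transitive", nondir_only = TRUE,
      form_ok = function(f) f$category %in%
        c("verb_finite", "verb_base", "verb_ppart"),
      expr = function(T) paste0(
        "VP=vp < (", .verb_pre, " < ", T, "=trig) and VP=vp < ",
        "(PP=pp < (/^(IN|TO)$/ < /^(?i)(with|to)$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!tmpl_is_head(idx, ids[["vp"]], ids[["trig"]])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    V6 = list(
      group = "verbal", elements = "NP_0 and NP_1 V_tr", slot = 0L,
      frames = "transitive", nondir_only = TRUE, expand = TRUE,
      form_ok = verb_form,
      expr = function(T) paste0(
        "S=cl < (NP=arg < CC) and S=cl < (VP=vp << (", .verb_pre,
        " < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!precedes(idx, ids["arg"], ids["vp"])) return(NULL)
        if (!tmpl_active_head(idx, ids[["vp"]], ids[["trig"]])) return(NULL)
        # reciprocal use: no direct object in the verb group
        ch <- tmpl_head_info(idx, ids[["vp"]])
        kids <- idx$children[[ch$head_vp]]
        if (any(idx$label[kids] == "NP")) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    V7 = list(
      group = "verbal", elements = "NP_1 V_tr (unaccusative)", slot = 1L,
      frames = "unaccusative", form_ok = verb_form,
      expr = function(T) paste0(
        "S=cl < NP=arg and S=cl < (VP=vp << (", .verb_pre, " < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!precedes(idx, ids["arg"], ids["vp"])) return(NULL)
        if (!tmpl_active_head(idx, ids[["vp"]], ids[["trig"]])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),

    N1 = list(
      group = "nominal", elements = "N_tr of NP_1", slot = 1L,
      frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "NP=np << (", .nn_pre, " < ", T, "=trig) and NP=np < ",
        "(PP=pp < (IN < /^(?i)of$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], ids["pp"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    N2 = list(
      group = "nominal", elements = "NP_1 N_tr (compound)", slot = 1L,
      frames = "all", form_ok = nom_form,
      expr = function(T) paste0("NP=np < (", .nn_pre, " < ", T, "=trig)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        lc <- left_compound(idx, ids[["trig"]])
        if (is.na(lc)) return(NULL)
        list(cand(ids[["trig"]], lc))
      }),
    N3 = list(
      group = "nominal", elements = "N_tr ... by NP_0", slot = 0L,
      frames = "transitive", form_ok = nom_form,
      expr = function(T) paste0(
        "NP=np << (", .nn_pre, " < ", T, "=trig) and NP=np < ",
        "(PP=pp < (IN < /^(?i)by$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], ids["pp"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    N4 = list(
      group = "nominal", elements = "NP_1 's N_tr", slot = 1L,
      frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "NP=np < (NP=arg < POS) and NP=np < (", .nn_pre, " < ", T, "=trig)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["arg"], ids["trig"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    N5 = list(
      group = "nominal", elements = "N_tr of NP_0 to|with NP_1", slot = 1L,
      frames = "transitive", nondir_only = TRUE, form_ok = nom_form,
      expr = function(T) paste0(
        "NP=np << (", .nn_pre, " < ", T, "=trig) and ",
        "NP=np < (PP < (IN < /^(?i)of$/)) and ",
        "NP=np < (PP=pp < (/^(IN|TO)$/ < /^(?i)(to|with)$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], ids["pp"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    N6 = list(
      group = "nominal", elements = "N_tr between NP_0 and NP_1", slot = 1L,
      frames = "transitive", nondir_only = TRUE, expand = TRUE,
      form_ok = nom_form,
      expr = function(T) paste0(
        "NP=np << (", .nn_pre, " < ", T, "=trig) and NP=np < ",
        "(PP=pp < (IN < /^(?i)between$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], ids["pp"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    N7 = list(
      group = "nominal", elements = "NP_0 N_tr to|with NP_1", slot = 1L,
      frames = "transitive", nondir_only = TRUE, form_ok = nom_form,
      expr = function(T) paste0(
        "NP=np << (", .nn_pre, " < ", T, "=trig) and NP=np < ",
        "(PP=pp < (/^(IN|TO)$/ < /^(?i)(to|with)$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (is.na(left_compound(idx, ids[["trig"]]))) return(NULL)
        if (!precedes(idx, ids["trig"], ids["pp"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),
    N8 = list(
      group = "nominal", elements = "NP_1-N_tr (hyphenated compound)",
      slot = 1L, frames = "transitive", form_ok = function(f) {
        f$category == "nominal" && identical(f$nominal_class, "process") ||
          f$category == "verb_prespart"
      },
      expr = function(T) {
        # T is /^(?i)surface$/ ; build /^(?i)\S+-surface$/
        inner <- sub("^/\\^\\(\\?i\\)", "", sub("\\$/$", "", T))
        paste0("/^(NN|NNS|JJ|VBG)$/ < /^(?i)\\S+-", inner, "$/=trig")
      },
      post = function(idx, ids) {
        list(cand(ids[["trig"]], NA_integer_, hyphen = TRUE))
      }),
    N9 = list(
      group = "nominal", elements = "N_tr of NP_1 by NP_0", slot = 0L,
      frames = "transitive", form_ok = nom_form,
      expr = function(T) paste0(
        "NP=np << (", .nn_pre, " < ", T, "=trig) and ",
        "NP=np < (PP < (IN < /^(?i)of$/)) and ",
        "NP=np < (PP=pp < (IN < /^(?i)by$/) and PP < NP=arg)"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], ids["pp"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),

    A1 = list(
      group = "adjectival", elements = "Adj_tr:ppart NP_1", slot = 1L,
      frames = "all", form_ok = adj_past,
      expr = function(T) paste0("NP=np < (/^(VBN|JJ)$/ < ", T, "=trig)"),
      post = function(idx, ids) {
        h <- np_head_leaf(idx, ids[["np"]])
        if (is.na(h) || identical(h, ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], h)) return(NULL)
        list(cand(ids[["trig"]], ids[["np"]]))
      }),
    A2 = list(
      group = "adjectival", elements = "Adj_tr:prespart NP_0", slot = 0L,
      frames = "transitive", dir_only = TRUE, form_ok = adj_pres,
      expr = function(T) paste0("NP=np < (/^(VBG|JJ)$/ < ", T, "=trig)"),
      post = function(idx, ids) {
        h <- np_head_leaf(idx, ids[["np"]])
        if (is.na(h) || identical(h, ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], h)) return(NULL)
        list(cand(ids[["trig"]], ids[["np"]]))
      }),
    A3 = list(
      group = "adjectival", elements = "Adj_tr:prespart NP_1 (reciprocal)",
      slot = 1L, frames = "transitive", nondir_only = TRUE,
      form_ok = adj_pres,
      expr = function(T) paste0("NP=np < (/^(VBG|JJ)$/ < ", T, "=trig)"),
      post = function(idx, ids) {
        h <- np_head_leaf(idx, ids[["np"]])
        if (is.na(h) || identical(h, ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["trig"], h)) return(NULL)
        list(cand(ids[["trig"]], ids[["np"]]))
      }),
    A4 = list(
      group = "adjectival", elements = "NP_1 be Adj_tr", slot = 1L,
      frames = "all", form_ok = adj_any,
      expr = function(T) paste0(
        "S=cl < NP=arg and S=cl < (VP=vp < (/^VB/ < ",
        "/^(?i)(is|are|was|were|be|been|being|remains?|remained)$/) ",
        "and VP < (ADJP << (/^(JJ|VBN|VBG)$/ < ", T, "=trig)))"),
      post = function(idx, ids) {
        if (!precedes(idx, ids["arg"], ids["vp"])) return(NULL)
        list(cand(ids[["trig"]], ids[["arg"]]))
      }),

    Z1 = list(
      group = "null_argument", elements = "via N_tr (theme = matrix object)",
      slot = 1L, frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "PP=pp < (IN < /^(?i)via$/) and PP=pp < (NP=np << (", .nn_pre,
        " < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        vp <- idx$parent[ids[["pp"]]]
        if (is.na(vp) || idx$label[vp] != "VP") return(NULL)
        kids <- idx$children[[vp]]
        objs <- kids[idx$label[kids] == "NP"]
        objs <- objs[idx$end[objs] <= idx$start[ids[["pp"]]]]
        if (!length(objs)) return(NULL)
        list(cand(ids[["trig"]], objs[length(objs)]))
      }),
    Z2 = list(
      group = "null_argument",
      elements = "upon|after|following N_tr , S (theme = matrix subject)",
      slot = 1L, frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "PP=pp < (IN < /^(?i)(upon|after|following)$/) and PP=pp < ",
        "(NP=np << (", .nn_pre, " < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!np_bare(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        s <- nearest_ancestor(idx, ids[["pp"]], "S")
        if (is.na(s)) return(NULL)
        subj <- subject_of(idx, s)
        if (is.na(subj) || identical(subj, ids[["np"]])) return(NULL)
        list(cand(ids[["trig"]], subj))
      }),
    Z3 = list(
      group = "null_argument", elements = "NP_1 undergo N_tr", slot = 1L,
      frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "VP=vp < (", .verb_pre,
        " < /^(?i)(undergo|undergoes|underwent|undergone|undergoing)$/) ",
        "and VP=vp < (NP=np << (", .nn_pre, " < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        s <- nearest_ancestor(idx, ids[["vp"]], "S")
        if (is.na(s)) return(NULL)
        subj <- subject_of(idx, s)
        if (is.na(subj)) return(NULL)
        list(cand(ids[["trig"]], subj))
      }),
    Z4 = list(
      group = "null_argument",
      elements = "N_tr be observed|detected|seen (theme from co-trigger)",
      slot = 1L, frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "S=cl < (NP=np << (", .nn_pre, " < ", T, "=trig)) and S=cl < VP=vp"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!np_bare(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!precedes(idx, ids["np"], ids["vp"])) return(NULL)
        ch <- tmpl_head_info(idx, ids[["vp"]])
        if (is.na(ch$head)) return(NULL)
        if (!tolower(idx$token[ch$head]) %in% .observe_verbs) return(NULL)
        if (!vg_passive(ch)) return(NULL)
        list(cand(ids[["trig"]], NA_integer_, defer = "other_theme"))
      }),
    Z5 = list(
      group = "null_argument",
      elements = "V_cause N_tr (theme = object of sister clause)",
      slot = 1L, frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "VP=vp < (", .verb_pre,
        " < /^(?i)(induce[ds]?|inducing|prevent(s|ed)?|preventing|",
        "cause[ds]?|causing|trigger(s|ed)?|triggering|block(s|ed)?|",
        "blocking|promote[ds]?|promoting|enhance[ds]?|enhancing)$/) ",
        "and VP=vp < (NP=np << (", .nn_pre, " < ", T, "=trig))"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        if (!np_bare(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        s <- nearest_ancestor(idx, ids[["vp"]], "S")
        if (is.na(s)) return(NULL)
        # rightmost object NP of a preceding sister verb phrase
        cands <- integer()
        for (d in idx_descendants(idx, s)) {
          if (idx$label[d] != "NP") next
          if (idx$end[d] > idx$start[ids[["vp"]]]) next
          p <- idx$parent[d]
          if (!is.na(p) && idx$label[p] == "VP" && p != ids[["vp"]]) {
            cands <- c(cands, d)
          }
        }
        if (!length(cands)) return(NULL)
        list(cand(ids[["trig"]], cands[which.max(idx$end[cands])]))
      }),
    Z6 = list(
      group = "null_argument",
      elements = "result in N_tr (theme = matrix subject)",
      slot = 1L, frames = "all", form_ok = nom_form,
      expr = function(T) paste0(
        "VP=vp < (", .verb_pre, " < /^(?i)(result(s|ed)?|resulting)$/) ",
        "and VP=vp < (PP=pp < (IN < /^(?i)in$/) and PP < (NP=np << (",
        .nn_pre, " < ", T, "=trig)))"),
      post = function(idx, ids) {
        if (!np_head_is(idx, ids[["np"]], ids[["trig"]])) return(NULL)
        s <- nearest_ancestor(idx, ids[["vp"]], "S")
        if (is.na(s)) return(NULL)
        subj <- subject_of(idx, s)
        if (is.na(subj)) return(NULL)
        list(cand(ids[["trig"]], subj))
      })
  )
})

template_field <- function(def, field, default) {
  v <- def[[field]]
  if (is.null(v)) default else v
}

#' Summary table of the template inventory
#'
#' @return a data.frame with one row per template: `id`, `group`,
#'   `elements`, `slot`, `directional_only`, `nondirectional_only`,
#'   `frames`, `expand_conjuncts`
#' @export
template_table <- function() {
  ids <- names(.template_defs)
  data.frame(
    id = ids,
    group = vapply(.template_defs, function(d) d$group, character(1)),
    elements = vapply(.template_defs, function(d) d$elements, character(1)),
    slot = vapply(.template_defs, function(d) d$slot, integer(1)),
    directional_only = vapply(.template_defs, template_field,
                              logical(1), field = "dir_only", default = FALSE),
    nondirectional_only = vapply(.template_defs, template_field, logical(1),
                                 field = "nondir_only", default = FALSE),
    frames = vapply(.template_defs, function(d) d$frames, character(1)),
    expand_conjuncts = vapply(.template_defs, template_field, logical(1),
                              field = "expand", default = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' List the fixed template inventory
#'
#' @param group optional filter, one of `"verbal"`, `"nominal"`,
#'   `"adjectival"`, `"null_argument"`
#' @return list of `pattern_template` objects (26 in total)
#' @export
list_templates <- function(group = NULL) {
  tt <- template_table()
  ids <- if (is.null(group)) tt$id else tt$id[tt$group %in% group]
  lapply(ids, function(id) {
    d <- .template_defs[[id]]
    row <- tt[tt$id == id, ]
    structure(
      list(id = id, group = d$group, elements = d$elements,
           captured_slot = if (d$group == "null_argument") NA_integer_ else d$slot,
           recovered_slot = d$slot,
           directional_only = row$directional_only,
           nondirectional_only = row$nondirectional_only,
           frames = d$frames, expand_conjuncts = row$expand_conjuncts),
      class = "pattern_template")
  })
}

#' @export
print.pattern_template <- function(x, ...) {
  cat("<pattern_template> ", x$id, " [", x$group, "]  ", x$elements, "\n",
      sep = "")
  invisible(x)
}

#' Instantiate pattern templates with trigger forms
#'
#' Takes the cross product of the frame's compatible templates and the
#' trigger forms whose category matches each template's group, and
#' compiles one lexico-syntactic pattern per combination by substituting
#' the form's surface string for the trigger placeholder. For a
#' non-directional trigger whose two roles differ, each slot-capturing
#' pattern additionally gets a role-swapped twin, so the pattern set is
#' closed under swapping of NP_0 and NP_1.
#'
#' @param spec a `trigger_spec`
#' @param forms list of `trigger_form`, usually
#'   `derive_trigger_forms(spec$root, spec$affixes)`
#' @param frame a `frame` from [select_frame()]
#' @return list of `lexsyn_pattern` objects
#' @export
generate_patterns <- function(spec, forms, frame) {
  out <- list()
  slot_idx <- vapply(spec$slots, function(s) s$index, integer(1))
  roles_differ <- spec$direction == "non-directional" &&
    length(unique(unlist(spec$roles))) > 1L
  for (tid in frame$compatible_templates) {
    d <- .template_defs[[tid]]
    slot <- d$slot
    if (!slot %in% slot_idx) {
      # a one-slot frame realizes its single slot regardless of the
      # template's canonical slot number
      slot <- slot_idx[1L]
    }
    seen <- character()
    for (f in forms) {
      if (!d$form_ok(f)) next
      # the same surface may qualify under two categories (e.g. a gerund
      # is both a process nominal and a present participle); one pattern
      # per (template, surface, slot) is enough
      if (f$surface %in% seen) next
      seen <- c(seen, f$surface)
      tp <- compile_pattern(d$expr(tok_regex(f$surface)))
      out[[length(out) + 1L]] <- new_lexsyn_pattern(tid, spec, f, tp, slot)
      if (roles_differ && frame$allows_swap && length(slot_idx) == 2L &&
          !is.na(d$slot)) {
        other <- setdiff(slot_idx, slot)
        out[[length(out) + 1L]] <-
          new_lexsyn_pattern(tid, spec, f, tp, other, swapped = TRUE)
      }
    }
  }
  out
}

new_lexsyn_pattern <- function(template_id, spec, form, tree_pattern, slot,
                               swapped = FALSE) {
  structure(list(template_id = template_id, spec = spec, form = form,
                 tree_pattern = tree_pattern, slot = as.integer(slot),
                 swapped = swapped),
            class = "lexsyn_pattern")
}

#' @export
print.lexsyn_pattern <- function(x, ...) {
  cat("<lexsyn_pattern> ", x$template_id, " '", x$form$surface, "' (",
      x$spec$relation, ", NP", x$slot, ")\n", sep = "")
  invisible(x)
}

#' Combine trigger-argument pairs into events
#'
#' Pairs extracted one argument at a time are merged when they share the
#' same trigger occurrence (relation and character span). Non-directional
#' relations collect all themes into one event; directional relations
#' split multiple themes into one event per theme, copying any agent.
#' Two agents on one directional trigger occurrence yield alternative
#' events (one per agent) with a warning.
#'
#' @param pairs list of `trigger_arg_pair` objects from one document
#' @return list of `event` objects
#' @export
pairs_to_events <- function(pairs) {
  if (!length(pairs)) return(list())
  key <- vapply(pairs, function(p) {
    paste(p$relation, p$trigger_span[1], p$trigger_span[2])
  }, character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- pairs[key == k]
    p1 <- grp[[1L]]
    roles <- vapply(grp, function(p) p$role, character(1))
    themes <- unique_mentions(lapply(grp[roles == "theme"], function(p) p$arg))
    agents <- unique_mentions(lapply(grp[roles == "agent"], function(p) p$arg))
    nondir <- identical(p1$direction, "non-directional")
    if (!length(themes)) next  # an event needs at least one theme
    if (length(agents) > 1L && !nondir) {
      warning("two agents for one directional trigger occurrence of '",
              p1$relation, "'; emitting alternative events")
    }
    agent_sets <- if (length(agents) > 1L && !nondir) {
      lapply(agents, list)
    } else if (length(agents)) list(agents) else list(list())
    if (nondir) {
      for (ag in agent_sets) {
        out[[length(out) + 1L]] <- new_event(p1$relation, p1$trigger_span,
                                             p1$trigger_form, themes, ag)
      }
    } else {
      for (th in themes) for (ag in agent_sets) {
        out[[length(out) + 1L]] <- new_event(p1$relation, p1$trigger_span,
                                             p1$trigger_form, list(th), ag)
      }
    }
  }
  out
}

unique_mentions <- function(ms) {
  if (!length(ms)) return(list())
  key <- vapply(ms, function(m) paste(m$span[1], m$span[2]), character(1))
  ms[!duplicated(key)]
}

new_event <- function(relation, trigger_span, trigger_form, themes, agents) {
  structure(list(relation = relation, trigger_span = trigger_span,
                 trigger_form = trigger_form,
                 args = list(theme = themes, agent = agents)),
            class = "event")
}

#' @export
print.event <- function(x, ...) {
  th <- paste(vapply(x$args$theme, function(m) m$text, character(1)),
              collapse = ", ")
  ag <- paste(vapply(x$args$agent, function(m) m$text, character(1)),
              collapse = ", ")
  cat("<event> ", x$relation, "(", x$trigger_form, "@[",
      x$trigger_span[1], ",", x$trigger_span[2], ") theme={", th, "}",
      if (nzchar(ag)) paste0(" agent={", ag, "}"), ")\n", sep = "")
  invisible(x)
}
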