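#' @title Trigger specifications, surface-form derivation, and frames
#' @description
#' A trigger specification declares, for one verb root, the relation it
#' signals, its subcategorization frame, per-slot semantic type
#' constraints, semantic role assignments, directionality, and optional
#' lexical guards. All surface trigger forms (inflections, nominals,
#' adjectivals, prefixed variants) are derived from the root by
#' rule-based English morphology with an explicit exception lexicon.
#' @name trigger_lexicon
NULL

.known_frames <- c("NP0/NP1", "NP0", "NP1")

.known_sem_types <- c("GGP", "gene", "rna", "protein", "protein_part",
                      "gene_part", "chemical", "class_noun", "other")

new_arg_slot <- function(index, allowed_types) {
  stopifnot(length(allowed_types) >= 1L)
  structure(list(index = as.integer(index),
                 allowed_types = unique(allowed_types)),
            class = "arg_slot")
}

new_trigger_spec <- function(root, relation, frame, slots, roles, direction,
                             guards = list(), affixes = character()) {
  if (!nzchar(root) || grepl("\\s", root) || root != tolower(root)) {
    stop("trigger root must be lowercase, non-empty, without whitespace: '",
         root, "'")
  }
  slot_idx <- vapply(slots, function(s) s$index, integer(1))
  for (ri in as.integer(names(roles))) {
    if (!ri %in% slot_idx) {
      stop("role assigned to undeclared slot NP", ri, " in spec for '",
           root, "'")
    }
  }
  if (direction == "non-directional" && length(slots) < 2L) {
    stop("non-directional trigger '", root, "' needs a frame with >= 2 slots")
  }
  structure(list(root = root, relation = relation, frame = frame,
                 slots = slots, roles = roles, direction = direction,
                 guards = guards, affixes = affixes),
            class = "trigger_spec")
}

#' @export
print.trigger_spec <- function(x, ...) {
  cat("<trigger_spec> ", x$root, " -> ", x$relation, " [", x$frame, ", ",
      x$direction, "]\n", sep = "")
  invisible(x)
}

#' Parse a trigger specification file
#'
#' The file format is line-oriented, with blank-line-separated blocks.
#' Recognized lines are `trigger: <root>`, `relation: <name>`,
#' `frame: <NP0/NP1|NP0|NP1>`, `type: NP<i> = <T1>|<T2>...`,
#' `role: NP<i> = agent|theme`, `direction: directional|non-directional`,
#' optional `guard: NP<i> ~ <word>` (a co-occurrence constraint: the
#' argument noun phrase must contain the word), and optional
#' `affixes: <comma-separated descriptors>`. Two blocks may share a root
#' (homonymous triggers for different relations); they are told apart at
#' extraction time by their type constraints and guards.
#'
#' @param text spec file content as a single string or character vector
#'   of lines
#' @return a list of `trigger_spec` objects
#' @examples
#' specs <- parse_trigger_spec("
#' trigger: phosphorylate
#' relation: Phosphorylation
#' frame: NP0/NP1
#' type: NP0 = GGP
#' type: NP1 = GGP|protein_part
#' role: NP0 = agent
#' role: NP1 = theme
#' direction: directional
#' ")
#' specs[[1]]$relation
#' @export
parse_trigger_spec <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  blocks <- list(); cur <- integer()
  for (k in seq_along(lines)) {
    if (grepl("^\\s*(#|$)", lines[k])) {
      if (length(cur)) { blocks[[length(blocks) + 1L]] <- cur; cur <- integer() }
    } else cur <- c(cur, k)
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
  lapply(blocks, function(ks) parse_spec_block(lines, ks))
}

parse_spec_block <- function(lines, ks) {
  root <- NULL; relation <- NULL; frame <- NULL
  types <- list(); roles <- list(); direction <- "directional"
  guards <- list(); affixes <- character()
  for (k in ks) {
    ln <- trimws(lines[k])
    m <- regmatches(ln, regexec("^([a-z]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) < 3L) stop("line ", k, ": cannot parse '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    if (key == "trigger") root <- val
    else if (key == "relation") relation <- val
    else if (key == "frame") {
      if (!val %in% .known_frames) {
        stop("line ", k, ": unknown frame name '", val, "'")
      }
      frame <- val
    } else if (key == "type") {
      p <- regmatches(val, regexec("^NP(\\d+)\\s*=\\s*(.+)$", val))[[1]]
      if (length(p) < 3L) stop("line ", k, ": cannot parse type constraint")
      tys <- trimws(strsplit(p[3], "|", fixed = TRUE)[[1]])
      bad <- setdiff(tys, .known_sem_types)
      if (length(bad)) {
        stop("line ", k, ": unknown semantic type ",
             paste(bad, collapse = ", "))
      }
      types[[p[2]]] <- tys
    } else if (key == "role") {
      p <- regmatches(val, regexec("^NP(\\d+)\\s*=\\s*(agent|theme)$", val))[[1]]
      if (length(p) < 3L) stop("line ", k, ": cannot parse role assignment")
      roles[[p[2]]] <- p[3]
    } else if (key == "direction") {
      if (!val %in% c("directional", "non-directional")) {
        stop("line ", k, ": direction must be directional or non-directional")
      }
      direction <- val
    } else if (key == "guard") {
      p <- regmatches(val, regexec("^NP(\\d+)\\s*~\\s*(\\S+)$", val))[[1]]
      if (length(p) < 3L) stop("line ", k, ": cannot parse guard")
      guards[[length(guards) + 1L]] <- list(slot = as.integer(p[2]),
                                            word = p[3])
    } else if (key == "affixes") {
      affixes <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else stop("line ", k, ": unknown key '", key, "'")
  }
  if (is.null(root)) stop("spec block at line ", ks[1], " has no trigger line")
  if (is.null(relation)) stop("spec block for '", root, "' has no relation")
  if (is.null(frame)) stop("spec block for '", root, "' has no frame")
  slot_ids <- sort(unique(as.integer(names(types))))
  if (!length(slot_ids)) {
    # slots implied by the frame name
    slot_ids <- if (frame == "NP0/NP1") c(0L, 1L)
                else if (frame == "NP0") 0L else 1L
    types <- stats::setNames(rep(list("GGP"), length(slot_ids)),
                             as.character(slot_ids))
  }
  slots <- lapply(slot_ids, function(i) new_arg_slot(i, types[[as.character(i)]]))
  roles <- stats::setNames(unlist(roles), names(roles))
  new_trigger_spec(root, relation, frame, slots, roles, direction,
                   guards, affixes)
}

# ---- morphology ----------------------------------------------------------

# irregular inflections and derivations; the user-confirmation step of an
# interactive workflow is replaced by this exception lexicon
.morph_exceptions <- list(
  bind = list(past = "bound", ppart = "bound"),
  undergo = list(past = "underwent", ppart = "undergone", third = "undergoes"),
  produce = list(affix = c("-ion" = "production")),
  transcribe = list(affix = c("-tion" = "transcription",
                              "-tional" = "transcriptional",
                              "-tionally" = "transcriptionally")),
  degrade = list(affix = c("-tion" = "degradation",
                           "-tive" = "degradative")),
  proteolyse = list(affix = c("-sis" = "proteolysis",
                              "-tic" = "proteolytic",
                              "-tically" = "proteolytically")),
  accumulate = list(affix = c("-ation" = "accumulation")),
  ligate = list(affix = c("-ion" = "ligation"))
)

# entity-class nominalizations: derivable but never used to generate
# patterns (they name things, not processes)
.entity_nominals <- c(transcribe = "transcript", produce = "product",
                      express = "expressate")

.vowel <- function(ch) ch %in% c("a", "e", "i", "o", "u")

morph_stem_join <- function(root, suffix) {
  # e-drop before vowel-initial suffix; y -> i; CVC doubling for short stems
  first <- substr(suffix, 1L, 1L)
  n <- nchar(root)
  last <- substr(root, n, n)
  penult <- if (n >= 2L) substr(root, n - 1L, n - 1L) else ""
  if (.vowel(first)) {
    if (last == "e" && penult != "e") return(paste0(substr(root, 1L, n - 1L), suffix))
    if (last == "y" && !.vowel(penult) && first != "i") {
      return(paste0(substr(root, 1L, n - 1L), "i", suffix))
    }
    if (n <= 4L && !.vowel(last) && .vowel(penult) && !last %in% c("w", "x", "y") &&
        (n < 3L || !.vowel(substr(root, n - 2L, n - 2L)))) {
      return(paste0(root, last, suffix))
    }
  }
  paste0(root, suffix)
}

inflect_third <- function(root) {
  n <- nchar(root); last <- substr(root, n, n)
  if (grepl("(s|x|z|ch|sh)$", root)) return(paste0(root, "es"))
  if (last == "y" && !.vowel(substr(root, n - 1L, n - 1L))) {
    return(paste0(substr(root, 1L, n - 1L), "ies"))
  }
  paste0(root, "s")
}

pluralize <- function(noun) inflect_third(noun)

.suffix_affixes <- c("-ion", "-tion", "-ation", "-age", "-ance", "-ment",
                     "-sis", "-al", "-ive", "-tic", "-tional", "-tionally",
                     "-tically", "-tive")
.prefix_affixes <- c("over-", "co-", "non-", "re-", "under-", "hyper-",
                     "im-", "trans-", "cross-")
.adjectival_suffixes <- c("-ive", "-tic", "-tional", "-al", "-tionally",
                          "-tically", "-tive")

new_trigger_form <- function(surface, category, derivation,
                             nominal_class = NA_character_) {
  stopifnot(nzchar(surface))
  structure(list(surface = surface, category = category,
                 derivation = derivation, nominal_class = nominal_class),
            class = "trigger_form")
}

#' Derive all surface trigger forms from a root morpheme
#'
#' Applies standard English inflection rules (e-drop before vowel-initial
#' suffixes, y-to-i, consonant doubling) plus an exception lexicon to
#' produce the finite, participial, base, nominal and adjectival surface
#' forms of a verb root, composed with the requested affixes. Prefix
#' affixes (`over-`, `co-`, ...) are composed with every base form;
#' suffix affixes (`-ion`, `-age`, ...) derive nominals or adjectivals.
#' Nominal forms carry a nominal class: only process-class nominals
#' ("phosphorylation") are later used to generate patterns, while
#' entity-class nominals ("transcript") are flagged and excluded.
#'
#' @param root verb base form, lowercase
#' @param affixes character vector of affix descriptors, e.g.
#'   `c("-ion", "over-")`; unknown descriptors are ignored with a warning
#' @return list of `trigger_form` objects (no duplicates; deterministic)
#' @examples
#' fs <- derive_trigger_forms("phosphorylate", c("-ion", "under-", "hyper-"))
#' vapply(fs, function(f) f$surface, character(1))
#' @export
derive_trigger_forms <- function(root, affixes = character()) {
  exc <- .morph_exceptions[[root]] %||% list()
  suffixes <- intersect(affixes, .suffix_affixes)
  prefixes <- intersect(affixes, .prefix_affixes)
  hyphen_pre <- setdiff(grep("-$", affixes, value = TRUE), .prefix_affixes)
  unknown <- setdiff(affixes, c(suffixes, prefixes, hyphen_pre))
  if (length(unknown)) {
    warning("ignoring unknown affix descriptor(s): ",
            paste(unknown, collapse = ", "))
  }

  third <- exc$third %||% inflect_third(root)
  past <- exc$past %||% morph_stem_join(root, "ed")
  ppart <- exc$ppart %||% past
  ger <- exc$gerund %||% morph_stem_join(root, "ing")

  forms <- list(
    new_trigger_form(root, "verb_base", "root"),
    new_trigger_form(third, "verb_finite", "3sg"),
    new_trigger_form(past, "verb_finite", "past"),
    new_trigger_form(ppart, "verb_ppart", "past participle"),
    new_trigger_form(ger, "verb_prespart", "present participle")
  )

  # the gerund doubles as a process nominal ("binding of A to B")
  nominals <- list(list(surface = ger, derivation = "-ing"))
  adjectivals <- list()
  for (sfx in suffixes) {
    # "-tion" behaves like "-ion" after the regular e-drop ("initiate" ->
    # "initiation"); true stem changes live in the exception lexicon
    stem_sfx <- if (sfx == "-tion") "ion" else sub("^-", "", sfx)
    surf <- unname(exc$affix[sfx]) %||% morph_stem_join(root, stem_sfx)
    if (is.na(surf)) surf <- morph_stem_join(root, stem_sfx)
    if (sfx %in% .adjectival_suffixes) {
      adjectivals[[length(adjectivals) + 1L]] <-
        list(surface = surf, derivation = sfx)
    } else {
      nominals[[length(nominals) + 1L]] <-
        list(surface = surf, derivation = sfx)
    }
  }
  for (nm in nominals) {
    forms[[length(forms) + 1L]] <-
      new_trigger_form(nm$surface, "nominal", nm$derivation, "process")
    forms[[length(forms) + 1L]] <-
      new_trigger_form(pluralize(nm$surface), "nominal",
                       paste0(nm$derivation, " plural"), "process")
  }
  if (root %in% names(.entity_nominals)) {
    forms[[length(forms) + 1L]] <-
      new_trigger_form(.entity_nominals[[root]], "nominal",
                       "entity nominal", "entity")
  }
  for (ad in adjectivals) {
    forms[[length(forms) + 1L]] <-
      new_trigger_form(ad$surface, "adjectival", ad$derivation)
  }
  # participles double as adjectival modifiers ("phosphorylated Cas")
  forms[[length(forms) + 1L]] <- new_trigger_form(ppart, "adjectival",
                                                  "past participle")
  forms[[length(forms) + 1L]] <- new_trigger_form(ger, "adjectival",
                                                  "present participle")

  # prefixed variants of every form derived so far
  prefixed <- list()
  for (pre in prefixes) {
    stem <- sub("-$", "", pre)
    for (f in forms) {
      prefixed[[length(prefixed) + 1L]] <-
        new_trigger_form(paste0(stem, f$surface), f$category,
                         paste0(pre, " ", f$derivation), f$nominal_class)
    }
  }
  # open-class hyphenated prefixes (e.g. "DNA-") keep the hyphen
  for (pre in hyphen_pre) {
    stem <- sub("-$", "", pre)
    prefixed[[length(prefixed) + 1L]] <-
      new_trigger_form(paste0(stem, "-", ger), "nominal",
                       paste0(pre, " -ing"), "process")
  }
  forms <- c(forms, prefixed)

  # dedupe on (surface, category), keep first
  key <- vapply(forms, function(f) paste(f$surface, f$category), character(1))
  forms[!duplicated(key)]
}

# ---- frames --------------------------------------------------------------

new_frame <- function(name, slot_arity, compatible_templates, allows_swap) {
  stopifnot(length(compatible_templates) >= 1L)
  structure(list(name = name, slot_arity = as.integer(slot_arity),
                 compatible_templates = compatible_templates,
                 allows_swap = isTRUE(allows_swap)),
            class = "frame")
}

#' The built-in frame registry
#'
#' Three frames are registered: `NP0/NP1` (transitive), `NP0`
#' (intransitive agentive; active-subject template only, since only
#' transitive verbs can be passivized), and `NP1` (unaccusative, for
#' triggers such as "accumulate" or "localize" whose surface subject is
#' the theme).
#'
#' @return named list of `frame` objects
#' @export
frame_registry <- function() {
  tpl <- template_table()
  list(
    "NP0/NP1" = new_frame("NP0/NP1", 2L,
                          tpl$id[tpl$frames %in% c("all", "transitive")],
                          allows_swap = FALSE),
    "NP0" = new_frame("NP0", 1L, "V1", allows_swap = FALSE),
    "NP1" = new_frame("NP1", 1L,
                      tpl$id[tpl$frames %in% c("all", "unaccusative")],
                      allows_swap = FALSE)
  )
}

#' Select and specialize the frame for a trigger specification
#'
#' Returns the registered frame named by the spec. For a non-directional
#' trigger the returned frame has `allows_swap = TRUE` and retains the
#' non-directional-only templates; for a directional trigger those
#' templates are removed.
#'
#' @param spec a `trigger_spec`
#' @param registry a frame registry, by default [frame_registry()]
#' @return a `frame`
#' @export
select_frame <- function(spec, registry = frame_registry()) {
  fr <- registry[[spec$frame]]
  if (is.null(fr)) stop("unregistered frame name: '", spec$frame, "'")
  tpl <- template_table()
  keep <- fr$compatible_templates
  if (spec$direction == "non-directional") {
    fr$allows_swap <- TRUE
    keep <- setdiff(keep, tpl$id[tpl$directional_only])
  } else {
    keep <- setdiff(keep, tpl$id[tpl$nondirectional_only])
  }
  fr$compatible_templates <- keep
  fr
}
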