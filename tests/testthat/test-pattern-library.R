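test_that("the template inventory is fixed at 26 with the stated partition", {
  tpls <- list_templates()
  expect_length(tpls, 26L)
  groups <- table(vapply(tpls, function(t) t$group, character(1)))
  expect_equal(as.integer(groups[c("verbal", "nominal", "adjectival",
                                   "null_argument")]),
               c(7L, 9L, 4L, 6L))
  expect_true(length(list_templates(group = "null_argument")) > 0L)
  # at most one argument placeholder: captured_slot is scalar or absent
  for (t in tpls) {
    expect_length(t$captured_slot, 1L)
    if (t$group == "null_argument") expect_true(is.na(t$captured_slot))
  }
  expect_false(anyDuplicated(vapply(tpls, function(t) t$id,
                                    character(1))) > 0)
})

test_that("pattern generation is the template-by-form cross product", {
  spec <- parse_trigger_spec(
    "trigger: phosphorylate\nrelation: Phosphorylation\nframe: NP0/NP1\ntype: NP0 = GGP\ntype: NP1 = GGP|protein_part\nrole: NP0 = agent\nrole: NP1 = theme\ndirection: directional")[[1]]
  forms <- derive_trigger_forms("phosphorylate", "-ion")
  frame <- select_frame(spec)
  pats <- generate_patterns(spec, forms, frame)
  # expected size: sum over templates of distinct compatible surfaces
  defs <- patrex:::.template_defs
  expected <- 0L
  for (tid in frame$compatible_templates) {
    ok <- vapply(forms, defs[[tid]]$form_ok, logical(1))
    expected <- expected + length(unique(vapply(forms[ok], function(f)
      f$surface, character(1))))
  }
  expect_length(pats, expected)
  key <- vapply(pats, function(p)
    paste(p$template_id, p$form$surface, p$slot), character(1))
  expect_false(anyDuplicated(key) > 0)
  # realizations named in the frame: active subject and passive subject
  ids <- vapply(pats, function(p) p$template_id, character(1))
  surfs <- vapply(pats, function(p) p$form$surface, character(1))
  expect_true(any(ids == "V1" & surfs == "phosphorylates"))
  expect_true(any(ids == "V3" & surfs == "phosphorylated"))
  # every compiled tree pattern is usable
  for (p in pats[1:5]) expect_s3_class(p$tree_pattern, "tree_pattern")
})

test_that("non-directional triggers get the swap-closed pattern set", {
  bind <- parse_trigger_spec(
    "trigger: bind\nrelation: Binding\nframe: NP0/NP1\ntype: NP0 = GGP\ntype: NP1 = GGP\nrole: NP0 = theme\nrole: NP1 = theme\ndirection: non-directional")[[1]]
  pats <- generate_patterns(bind, derive_trigger_forms("bind", character()),
                            select_frame(bind))
  ids <- unique(vapply(pats, function(p) p$template_id, character(1)))
  expect_true(all(c("V5", "V6", "N5", "N6", "N7") %in% ids))
  # both roles are theme, so swapping slot names changes no role
  # assignment: the swapped twin of any pattern extracts identically
  for (p in pats) {
    expect_equal(patrex:::role_of(p$spec, p$slot),
                 patrex:::role_of(p$spec, setdiff(c(0L, 1L), p$slot)))
  }
  # an intransitive frame generates no passive pattern at all
  intr <- parse_trigger_spec(
    "trigger: migrate\nrelation: Localization\nframe: NP0\ntype: NP0 = GGP\nrole: NP0 = agent")[[1]]
  pi <- generate_patterns(intr, derive_trigger_forms("migrate", character()),
                          select_frame(intr))
  expect_false(any(vapply(pi, function(p) p$template_id, character(1)) %in%
                     c("V3", "V4")))
})

test_that("pairs sharing a trigger occurrence combine into events", {
  men <- function(txt, a, b) patrex:::new_entity_mention(
    c(a, b), txt, "GGP", "preannotated", id = txt)
  spec <- golden_specs()[[1]]
  mk <- function(role, arg, rel = "Phosphorylation", span = c(4L, 18L),
                 dir = "directional") {
    patrex:::new_pair(rel, span, "phosphorylates", if (role == "agent") 0L
                      else 1L, role, arg, dir, spec)
  }
  evs <- pairs_to_events(list(mk("agent", men("JNK", 0, 3)),
                              mk("theme", men("NFAT4", 19, 24))))
  expect_length(evs, 1L)
  expect_equal(evs[[1]]$args$theme[[1]]$text, "NFAT4")
  expect_equal(evs[[1]]$args$agent[[1]]$text, "JNK")

  # a lone theme still makes an event; a lone agent does not
  expect_length(pairs_to_events(list(mk("theme", men("NFAT4", 19, 24)))), 1L)
  expect_length(pairs_to_events(list(mk("agent", men("JNK", 0, 3)))), 0L)

  # two themes on a directional trigger split into one event each
  evs2 <- pairs_to_events(list(mk("agent", men("JNK", 0, 3)),
                               mk("theme", men("A", 19, 20)),
                               mk("theme", men("B", 25, 26))))
  expect_length(evs2, 2L)
  expect_true(all(vapply(evs2, function(e) length(e$args$theme),
                         integer(1)) == 1L))
  expect_true(all(vapply(evs2, function(e) e$args$agent[[1]]$text,
                         character(1)) == "JNK"))

  # a non-directional trigger keeps all themes in one event
  evs3 <- pairs_to_events(list(
    mk("theme", men("A", 0, 1), rel = "Binding", dir = "non-directional"),
    mk("theme", men("B", 5, 6), rel = "Binding", dir = "non-directional")))
  expect_length(evs3, 1L)
  expect_length(evs3[[1]]$args$theme, 2L)

  # two agents on one directional occurrence: alternatives plus warning
  expect_warning(
    evs4 <- pairs_to_events(list(mk("agent", men("X", 0, 1)),
                                 mk("agent", men("Y", 2, 3)),
                                 mk("theme", men("Z", 5, 6)))),
    "two agents")
  expect_length(evs4, 2L)
})
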