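test_that("a trigger specification file parses into structured specs", {
  specs <- parse_trigger_spec("
trigger: phosphorylate
relation: Phosphorylation
frame: NP0/NP1
type: NP0 = GGP
type: NP1 = GGP|protein_part
role: NP0 = agent
role: NP1 = theme
direction: directional
")
  expect_length(specs, 1L)
  sp <- specs[[1]]
  expect_equal(sp$root, "phosphorylate")
  expect_equal(sp$relation, "Phosphorylation")
  expect_equal(sp$frame, "NP0/NP1")
  expect_equal(length(sp$slots), 2L)
  expect_setequal(sp$slots[[2]]$allowed_types, c("GGP", "protein_part"))
  expect_equal(sp$roles[["0"]], "agent")
  expect_equal(sp$roles[["1"]], "theme")
  expect_equal(sp$direction, "directional")
})

test_that("homonymous roots yield distinct specs and empty input yields none", {
  specs <- parse_trigger_spec("
trigger: express
relation: Gene_expression
frame: NP0/NP1
type: NP1 = GGP|gene
role: NP1 = theme
direction: directional

trigger: express
relation: Transcription
frame: NP0/NP1
type: NP1 = rna
role: NP1 = theme
guard: NP1 ~ mRNA
direction: directional
")
  expect_length(specs, 2L)
  expect_equal(vapply(specs, function(s) s$root, character(1)),
               c("express", "express"))
  expect_equal(vapply(specs, function(s) s$relation, character(1)),
               c("Gene_expression", "Transcription"))
  expect_length(specs[[2]]$guards, 1L)
  expect_length(parse_trigger_spec(""), 0L)
})

test_that("malformed spec blocks fail with informative errors", {
  expect_error(parse_trigger_spec("trigger: x\nrelation: R\nframe: NP9"),
               "unknown frame")
  expect_error(parse_trigger_spec(
    "trigger: x\nrelation: R\nframe: NP0\ntype: NP0 = GGP\nrole: NP3 = theme"),
    "undeclared slot")
  expect_error(parse_trigger_spec(
    "trigger: x\nrelation: R\nframe: NP0\ntype: NP0 = blargh"),
    "unknown semantic type")
})

test_that("trigger forms derive by inflection rules plus affixes", {
  s <- function(fs) vapply(fs, function(f) f$surface, character(1))
  f1 <- s(derive_trigger_forms("phosphorylate", c("-ion", "under-", "hyper-")))
  expect_true(all(c("phosphorylates", "phosphorylated", "phosphorylation",
                    "hyperphosphorylation", "underphosphorylated") %in% f1))
  expect_true("cleavage" %in% s(derive_trigger_forms("cleave", "-age")))
  f2 <- s(derive_trigger_forms("express",
                               c("-ion", "over-", "co-", "non-", "re-")))
  expect_true(all(c("expression", "expressions", "overexpression",
                    "coexpression", "nonexpression", "reexpression") %in% f2))
  # exception lexicon: irregular past/participle and stem changes
  expect_true(all(c("bound", "binding") %in%
                    s(derive_trigger_forms("bind", character()))))
  expect_true("transcription" %in%
                s(derive_trigger_forms("transcribe", "-tion")))
  expect_true("degradation" %in% s(derive_trigger_forms("degrade", "-tion")))
  expect_true("proteolysis" %in% s(derive_trigger_forms("proteolyse", "-sis")))
  expect_true("appearance" %in% s(derive_trigger_forms("appear", "-ance")))
  expect_true("engagement" %in% s(derive_trigger_forms("engage", "-ment")))
  expect_warning(derive_trigger_forms("bind", "xyz-affix"), "unknown affix")
})

test_that("derivation is deterministic, idempotent and duplicate-free", {
  for (root in c("phosphorylate", "express", "bind", "localize")) {
    a <- derive_trigger_forms(root, c("-ion", "co-"))
    b <- derive_trigger_forms(root, c("-ion", "co-"))
    expect_identical(a, b)
    key <- vapply(a, function(f) paste(f$surface, f$category), character(1))
    expect_false(anyDuplicated(key) > 0)
    # after stripping prefixes, every surface starts with the root stem
    stem <- substr(root, 1, 3)
    for (f in a) {
      surf <- sub("^(co|over|non|re|under|hyper|im|trans|cross)", "",
                  f$surface)
      expect_true(grepl(stem, paste0(surf, " "), fixed = TRUE) ||
                    grepl("past", f$derivation))
    }
  }
})

test_that("entity-class nominals are flagged and excluded from patterns", {
  fs <- derive_trigger_forms("transcribe", "-tion")
  ent <- Filter(function(f) identical(f$nominal_class, "entity"), fs)
  expect_length(ent, 1L)
  expect_equal(ent[[1]]$surface, "transcript")
  spec <- parse_trigger_spec(
    "trigger: transcribe\nrelation: Transcription\nframe: NP0/NP1\ntype: NP1 = rna\nrole: NP1 = theme")[[1]]
  pats <- generate_patterns(spec, fs, select_frame(spec))
  surfs <- vapply(pats, function(p) p$form$surface, character(1))
  expect_false("transcript" %in% surfs)
  expect_true("transcription" %in% surfs)
})

test_that("frame selection respects directionality and passivization", {
  reg <- frame_registry()
  tt <- template_table()
  phos <- parse_trigger_spec(
    "trigger: phosphorylate\nrelation: Phosphorylation\nframe: NP0/NP1\ntype: NP0 = GGP\ntype: NP1 = GGP\nrole: NP0 = agent\nrole: NP1 = theme\ndirection: directional")[[1]]
  fr <- select_frame(phos)
  expect_false(fr$allows_swap)
  expect_length(intersect(fr$compatible_templates,
                          tt$id[tt$nondirectional_only]), 0L)

  bind <- parse_trigger_spec(
    "trigger: bind\nrelation: Binding\nframe: NP0/NP1\ntype: NP0 = GGP\ntype: NP1 = GGP\nrole: NP0 = theme\nrole: NP1 = theme\ndirection: non-directional")[[1]]
  fb <- select_frame(bind)
  expect_true(fb$allows_swap)
  expect_true(all(tt$id[tt$nondirectional_only] %in%
                    fb$compatible_templates))

  # intransitive frame carries no passive templates
  intr <- parse_trigger_spec(
    "trigger: migrate\nrelation: Localization\nframe: NP0\ntype: NP0 = GGP\nrole: NP0 = agent")[[1]]
  fi <- select_frame(intr)
  expect_false(any(c("V3", "V4") %in% fi$compatible_templates))
  expect_error(select_frame(phos, registry = list()), "unregistered frame")

  # slot arity always matches the spec's slots
  for (sp in list(phos, bind, intr)) {
    expect_equal(select_frame(sp)$slot_arity, length(sp$slots))
  }
})
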