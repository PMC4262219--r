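test_that("a simple transitive clause yields both role pairs", {
  doc <- golden_doc(
    "JNK phosphorylates NFAT4",
    "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
    c("JNK", "NFAT4"))
  v <- identity_variant(doc$sentences[[1]]$tree, doc$text)
  prs <- extract_sentence(v, golden_patterns(), doc$mentions)
  smry <- vapply(prs, function(p) paste(p$role, p$arg$text), character(1))
  expect_setequal(smry, c("agent JNK", "theme NFAT4"))
  evs <- extract_document(doc, golden_patterns())
  expect_equal(event_summary(evs),
               "Phosphorylation(phosphorylates: theme=NFAT4, agent=JNK)")
})

test_that("a full NP agent is extracted with its annotated mention", {
  doc <- golden_doc(
    "The c-Jun amino-terminal kinase phosphorylates NFAT4.",
    paste0("(S (NP (DT The) (NNP c-Jun) (JJ amino-terminal) (NN kinase)) ",
           "(VP (VBZ phosphorylates) (NP (NNP NFAT4))) (. .))"),
    c("c-Jun amino-terminal kinase", "NFAT4"))
  evs <- extract_document(doc, golden_patterns())
  expect_length(evs, 1L)
  expect_equal(evs[[1]]$args$agent[[1]]$text, "c-Jun amino-terminal kinase")
  expect_equal(evs[[1]]$args$theme[[1]]$text, "NFAT4")
})

test_that("adverbial adjuncts between trigger and argument are skipped", {
  doc <- golden_doc(
    "PROT1 abundantly expressed PROT2 .",
    paste0("(S (NP (NNP PROT1)) (VP (ADVP (RB abundantly)) ",
           "(VBD expressed) (NP (NNP PROT2))) (. .))"),
    c("PROT1", "PROT2"))
  evs <- extract_document(doc, golden_patterns())
  expect_equal(event_summary(evs),
               "Gene_expression(expressed: theme=PROT2, agent=PROT1)")
})

test_that("auxiliary chains are matched through the verb-group head", {
  doc <- golden_doc(
    "PROT1 has been shown to phosphorylate PROT2 .",
    paste0("(S (NP (NNP PROT1)) (VP (VBZ has) (VP (VBN been) (VP (VBN shown) ",
           "(S (VP (TO to) (VP (VB phosphorylate) (NP (NNP PROT2)))))))) (. .))"),
    c("PROT1", "PROT2"))
  evs <- extract_document(doc, golden_patterns())
  expect_equal(event_summary(evs),
               "Phosphorylation(phosphorylate: theme=PROT2, agent=PROT1)")
})

test_that("lexical guards route homonymous triggers", {
  # with an mRNA theme, "expressed" means transcription, not expression
  doc <- golden_doc(
    "PROT1 mRNA was expressed .",
    paste0("(S (NP (NNP PROT1) (NN mRNA)) (VP (VBD was) ",
           "(VP (VBN expressed))) (. .))"),
    c("PROT1"))
  evs <- extract_document(doc, golden_patterns())
  expect_equal(event_summary(evs),
               "Transcription(expressed: theme=PROT1)")
  # without mRNA the unguarded gene-expression reading survives
  doc2 <- golden_doc(
    "PROT1 was expressed .",
    "(S (NP (NNP PROT1)) (VP (VBD was) (VP (VBN expressed))) (. .))",
    c("PROT1"))
  evs2 <- extract_document(doc2, golden_patterns())
  expect_equal(event_summary(evs2),
               "Gene_expression(expressed: theme=PROT1)")
})

test_that("non-directional extraction is symmetric under argument swap", {
  mk <- function(a, b) golden_doc(
    sprintf("%s interacts with %s .", a, b),
    sprintf(paste0("(S (NP (NNP %s)) (VP (VBZ interacts) ",
                   "(PP (IN with) (NP (NNP %s)))) (. .))"), a, b),
    c(a, b))
  e1 <- extract_document(mk("PROT1", "PROT2"), golden_patterns())
  e2 <- extract_document(mk("PROT2", "PROT1"), golden_patterns())
  themes <- function(evs) sort(vapply(evs[[1]]$args$theme,
                                      function(m) m$text, character(1)))
  expect_length(e1, 1L)
  expect_equal(themes(e1), themes(e2))
  expect_equal(themes(e1), c("PROT1", "PROT2"))
})

test_that("no emitted pair violates its slot type constraint", {
  fx <- generate_fixtures(fixture_recipe(seed = 23, n_sentences = 30))
  pats <- compile_specs(parse_trigger_spec(fixture_spec_text()))
  evs <- suppressWarnings(extract_document(fx$doc, pats))
  specs <- parse_trigger_spec(fixture_spec_text())
  slot_types <- list()
  for (sp in specs) for (sl in sp$slots) {
    slot_types[[sp$relation]] <- union(slot_types[[sp$relation]],
                                       sl$allowed_types)
  }
  for (e in evs) {
    for (m in c(e$args$theme, e$args$agent)) {
      expect_equal(m$source, "preannotated")
      expect_true(satisfies(m, patrex:::new_arg_slot(
        0L, slot_types[[e$relation]])))
    }
  }
})

test_that("extraction is deterministic and order-stable", {
  fx <- generate_fixtures(fixture_recipe(seed = 31, n_sentences = 15))
  pats <- compile_specs(parse_trigger_spec(fixture_spec_text()))
  a <- suppressWarnings(extract_document(fx$doc, pats))
  b <- suppressWarnings(extract_document(fx$doc, pats))
  expect_identical(event_summary(a), event_summary(b))
})

test_that("an unreadable sentence parse is skipped with a warning", {
  doc <- make_document("JNK binds DNA",
                       list(list(text = "JNK binds DNA", start = 0L,
                                 tree = NULL)),
                       read_a1("T1\tProtein 0 3\tJNK"))
  expect_warning(evs <- extract_document(doc, golden_patterns()),
                 "skipped")
  expect_length(evs, 0L)
})
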