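test_that("a part keyword phrase links to the whole it contains", {
  sent <- "Both Eomes and Runx3 bind at the Prf1 locus ."
  tree <- read_bracketed(
    paste0("(S (NP (DT Both) (NP (NNP Eomes)) (CC and) (NP (NNP Runx3))) ",
           "(VP (VBP bind) (PP (IN at) (NP (DT the) (NNP Prf1) ",
           "(NN locus)))) (. .))"), sent)
  mentions <- read_a1(c("T1\tProtein 5 10\tEomes", "T2\tProtein 15 20\tRunx3",
                        paste0("T3\tProtein ", regexpr("Prf1", sent) - 1,
                               " ", regexpr("Prf1", sent) + 3, "\tPrf1")))
  links <- detect_links(tree, mentions)
  pw <- Filter(function(l) l$kind == "part_whole", links)
  expect_length(pw, 1L)
  expect_equal(pw[[1]]$source$text, "the Prf1 locus")
  expect_equal(pw[[1]]$target$text, "Prf1")
})

test_that("member-collection lists link every member to the collection", {
  sent <- paste0("expression of adhesion molecules including ",
                 "integrin alpha , L-selectin , ICAM-3 , and H-CAM")
  tree <- read_bracketed(
    paste0("(NP (NP (NN expression)) (PP (IN of) (NP (NP (NN adhesion) ",
           "(NNS molecules)) (PP (VBG including) (NP ",
           "(NP (NNP integrin) (NN alpha)) (, ,) (NP (NNP L-selectin)) ",
           "(, ,) (NP (NNP ICAM-3)) (, ,) (CC and) (NP (NNP H-CAM)))))))"),
    sent)
  names4 <- c("integrin alpha", "L-selectin", "ICAM-3", "H-CAM")
  mentions <- lapply(seq_along(names4), function(k) {
    at <- regexpr(names4[k], sent, fixed = TRUE)
    patrex:::new_entity_mention(c(at - 1L, at - 1L + nchar(names4[k])),
                                names4[k], "GGP", "preannotated",
                                paste0("T", k))
  })
  links <- detect_links(tree, mentions)
  mc <- Filter(function(l) l$kind == "member_collection", links)
  expect_length(mc, 4L)
  expect_setequal(vapply(mc, function(l) l$source$text, character(1)),
                  names4)
  expect_true(all(vapply(mc, function(l)
    l$target$text == "adhesion molecules", logical(1))))
})

test_that("a sentence without referential cues yields no links", {
  tree <- read_bracketed(
    "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
    "JNK phosphorylates NFAT4")
  mentions <- read_a1(c("T1\tProtein 0 3\tJNK", "T2\tProtein 19 24\tNFAT4"))
  expect_length(detect_links(tree, mentions), 0L)
})

test_that("resolution follows member-collection and hyponymy chains", {
  # chain: <transcribed, the earliest genes> + member_collection(one ->
  # the earliest genes) + hyponymy(TNF-alpha -> one) resolves to the
  # actual theme
  men <- function(txt, a, b, src = "heuristic", ty = "class_noun") {
    patrex:::new_entity_mention(c(a, b), txt, ty, src,
                                id = if (src == "preannotated") txt else
                                  NA_character_)
  }
  genes <- men("the earliest genes", 10, 28)
  one <- men("one", 0, 3)
  tnf <- men("tumor necrosis factor alpha", 40, 67, "preannotated", "GGP")
  links <- list(
    patrex:::new_ref_link("member_collection", one, genes),
    patrex:::new_ref_link("hyponymy", tnf, one))
  spec <- Filter(function(s) s$relation == "Transcription",
                 golden_specs())[[1]]
  pair <- patrex:::new_pair("Transcription", c(30L, 41L), "transcribed",
                            1L, "theme", genes, "directional", spec)
  out <- resolve_pair(pair, links, spec$slots[[2]])
  expect_length(out, 1L)
  expect_equal(out[[1]]$arg$text, "tumor necrosis factor alpha")
  expect_equal(out[[1]]$arg$source, "preannotated")
})

test_that("an already-informative argument is returned unchanged", {
  m <- patrex:::new_entity_mention(c(0L, 5L), "NFAT4", "GGP",
                                   "preannotated", "T1")
  spec <- golden_specs()[[1]]
  pair <- patrex:::new_pair("Phosphorylation", c(10L, 24L),
                            "phosphorylates", 1L, "theme", m,
                            "directional", spec)
  links <- list(patrex:::new_ref_link(
    "hyponymy", patrex:::new_entity_mention(c(30L, 35L), "x", "GGP",
                                            "preannotated", "T2"),
    patrex:::new_entity_mention(c(0L, 5L), "NFAT4", "class_noun")))
  expect_identical(resolve_pair(pair, links)[[1]], pair)
  # and resolution with no links at all is the identity
  expect_identical(resolve_pair(pair, list())[[1]], pair)
})

test_that("resolution terminates on adversarial cyclic link graphs", {
  men <- function(a, b, src = "heuristic") patrex:::new_entity_mention(
    c(a, b), paste0("m", a), if (src == "preannotated") "GGP" else
      "class_noun", src, id = if (src == "preannotated") paste0("T", a) else
      NA_character_)
  # a ring of apposition links (bidirectional, so fully cyclic) plus one
  # informative exit
  ring <- lapply(0:9, function(k) {
    patrex:::new_ref_link("apposition", men(k * 10, k * 10 + 5),
                          men(((k + 1) %% 10) * 10, ((k + 1) %% 10) * 10 + 5))
  })
  exit <- patrex:::new_ref_link("hyponymy", men(500, 505, "preannotated"),
                                men(70, 75))
  spec <- golden_specs()[[1]]
  pair <- patrex:::new_pair("Phosphorylation", c(200L, 210L), "x", 1L,
                            "theme", men(0, 5), "directional", spec)
  out <- resolve_pair(pair, c(ring, list(exit)), spec$slots[[2]])
  expect_length(out, 1L)
  expect_equal(out[[1]]$arg$span, c(500L, 505L))
  # self-referential and duplicated links also terminate
  dup <- c(ring, ring, list(exit))
  expect_length(resolve_pair(pair, dup, spec$slots[[2]]), 1L)
})

test_that("external coreference links are validated and merged", {
  good <- patrex:::new_ref_link(
    "relpronoun_coref",
    patrex:::new_entity_mention(c(40L, 51L), "the protein", "other"),
    patrex:::new_entity_mention(c(17L, 22L), "c-Fox", "GGP",
                                "preannotated", "T1"))
  merged <- register_external_coref(list(good), list())
  expect_length(merged, 1L)
  bad <- good
  bad$source$span <- c(10L, 5L)
  expect_error(register_external_coref(list(bad)), "malformed span")
  expect_error(register_external_coref(list("not a link")), "not a ref_link")
  # file round trip
  lines <- "40\t51\t17\t22\trelpronoun_coref"
  parsed <- read_coref_links(lines, "x")
  expect_length(parsed, 1L)
  expect_equal(parsed[[1]]$kind, "relpronoun_coref")
})
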