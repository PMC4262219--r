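raf_sentence <- function() {
  sent <- paste0(
    "Active Raf-1 phosphorylates and activates the mitogen-activated ",
    "protein (MAP) kinase/extracellular signal-regulated kinase kinase 1 ",
    "(MEK1), which in turn phosphorylates and activates the MAP kinases/ ",
    "extracellular signal regulated kinases, ERK1 and ERK2.")
  parse <- paste0(
    "(S (NP (JJ Active) (NNP Raf-1)) ",
    "(VP (VBZ phosphorylates) (CC and) (VBZ activates) ",
    "(NP (NP (DT the) (JJ mitogen-activated) (NN protein) ",
    "(-LRB- -LRB-) (NP (NNP MAP)) (-RRB- -RRB-) ",
    "(NN kinase/extracellular) (JJ signal-regulated) (NN kinase) ",
    "(NN kinase) (CD 1)) ",
    "(-LRB- -LRB-) (NP (NNP MEK1)) (-RRB- -RRB-) (, ,) ",
    "(SBAR (WHNP (WDT which)) (S (ADVP (IN in) (NN turn)) ",
    "(VP (VBZ phosphorylates) (CC and) (VBZ activates) ",
    "(NP (NP (DT the) (NNP MAP) (NNS kinases/) (JJ extracellular) ",
    "(NN signal) (VBN regulated) (NNS kinases)) (, ,) ",
    "(NP (NP (NNP ERK1)) (CC and) (NP (NNP ERK2))))))))) (. .))")
  list(sent = sent, tree = read_bracketed(parse, sent))
}

test_that("constructs of all five kinds are detected", {
  rs <- raf_sentence()
  cs <- detect_constructs(rs$tree)
  kinds <- vapply(cs, function(c) c$kind, character(1))
  expect_true("coordination" %in% kinds)       # phosphorylates and activates
  expect_true("parenthetical" %in% kinds)      # (MAP), (MEK1)
  expect_true("relative_clause_full" %in% kinds) # which in turn ...
  expect_true(sum(kinds == "coordination") >= 3L) # two verb + ERK1/ERK2

  # a sentence with none of the cues yields no constructs
  plain <- read_bracketed(
    "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
    "JNK phosphorylates NFAT4")
  expect_length(detect_constructs(plain), 0L)

  # a prenominal participle is not a reduced relative clause
  p29 <- read_bracketed(
    paste0("(S (NP (DT the) (NN protein)) (VP (VBD was) (VP (VBN dimerized) ",
           "(PP (IN with) (NP (VBN phosphorylated) (NNP c-Jun))))) (. .))"),
    "the protein was dimerized with phosphorylated c-Jun .")
  expect_length(detect_constructs(p29), 0L)
})

test_that("apposition detection requires a determiner or number", {
  app <- read_bracketed(
    paste0("(S (NP (NP (NNP CD14)) (, ,) (NP (DT a) (NN glycoprotein)) ",
           "(, ,)) (VP (VBD was) (VP (VBN expressed))) (. .))"),
    "CD14 , a glycoprotein , was expressed .")
  kinds <- vapply(detect_constructs(app), function(c) c$kind, character(1))
  expect_true("apposition" %in% kinds)
  # a bare-name second NP is not an appositive
  noap <- read_bracketed(
    paste0("(S (NP (NP (NNS kinases)) (, ,) (NP (NNP ERK1))) ",
           "(VP (VBD were) (VP (VBN studied))) (. .))"),
    "kinases , ERK1 were studied .")
  kinds2 <- vapply(detect_constructs(noap), function(c) c$kind, character(1))
  expect_false("apposition" %in% kinds2)
})

test_that("coordination splits into one variant per conjunct", {
  tr <- read_bracketed(
    paste0("(S (NP (NP (NNP A)) (CC and) (NP (NNP B))) ",
           "(VP (VBD were) (VP (VBN expressed))) (. .))"),
    "A and B were expressed .")
  vs <- simplify(tr, sentence = "A and B were expressed .")
  texts <- vapply(vs, function(v) v$text, character(1))
  expect_length(vs, 3L)
  expect_equal(texts[1], "A and B were expressed .")
  expect_setequal(texts[-1], c("A were expressed .", "B were expressed ."))
  # deterministic and stable
  vs2 <- simplify(tr, sentence = "A and B were expressed .")
  expect_identical(vapply(vs2, function(v) v$text, character(1)), texts)
})

test_that("no constructs means exactly the original variant", {
  tr <- read_bracketed(
    "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
    "JNK phosphorylates NFAT4")
  vs <- simplify(tr, sentence = "JNK phosphorylates NFAT4")
  expect_length(vs, 1L)
  expect_equal(vs[[1]]$text, "JNK phosphorylates NFAT4")
})

test_that("the complex worked example exposes the buried clause", {
  rs <- raf_sentence()
  vs <- simplify(rs$tree, sentence = rs$sent, max_variants = 128L)
  texts <- vapply(vs, function(v) v$text, character(1))
  hit <- grepl("^MEK1 in turn phosphorylates", texts) &
    grepl("ERK1", texts)
  expect_true(any(hit))
})

test_that("offset maps are monotonic and map back to original surface", {
  rs <- raf_sentence()
  vs <- simplify(rs$tree, sentence = rs$sent, max_variants = 128L)
  for (v in vs) {
    m <- v$offset_map[!is.na(v$offset_map)]
    expect_true(all(diff(m) > 0))  # strictly monotonic over mapped chars
    # every mapped character equals the original character
    pos <- which(!is.na(v$offset_map))
    for (k in pos[seq_len(min(20, length(pos)))]) {
      expect_equal(substr(v$text, k, k),
                   substr(rs$sent, v$offset_map[k] + 1,
                          v$offset_map[k] + 1))
    }
  }
})

test_that("map_span recovers original spans and rejects pure glue", {
  tr <- read_bracketed(
    paste0("(S (NP (NP (DT the) (NN protein)) (VP (VBN phosphorylated) ",
           "(PP (IN by) (NP (NNP JNK))))) (VP (VBD was) ",
           "(VP (VBN purified))) (. .))"),
    "the protein phosphorylated by JNK was purified .")
  vs <- simplify(tr, sentence = "the protein phosphorylated by JNK was purified .")
  rc <- Filter(function(v) grepl("^the protein was phosphorylated", v$text),
               vs)
  expect_length(rc, 1L)
  v <- rc[[1]]
  at <- regexpr("JNK", v$text, fixed = TRUE)
  orig <- map_span(v, c(at - 1L, at + 2L))
  expect_equal(substr("the protein phosphorylated by JNK was purified .",
                      orig[1] + 1, orig[2]), "JNK")
  # the inserted copula has no original counterpart
  glue_at <- regexpr(" was ", v$text, fixed = TRUE)
  expect_error(map_span(v, c(glue_at, glue_at + 3L)), "glue")
})

test_that("attachment ambiguities yield one variant per reading", {
  # "NP1 of NP2 which V": clause high vs low
  tr <- read_bracketed(
    paste0("(S (NP (NP (NP (DT the) (NN domain)) (PP (IN of) ",
           "(NP (NNP PROT1)))) (SBAR (WHNP (WDT which)) (S (VP (VBZ binds) ",
           "(NP (NNP PROT2)))))) (VP (VBZ matters)) (. .))"),
    "the domain of PROT1 which binds PROT2 matters .")
  av <- attachment_alternatives(tr,
                                "the domain of PROT1 which binds PROT2 matters .")
  expect_true(any(vapply(av, function(v)
    identical(v$attachment_choice, "rc_low"), logical(1))))

  # "Adj NPa and NPb": distributed reading
  tr2 <- read_bracketed(
    paste0("(S (NP (NP (JJ phosphorylated) (NNP A)) (CC and) ",
           "(NP (NNP B))) (VP (VBD appeared)) (. .))"),
    "phosphorylated A and B appeared .")
  av2 <- attachment_alternatives(tr2, "phosphorylated A and B appeared .")
  dist <- Filter(function(v)
    identical(v$attachment_choice, "adj_distributed"), av2)
  expect_length(dist, 1L)
  expect_equal(dist[[1]]$text, "phosphorylated B appeared .")

  # unambiguous sentence: no alternatives
  plain <- read_bracketed(
    "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
    "JNK phosphorylates NFAT4")
  expect_length(attachment_alternatives(plain, "JNK phosphorylates NFAT4"),
                0L)
})

test_that("every variant's mapped tokens keep original relative order", {
  set.seed(7)
  fx <- generate_fixtures(fixture_recipe(seed = 11, n_sentences = 15))
  for (sent in fx$doc$sentences) {
    for (v in simplify(sent$tree, sentence = sent$text)) {
      m <- v$offset_map[!is.na(v$offset_map)]
      expect_true(all(diff(m) > 0))
    }
  }
})
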