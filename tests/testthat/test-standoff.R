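test_that("standoff bundles read and a2 writing round-trips", {
  txt <- "JNK phosphorylates NFAT4 ."
  a1 <- c("T1\tProtein 0 3\tJNK", "T2\tProtein 19 24\tNFAT4")
  a2 <- c("T3\tPhosphorylation 4 18\tphosphorylates",
          "E1\tPhosphorylation:T3 Theme:T2 Cause:T1")
  gs <- read_standoff(txt, a1, a2)
  expect_length(gs$entities, 2L)
  expect_length(gs$events, 1L)
  ev <- gs$events[[1]]
  expect_equal(ev$relation, "Phosphorylation")
  expect_equal(ev$trigger_span, c(4L, 18L))
  expect_equal(ev$args$theme[[1]]$text, "NFAT4")
  expect_equal(ev$args$agent[[1]]$text, "JNK")
  # round trip
  out <- write_a2(gs$events, txt, gs$entities)
  gs2 <- read_standoff(txt, a1, out)
  expect_equal(gs2$events, gs$events)
  # dangling references are reported by id
  expect_error(read_standoff(txt, a1, c("T3\tPhosphorylation 4 18\tx",
                                        "E1\tPhosphorylation:T3 Theme:T9")),
               "T9")
})

test_that("approximate span matching allows one token each side", {
  txt <- "The c-Jun amino-terminal kinase phosphorylates NFAT4 ."
  tokens <- patrex:::whitespace_tokens(txt)
  gold <- c(4L, 31L)   # "c-Jun amino-terminal kinase"
  expect_true(approx_span_match(gold, gold, tokens))
  expect_true(approx_span_match(c(0L, 31L), gold, tokens))  # + "The"
  expect_true(approx_span_match(c(0L, 46L), gold, tokens))  # + one each side
  expect_true(approx_span_match(c(4L, 46L), gold, tokens))  # + "phosphorylates"
  # two tokens beyond is out
  gold2 <- c(10L, 24L)  # "amino-terminal"
  expect_false(approx_span_match(c(0L, 24L), gold2, tokens))
})

test_that("approximate matching equals the enumerative oracle", {
  set.seed(99)
  for (rep in 1:1000) {
    lay <- random_layout()
    expect_equal(approx_span_match(lay$pred, lay$gold, lay$tokens),
                 oracle_approx(lay$pred, lay$gold, lay$tokens),
                 info = paste("pred", paste(lay$pred, collapse = ","),
                              "gold", paste(lay$gold, collapse = ",")))
  }
})

test_that("evaluation scores exact self-agreement as perfect", {
  fx <- generate_fixtures(fixture_recipe(seed = 8, n_sentences = 10))
  res <- evaluate(fx$gold$events, fx$gold)
  expect_equal(res$total$precision, 1)
  expect_equal(res$total$recall, 1)
  expect_equal(res$total$f1, 1)
  # empty predictions: precision 0 by convention, recall 0
  res0 <- evaluate(list(), fx$gold)
  expect_equal(res0$total$precision, 0)
  expect_equal(res0$total$recall, 0)
  expect_equal(res0$total$f1, 0)
})

test_that("equivalence classes expand gold counts", {
  txt <- "PROTA also called PROTB was expressed ."
  a1 <- c("T1\tProtein 0 5\tPROTA", "T2\tProtein 18 23\tPROTB")
  a2 <- c("T3\tGene_expression 28 37\texpressed",
          "E1\tGene_expression:T3 Theme:T1",
          "*\tEquiv T1 T2")
  gs <- read_standoff(txt, a1, a2)
  pred <- list(patrex:::new_event(
    "Gene_expression", c(28L, 37L), "expressed",
    list(gs$entity_ids[["T2"]]), list()))
  res <- evaluate(pred, gs)
  # the gold event is counted twice; the prediction matches one copy
  expect_equal(res$total$tp, 1)
  expect_equal(res$total$precision, 1)
  expect_equal(res$total$recall, 0.5)
})

test_that("adding a correct prediction never lowers recall", {
  fx <- generate_fixtures(fixture_recipe(seed = 13, n_sentences = 12))
  some <- fx$gold$events[seq_len(5)]
  r1 <- evaluate(some, fx$gold)
  r2 <- evaluate(fx$gold$events[seq_len(6)], fx$gold)
  expect_true(r2$total$recall >= r1$total$recall)
})

test_that("read_document aligns parses against the text", {
  fx <- generate_fixtures(fixture_recipe(seed = 17, n_sentences = 6))
  doc <- read_document(fx$text, fx$parses, fx$offsets, fx$a1)
  expect_length(doc$sentences, 6L)
  for (i in seq_along(doc$sentences)) {
    expect_false(is.null(doc$sentences[[i]]$tree))
    expect_equal(doc$sentences[[i]]$text,
                 substr(fx$text, fx$offsets[i, 1] + 1, fx$offsets[i, 2]))
  }
  # and the re-read document extracts like the in-memory one
  pats <- compile_specs(parse_trigger_spec(fixture_spec_text()))
  e1 <- suppressWarnings(extract_document(doc, pats))
  e2 <- suppressWarnings(extract_document(fx$doc, pats))
  expect_identical(event_summary(e1), event_summary(e2))
})
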