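test_that("bracketed parses read with correct character spans", {
  tr <- read_bracketed(
    "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
    "JNK phosphorylates NFAT4")
  expect_equal(c(tr$start, tr$end), c(0L, 24L))
  idx <- tree_index(tr)
  expect_length(idx$leaves, 3L)
  # word leaves reconstruct the sentence slices
  for (l in idx$leaves) {
    expect_equal(substr("JNK phosphorylates NFAT4", idx$start[l] + 1,
                        idx$end[l]), idx$token[l])
  }
  one <- read_bracketed("(NP (NN binding))", "binding")
  expect_equal(c(one$start, one$end), c(0L, 7L))
})

test_that("reader errors on malformed input", {
  expect_error(read_bracketed("(S (NP (NNP NFAT5)))", "NFAT4"),
               "alignment error.*NFAT5")
  expect_error(read_bracketed("(S (NP (NN x))", "x"), "unbalanced")
  expect_error(read_bracketed("(S (NP (NN x))))", "x"), "unbalanced")
})

test_that("span invariants hold on every node", {
  sent <- "The kinase was shown to bind DNA in vitro"
  tr <- read_bracketed(paste0(
    "(S (NP (DT The) (NN kinase)) (VP (VBD was) (VP (VBN shown) ",
    "(S (VP (TO to) (VP (VB bind) (NP (NNP DNA)) ",
    "(PP (IN in) (NP (NN vitro)))))))))"), sent)
  idx <- tree_index(tr)
  for (i in seq_along(idx$label)) {
    kids <- idx$children[[i]]
    if (!length(kids)) next
    expect_equal(idx$start[i], min(idx$start[kids]))
    expect_equal(idx$end[i], max(idx$end[kids]))
    # sibling spans are disjoint and ordered
    if (length(kids) > 1L) {
      expect_true(all(idx$end[kids[-length(kids)]] <=
                        idx$start[kids[-1L]]))
    }
    # the yield reconstructs the covered text up to whitespace
    expect_equal(gsub("\\s+", " ", substr(sent, idx$start[i] + 1,
                                          idx$end[i])),
                 patrex:::idx_yield(idx, i))
  }
})

test_that("pattern compilation rejects bad syntax with positions", {
  expect_error(compile_pattern("NP <"), "expected operand")
  expect_error(compile_pattern("NP < (NN"), "unbalanced")
  expect_error(compile_pattern("/unterminated"), "unterminated")
  expect_error(compile_pattern("! NP"), "syntax error")
  expect_error(compile_pattern("NP ! NN"), "relation operator")
  p <- compile_pattern("VP < (VBZ=trig <: /^phos/) and VP < NP=arg")
  expect_s3_class(p, "tree_pattern")
  expect_setequal(p$captures, c("trig", "arg"))
})

test_that("matching finds documented matches in document order", {
  tr <- read_bracketed(
    "(S (NP (NNP JNK)) (VP (VBZ phosphorylates) (NP (NNP NFAT4))))",
    "JNK phosphorylates NFAT4")
  ms <- match_all("VP < (VBZ=trig <: /^phosphorylat/) and VP < NP=arg", tr)
  expect_length(ms, 1L)
  expect_equal(ms[[1]]$bindings$trig$children[[1]]$token, "phosphorylates")
  expect_equal(ms[[1]]$bindings$arg$children[[1]]$children[[1]]$token,
               "NFAT4")
  expect_length(match_all("NP", tr), 2L)
  expect_length(match_all("ADJP", tr), 0L)
  # anchors come back in pre-order
  anchors <- vapply(match_all("NP", tr), function(m) m$anchor, integer(1))
  expect_equal(anchors, sort(anchors))
})

test_that("matcher agrees with a brute-force node-wise oracle", {
  set.seed(42)
  for (rep in 1:60) {
    tr <- random_tree()
    for (expr in oracle_patterns) {
      got <- sort(unique(vapply(match_all(expr, tr), function(m) m$anchor,
                                integer(1))))
      want <- sort(oracle_anchors(expr, tr))
      expect_equal(got, want,
                   info = paste("pattern:", expr, "tree:", deparse_tree(tr)))
    }
  }
})

test_that("verb group head selection skips auxiliaries and raising verbs", {
  h <- verb_group_head(read_bracketed(
    "(VP (VBZ is) (VP (VBN known) (S (VP (TO to) (VP (VB bind))))))",
    "is known to bind"))
  expect_equal(h$token, "bind")
  h2 <- verb_group_head(read_bracketed("(VP (VBZ phosphorylates))",
                                       "phosphorylates"))
  expect_equal(h2$token, "phosphorylates")
  h3 <- verb_group_head(read_bracketed(
    paste0("(VP (VBZ has) (VP (VBN been) (VP (VBN shown) ",
           "(S (VP (TO to) (VP (VB be) (VP (VBN phosphorylated))))))))"),
    "has been shown to be phosphorylated"))
  expect_equal(h3$token, "phosphorylated")
  expect_error(verb_group_head(read_bracketed("(NP (NN binding))",
                                              "binding")),
               "no verb leaf")
})
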