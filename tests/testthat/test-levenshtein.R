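wednesday_a <- c("w", "ε", "n", "z", "d", "e", "I")
wednesday_b <- c("w", "ε", "n", "ə", "s", "d", "e")

test_that("the classic worked alignment costs 3 edit operations", {
  al <- align(wednesday_a, wednesday_b)
  expect_equal(al$total, 3)
  expect_equal(sum(al$pairs$cost), al$total)
  # removing gaps from each side reproduces the inputs
  expect_equal(al$pairs$a[al$pairs$a != gap_symbol], wednesday_a)
  expect_equal(al$pairs$b[al$pairs$b != gap_symbol], wednesday_b)
})

test_that("identical and empty inputs behave as boundary cases", {
  expect_equal(edit_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(edit_distance(character(0), c("a", "b", "c")), 3)
  expect_equal(edit_distance(character(0), character(0)), 0)
})

test_that("a sensitive cost table prices the worked alignment at 0.081", {
  ct <- segment_costs(tibble::tibble(
    seg1 = c("-", "z", "I"),
    seg2 = c("ə", "s", "-"),
    cost = c(0.031, 0.020, 0.030)
  ))
  expect_equal(align(wednesday_a, wednesday_b, ct)$total, 0.081)
})

test_that("cost tables validate and symmetrize", {
  expect_error(
    segment_costs(tibble::tibble(seg1 = "a", seg2 = "b", cost = -1)),
    "non-negative"
  )
  expect_error(
    segment_costs(tibble::tibble(seg1 = "a", seg2 = "a", cost = 0.5)),
    "identity"
  )
  ct <- segment_costs(tibble::tibble(seg1 = "o", seg2 = "u", cost = 0.2))
  expect_equal(edit_distance("to", "tu", ct), edit_distance("tu", "to", ct))
  expect_equal(edit_distance("to", "tu", ct), 0.2)
})

test_that("DP alignment equals the brute-force recursion on short pairs", {
  set.seed(33)
  inv <- c("a", "b", "c")
  for (rep in 1:40) {
    x <- sample(inv, sample(0:6, 1), replace = TRUE)
    y <- sample(inv, sample(0:6, 1), replace = TRUE)
    expect_equal(edit_distance(x, y), brute_edit_distance(x, y))
    # symmetry under (symmetric) unit costs
    expect_equal(edit_distance(x, y), edit_distance(y, x))
  }
})

test_that("weighted totals never exceed unit totals for costs within [0,1]", {
  set.seed(34)
  ct <- segment_costs(tibble::tibble(
    seg1 = c("a", "a", "b", "-"),
    seg2 = c("b", "c", "c", "a"),
    cost = c(0.3, 0.6, 0.1, 0.5)
  ))
  for (rep in 1:20) {
    x <- sample(c("a", "b", "c"), sample(1:6, 1), replace = TRUE)
    y <- sample(c("a", "b", "c"), sample(1:6, 1), replace = TRUE)
    expect_lte(edit_distance(x, y, ct), edit_distance(x, y))
  }
})

test_that("PMI learning ranks frequently aligned segments cheaper", {
  # x always aligns with y, never with z
  a <- toy_corpus(c("pax", "tex", "kox"), speaker = "A")
  b <- toy_corpus(c("pay", "tey", "koy"), speaker = "B")
  ct <- learn_pmi_costs(dplyr::bind_rows(a, b))
  costs <- ct$pairs
  cxy <- costs$cost[costs$seg1 == "x" & costs$seg2 == "y" |
    costs$seg1 == "y" & costs$seg2 == "x"]
  expect_length(cxy, 1L)
  # unobserved pair falls back to the default, which must be dearer
  expect_lt(cxy, ct$default)
})

test_that("identical corpora learn zero identity costs and converge", {
  a <- toy_corpus(c("pat", "iku"), speaker = "A")
  b <- toy_corpus(c("pat", "iku"), speaker = "B")
  ct <- learn_pmi_costs(dplyr::bind_rows(a, b))
  expect_true(all(ct$pairs$cost[ct$pairs$seg1 == ct$pairs$seg2] == 0))
  expect_true(attr(ct, "converged"))
})

test_that("a systematic vowel shift earns a cheap substitution", {
  a <- toy_corpus(c("sok", "tol", "mon", "pok", "ros", "nol"), speaker = "A")
  b <- a
  b$speaker <- "B"
  b$pronunciation <- gsub("o", "u", b$pronunciation)
  ct <- learn_pmi_costs(dplyr::bind_rows(a, b))
  costs <- ct$pairs
  c_ou <- costs$cost[(costs$seg1 == "o" & costs$seg2 == "u") |
    (costs$seg1 == "u" & costs$seg2 == "o")]
  expect_length(c_ou, 1L)
  # cheaper than the generic substitution cost (default for unseen pairs)
  expect_lt(c_ou, ct$default)
  # and the weighted aggregate shrinks accordingly
  expect_lt(
    aggregate_levenshtein(a, b, ct),
    aggregate_levenshtein(a, b)
  )
  # brute-force recount: every 'o' slot aligned against 'u'
  n_ou <- sum(vapply(seq_len(nrow(a)), function(i) {
    al <- align(a$pronunciation[i], b$pronunciation[i], ct)
    sum((al$pairs$a == "o" & al$pairs$b == "u") |
      (al$pairs$a == "u" & al$pairs$b == "o"))
  }, numeric(1)))
  expect_equal(n_ou, sum(vapply(strsplit(a$pronunciation, ""), function(s) sum(s == "o"), numeric(1))))
})

test_that("PMI learning errors when nothing aligns", {
  a <- toy_corpus("pat", speaker = "A", outcome = "w1")
  b <- toy_corpus("iku", speaker = "B", outcome = "w2")
  expect_error(learn_pmi_costs(dplyr::bind_rows(a, b)), "no alignable")
})

test_that("aggregate distance averages over shared outcomes only", {
  a <- toy_corpus(c("pat", "iku"), speaker = "A", outcome = c("w1", "w2"))
  b <- toy_corpus(c("pat", "xyz"), speaker = "B", outcome = c("w1", "w3"))
  expect_equal(aggregate_levenshtein(a, b), 0)   # only w1 shared, identical
  expect_error(
    aggregate_levenshtein(a, toy_corpus("q", outcome = "w9", speaker = "C")),
    "share no outcomes"
  )
  # identical corpora -> 0; single shared word -> its edit distance
  expect_equal(aggregate_levenshtein(a, a), 0)
  b2 <- toy_corpus("pta", speaker = "B", outcome = "w1")
  expect_equal(aggregate_levenshtein(a, b2), edit_distance("pat", "pta"))
})

test_that("aggregate distance grows with synthetic perturbation rate", {
  set.seed(55)
  wins <- 0
  for (s in 1:10) {
    lex <- generate_lexicon(15, seed = 400 + s)
    mild <- perturb_speaker(lex, sub_rate = 0.1, speaker = "m", seed = 500 + s)
    heavy <- perturb_speaker(lex, sub_rate = 0.4, ins_rate = 0.1, speaker = "h", seed = 600 + s)
    wins <- wins + (aggregate_levenshtein(heavy, lex) > aggregate_levenshtein(mild, lex))
  }
  expect_gte(wins, 9)
})
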