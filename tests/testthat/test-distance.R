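test_that("baseline averages within speaker before across speakers", {
  w <- matrix(c(1, 0.8, 0.6), nrow = 3,
    dimnames = list(c("#ab", "aba", "ba#"), "w1")
  )
  # speaker A says the word twice (activations 1.8+0.6... construct directly)
  corp <- tibble::tibble(
    speaker = c("A", "A", "B"),
    outcome = "w1",
    pronunciation = c("aba", "ab", "a"),
    frequency = 1
  )
  # token activations: "aba" = 1+0.8+0.6 = 2.4; "ab" -> #ab, ab# -> 1; "a" -> #a# -> 0
  base <- baseline_profile(w, corp, n = 3, diacritics = "strip")
  # A's mean (2.4+1)/2 = 1.7; B's 0; across speakers (1.7+0)/2 = 0.85
  expect_equal(base$activation, 0.85)
  # NOT the pooled token mean (2.4+1+0)/3
  expect_false(isTRUE(all.equal(base$activation, mean(c(2.4, 1, 0)))))
})

test_that("two single-token reference speakers average arithmetically", {
  w <- matrix(c(0.5, 0.5, 0, 0.5), nrow = 4,
    dimnames = list(c("#ab", "ab#", "#ac", "ac#"), "w1")
  )
  corp <- tibble::tibble(
    speaker = c("A", "B"), outcome = "w1",
    pronunciation = c("ab", "ac"), frequency = 1
  )
  base <- baseline_profile(w, corp, n = 3, diacritics = "strip")
  expect_equal(base$activation, (1.0 + 0.5) / 2)
})

test_that("a speaker identical to its own single-speaker model has distance 0", {
  lex <- generate_lexicon(20, seed = 1)
  fit <- ndl_train(lex)
  base <- baseline_profile(fit, lex)
  d <- speaker_distances(fit, base, lex)
  expect_identical(d$distance, 0)
  expect_equal(d$n_outcomes, 20L)
})

test_that("constant activation shortfall gives the mean difference", {
  w <- matrix(c(1, 0.6), nrow = 2, dimnames = list(c("#a#", "#b#"), "w1"))
  base <- tibble::tibble(outcome = "w1", activation = 1)
  sp <- tibble::tibble(speaker = "x", outcome = "w1", pronunciation = "b", frequency = 1)
  d <- speaker_distances(w, base, sp, n = 3, diacritics = "strip")
  expect_equal(d$distance, 0.4)
  dabs <- speaker_distances(w, base, sp, mode = "absolute", n = 3, diacritics = "strip")
  expect_equal(dabs$distance, 0.4)
})

test_that("baseline outcomes a speaker lacks are skipped with a warning", {
  lex <- generate_lexicon(10, seed = 3)
  fit <- ndl_train(lex)
  base <- baseline_profile(fit, lex)
  partial <- lex[1:6, ]
  partial$speaker <- "part"
  expect_warning(
    d <- speaker_distances(fit, base, partial),
    "skipped"
  )
  expect_equal(d$n_outcomes, 6L)
  empty_overlap <- tibble::tibble(
    speaker = "z", outcome = "nothere", pronunciation = "pa", frequency = 1
  )
  expect_error(
    suppressWarnings(speaker_distances(fit, base, empty_overlap)),
    "no scorable tokens"
  )
})

test_that("accent distance resampling splits the reference group as specified", {
  # 6 reference speakers at fraction 0.5 -> 3 train / 3 baseline
  lex <- generate_lexicon(12, seed = 5)
  speakers <- lapply(1:6, function(i) {
    perturb_speaker(lex, sub_rate = 0.05, speaker = paste0("ref", i), seed = 50 + i)
  })
  test_sp <- perturb_speaker(lex, sub_rate = 0.4, speaker = "foreign", seed = 99)
  corp <- dplyr::bind_rows(c(speakers, list(test_sp)))
  res <- suppressWarnings(accent_distances(
    corp, paste0("ref", 1:6),
    n_reps = 3, seed = 42
  ))
  expect_equal(nrow(res), 7L)
  expect_equal(unique(res$n_reps), 3L)
  # foreign speaker further than any reference speaker
  expect_gt(
    res$mean_distance[res$speaker == "foreign"],
    max(res$mean_distance[res$speaker != "foreign"])
  )
  # reproducibility: identical seed, identical output
  res2 <- suppressWarnings(accent_distances(
    corp, paste0("ref", 1:6),
    n_reps = 3, seed = 42
  ))
  expect_identical(res, res2)
  expect_error(accent_distances(corp, "ref1"), "at least 2")
})

test_that("dialect matrix has a zero diagonal and the right shape", {
  lex <- generate_lexicon(15, seed = 8)
  v2 <- perturb_speaker(lex, sub_rate = 0.2, speaker = "v2", seed = 81)
  v3 <- perturb_speaker(lex, sub_rate = 0.35, ins_rate = 0.1, speaker = "v3", seed = 82)
  corp <- dplyr::bind_rows(lex, v2, v3)
  dd <- dialect_distances(corp)
  expect_equal(nrow(dd), 9L)
  m <- dialect_matrix(dd)
  expect_identical(unname(diag(m)), c(0, 0, 0))
  expect_equal(rownames(m), colnames(m))
})

test_that("identical corpora under two dialect labels give zero off-diagonals", {
  lex <- generate_lexicon(10, seed = 9)
  copy <- lex
  copy$speaker <- "copy"
  dd <- dialect_distances(dplyr::bind_rows(lex, copy))
  expect_equal(max(abs(dd$distance)), 0)
})

test_that("asymmetry arises when one dialect's cues subsume the other's", {
  # dialect B realises word w2 with A's pronunciation of w1 merged in; the
  # lexicons overlap unevenly so listener A and listener B hear different
  # amounts of familiar material
  a <- tibble::tibble(
    speaker = "A", outcome = c("w1", "w2", "w3"),
    pronunciation = c("pata", "niso", "kelu"), frequency = 1
  )
  b <- tibble::tibble(
    speaker = "B", outcome = c("w1", "w2", "w3"),
    pronunciation = c("pata", "nisolu", "kelu"), frequency = 1
  )
  dd <- dialect_distances(dplyr::bind_rows(a, b))
  m <- dialect_matrix(dd)
  expect_false(isTRUE(all.equal(m["A", "B"], m["B", "A"])))
})

test_that("log transform handles zeros by policy and preserves order", {
  x <- c(1, exp(1), exp(2))
  expect_equal(log_distance(x), c(0, 1, 2))
  expect_message(
    out <- log_distance(c(0, 1, 2)),
    "1 zero"
  )
  expect_true(is.na(out[1]))
  eps <- log_distance(c(0, 1), zeros = "epsilon", epsilon = 1e-6)
  expect_equal(eps[1], log(1e-6))
  expect_error(log_distance(-1), "non-negative")
  # Pearson r between ratings and log distances is invariant to log base
  d <- c(0.1, 0.2, 0.5, 0.9, 1.4)
  y <- c(6, 5, 4, 3, 2)
  expect_equal(
    pearson(y, log_distance(d)),
    pearson(y, log_distance(d, base = 10))
  )
})
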