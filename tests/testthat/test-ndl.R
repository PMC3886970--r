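test_that("build_events yields one frequency-weighted event per token", {
  ev <- build_events(demo_corpus())
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$frequency, c(28169384, 28169384, 852131, 852131))
  expect_setequal(ev$cues[[1]], c("#wɪ", "wɪθ", "ɪθ#"))
  single <- build_events(toy_corpus("pa"))
  expect_equal(nrow(single), 1L)
})

test_that("equilibrium solves forced single-cue systems", {
  # one event {c} -> O: P(O|c) = 1 forces V = 1
  f1 <- estimate_equilibrium(toy_events(list("c"), "O"))
  expect_equal(unname(f1$weights["c", "O"]), 1)
  # {c} -> O1 and {c} -> O2 equally often: 0.5 each
  f2 <- estimate_equilibrium(toy_events(list("c", "c"), c("O1", "O2")))
  expect_equal(unname(f2$weights["c", ]), c(0.5, 0.5))
})

test_that("equilibrium assigns zero weight to non-discriminative cues", {
  # {c1,c2} -> O and {c1} -> O': hand-solved system gives V(c1,O)=0, V(c2,O)=1
  f <- estimate_equilibrium(toy_events(list(c("c1", "c2"), "c1"), c("O", "Oprime")))
  expect_equal(unname(f$weights["c1", "O"]), 0, tolerance = 1e-12)
  expect_equal(unname(f$weights["c2", "O"]), 1, tolerance = 1e-12)
})

test_that("equilibrium residual is tiny on full-rank random systems", {
  set.seed(101)
  for (rep in 1:12) {
    ev <- random_full_rank_events(sample(3:6, 1), sample(2:3, 1))
    f <- estimate_equilibrium(ev)
    expect_lt(f$residual, 1e-8)
  }
})

test_that("equilibrium weights are invariant to frequency rescaling", {
  corp <- demo_corpus()
  f1 <- ndl_train(corp)
  f2 <- ndl_train(dplyr::mutate(corp, frequency = frequency * 1000))
  expect_lt(max(abs(f1$weights - f2$weights)), 1e-10)
})

test_that("training the demo corpus gives the 9-cue x 2-outcome matrix", {
  f <- ndl_train(demo_corpus())
  expect_equal(dim(f$weights), c(9L, 2L))
  expect_setequal(colnames(f$weights), c("with", "her"))
  expect_true("#ɹ#" %in% rownames(f$weights))
})

test_that("RW simulation follows the closed form for a single cue-outcome pair", {
  ev <- toy_events(list("c"), "O")
  p <- rw_params(alpha = 0.1, beta_present = 0.5)
  for (t in c(1, 5, 10, 50)) {
    f <- simulate_rw(ev, p, n_trials = t)
    expect_equal(unname(f$weights["c", "O"]), 1 - (1 - 0.05)^t, tolerance = 1e-12)
  }
})

test_that("pretrained cues block learning about redundant added cues", {
  ev1 <- toy_events(list("c1"), "O")
  pre <- simulate_rw(ev1, rw_params(), n_trials = 2000)
  expect_equal(unname(pre$weights["c1", "O"]), 1, tolerance = 1e-6)
  ev2 <- toy_events(list(c("c1", "c2")), "O")
  blocked <- simulate_rw(ev2, rw_params(), n_trials = 500, init = pre)
  expect_lt(abs(blocked$weights["c2", "O"]), 1e-6)
  # without pretraining the same trials share the credit
  control <- simulate_rw(ev2, rw_params(), n_trials = 500)
  expect_gt(control$weights["c2", "O"], 0.4)
})

test_that("long-run RW simulation converges to the Danks equilibrium", {
  set.seed(202)
  for (rep in 1:10) {
    ev <- random_full_rank_events(sample(3:6, 1), sample(2:3, 1))
    eq <- estimate_equilibrium(ev)
    sim <- simulate_rw(ev, rw_params(alpha = 0.1, beta_present = 0.05),
      n_trials = 50000
    )
    expect_lt(max(abs(sim$weights - eq$weights)), 0.05)
  }
})

test_that("sampled trial regime is seed-reproducible", {
  ev <- toy_events(list(c("c1", "c2"), "c1"), c("O", "Oprime"), frequency = c(3, 1))
  a <- simulate_rw(ev, n_trials = 200, regime = "sample", seed = 9)
  b <- simulate_rw(ev, n_trials = 200, regime = "sample", seed = 9)
  expect_identical(a$weights, b$weights)
  expect_error(simulate_rw(ev, n_trials = 10, regime = "sample"), "seed")
})

test_that("activation sums known-cue weights and ignores unknown cues", {
  w <- demo_weights()
  expect_equal(activation(w, c("#wɪ", "wɪθ", "ɪθ#"), "with"), 0.9995)
  expect_equal(activation(w, c("#wɪ", "wɪz", "ɪz#"), "with"), 0.2519)
  expect_equal(activation(w, c("xx", "yy"), "with"), 0)
  expect_error(activation(w, "#wɪ", "cat"), "known outcomes")
})

test_that("activation is linear in the weights and monotone in added known cues", {
  w <- demo_weights()
  a1 <- activation(w, c("#wɪ"), "with")
  a2 <- activation(w, c("#wɪ", "wɪθ"), "with")
  expect_gt(a2, a1)
  expect_equal(activation(2 * w, c("#wɪ", "wɪθ"), "with"), 2 * a2)
})

test_that("weight matrices round-trip through TSV bit-exactly", {
  f <- ndl_train(demo_corpus())
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_weights(f, tf, digits = NULL, header_lines = "test")
  again <- read_weights(tf)
  expect_identical(again[rownames(f$weights), colnames(f$weights)], f$weights)
})

test_that("tidy and glance summarise a fit", {
  f <- ndl_train(demo_corpus())
  td <- tidy(f)
  expect_equal(nrow(td), 18L)
  expect_named(td, c("cue", "outcome", "weight"))
  g <- glance(f)
  expect_equal(g$n_cues, 9L)
  expect_equal(g$n_events, 4L)
})
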