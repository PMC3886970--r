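# shared fixtures and independent oracles for the test suite

demo_file <- function(name) {
  system.file("extdata", name, package = "prondist", mustWork = TRUE)
}

demo_corpus <- function() read_corpus(demo_file("accent_demo_corpus.tsv"))
demo_probe <- function() read_corpus(demo_file("accent_demo_probe.tsv"))
demo_weights <- function() read_weights(demo_file("accent_demo_weights.tsv"))

# quick in-memory corpus builder
toy_corpus <- function(pronunciations, speaker = "s1",
                       outcome = paste0("w", seq_along(pronunciations)),
                       frequency = 1) {
  tibble::tibble(
    speaker = speaker, outcome = outcome,
    pronunciation = pronunciations, frequency = frequency
  )
}

# events straight from cue sets, bypassing IPA parsing
toy_events <- function(cues, outcomes, frequency = 1) {
  tibble::tibble(
    speaker = "s", outcome = outcomes, cues = cues,
    frequency = rep_len(frequency, length(outcomes))
  )
}

# independent brute-force edit distance: plain recursion over suffixes,
# no dynamic programming, unit costs
brute_edit_distance <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(
    brute_edit_distance(a[-1], b[-1]) + (a[1] != b[1]),
    brute_edit_distance(a[-1], b) + 1,
    brute_edit_distance(a, b[-1]) + 1
  )
}

# random event tables over small cue/outcome universes; regenerates until
# the cue conditional-probability matrix has full rank and is reasonably
# well conditioned (a finite-length learning run converges along the
# smallest eigendirection at rate ~ alpha*beta*lambda_min, so wildly
# ill-conditioned draws would need impractically long simulations)
random_full_rank_events <- function(n_cues, n_outcomes, n_events = 8,
                                    min_rcond = 0.05) {
  repeat {
    ev <- tibble::tibble(
      speaker = "s",
      outcome = paste0("o", sample(n_outcomes, n_events, replace = TRUE)),
      cues = lapply(seq_len(n_events), function(i) {
        paste0("c", sort(sample(n_cues, sample(1:3, 1))))
      }),
      frequency = stats::runif(n_events, 0.5, 2)
    )
    cues <- sort(unique(unlist(ev$cues)))
    m <- vapply(ev$cues, function(cs) as.numeric(cues %in% cs), numeric(length(cues)))
    co <- m %*% (t(m) * ev$frequency)
    pm <- co / diag(co)
    if (length(cues) >= 2 && qr(pm)$rank == length(cues) && rcond(pm) > min_rcond) {
      return(ev)
    }
  }
}
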