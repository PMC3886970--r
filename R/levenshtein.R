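#' Gap sentinel used in alignments and cost tables
#' @export
gap_symbol <- "-"

#' Build a segment cost table
#'
#' A symmetric table of substitution and indel costs over segments, with
#' the gap sentinel [gap_symbol] standing in for insertion/deletion.
#' Identity costs are 0 by definition; pairs absent from the table fall
#' back to `default` (1 gives the classic unit-cost Levenshtein distance).
#'
#' @param pairs Tibble/data frame with columns `seg1`, `seg2`, `cost`
#'   (costs >= 0; rows with `seg1 == seg2` must have cost 0), or `NULL`
#'   for pure unit costs.
#' @param default Cost for pairs not listed (>= 0).
#' @return An object of class `segment_costs`.
#' @export
segment_costs <- function(pairs = NULL, default = 1) {
  if (!is.finite(default) || default < 0) rlang::abort("`default` cost must be >= 0.")
  if (is.null(pairs)) {
    pairs <- tibble::tibble(seg1 = character(), seg2 = character(), cost = numeric())
  }
  pairs <- tibble::as_tibble(pairs)
  need <- c("seg1", "seg2", "cost")
  if (!all(need %in% names(pairs))) {
    rlang::abort("`pairs` needs columns seg1, seg2, cost.")
  }
  if (any(!is.finite(pairs$cost) | pairs$cost < 0)) {
    rlang::abort("segment costs must be non-negative and finite.")
  }
  if (any(pairs$seg1 == pairs$seg2 & pairs$cost != 0)) {
    rlang::abort("identity cost(x, x) must be 0.")
  }
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    key <- cost_key(pairs$seg1[i], pairs$seg2[i])
    assign(key, pairs$cost[i], envir = lookup)
  }
  structure(
    list(pairs = pairs, default = default, lookup = lookup),
    class = "segment_costs"
  )
}

cost_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")

cost_of <- function(costs, a, b) {
  if (identical(a, b)) return(0)
  if (is.null(costs)) return(1)
  key <- cost_key(a, b)
  if (exists(key, envir = costs$lookup, inherits = FALSE)) {
    get(key, envir = costs$lookup, inherits = FALSE)
  } else {
    costs$default
  }
}

#' @export
print.segment_costs <- function(x, ...) {
  cat(sprintf(
    "<segment_costs> %d listed pair(s), default cost %g\n",
    nrow(x$pairs), x$default
  ))
  invisible(x)
}

#' Read / write a segment cost table as TSV (seg1, seg2, cost)
#' @param path File path.
#' @param default Default cost for unlisted pairs.
#' @return A `segment_costs` object.
#' @export
read_costs <- function(path, default = 1) {
  raw <- read_tsv_skipping_header(path)
  require_columns(raw, c("seg1", "seg2", "cost"), path)
  segment_costs(
    tibble::tibble(seg1 = raw$seg1, seg2 = raw$seg2, cost = as.numeric(raw$cost)),
    default = default
  )
}

#' @rdname read_costs
#' @param costs A `segment_costs` object to write.
#' @param header_lines Optional `#%` provenance header lines.
#' @export
write_costs <- function(costs, path, header_lines = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0(header_prefix, " ", header_lines), con)
  }
  writeLines("seg1\tseg2\tcost", con)
  p <- costs$pairs
  writeLines(paste(p$seg1, p$seg2, as.character(p$cost), sep = "\t"), con)
  invisible(path)
}

as_segments <- function(x, diacritics = "strip") {
  if (is.character(x) && length(x) == 1L && nchar(x) != 1L && nzchar(x)) {
    parse_ipa(x, diacritics = diacritics)
  } else {
    as.character(x)
  }
}

#' Optimal alignment of two transcriptions (weighted Levenshtein)
#'
#' Dynamic-programming alignment minimising the total substitution /
#' insertion / deletion cost. With unit costs (`costs = NULL`) the total
#' is the classic Levenshtein edit distance. The backtrace is
#' deterministic, preferring match over substitution over deletion (a
#' segment of `t1` against a gap) over insertion.
#'
#' @param t1,t2 Segment vectors (from [parse_ipa()]) or single IPA strings,
#'   which are parsed with `diacritics = "strip"`. Empty (`character(0)`)
#'   inputs are allowed; the distance is then the other side's indel total.
#' @param costs A [segment_costs()] table, or `NULL` for unit costs.
#' @param normalize If `TRUE`, also report `total / alignment length`.
#' @return Object of class `ndl_alignment`: list with `pairs` (tibble
#'   `a`, `b`, `cost`, gaps as [gap_symbol]), `total`, and `normalized`.
#' @examples
#' align(c("w", "ɪ", "θ"), c("w", "ɪ", "z"))$total
#' @export
align <- function(t1, t2, costs = NULL, normalize = FALSE) {
  if (!is.null(costs) && !inherits(costs, "segment_costs")) {
    costs <- segment_costs(costs)
  }
  a <- as_segments(t1)
  b <- as_segments(t2)
  n <- length(a)
  m <- length(b)
  d <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) d[i + 1L, 1L] <- d[i, 1L] + cost_of(costs, a[i], gap_symbol)
  for (j in seq_len(m)) d[1L, j + 1L] <- d[1L, j] + cost_of(costs, gap_symbol, b[j])
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(
        d[i, j] + cost_of(costs, a[i], b[j]),
        d[i, j + 1L] + cost_of(costs, a[i], gap_symbol),
        d[i + 1L, j] + cost_of(costs, gap_symbol, b[j])
      )
    }
  }
  # backtrace, preferring match > substitution > deletion > insertion
  i <- n; j <- m
  pa <- character(0); pb <- character(0); pc <- numeric(0)
  push <- function(x, y, cost) {
    pa <<- c(x, pa); pb <<- c(y, pb); pc <<- c(cost, pc)
  }
  eps <- 1e-12
  while (i > 0L || j > 0L) {
    sub_cost <- if (i > 0L && j > 0L) cost_of(costs, a[i], b[j]) else Inf
    del_cost <- if (i > 0L) cost_of(costs, a[i], gap_symbol) else Inf
    ins_cost <- if (j > 0L) cost_of(costs, gap_symbol, b[j]) else Inf
    if (i > 0L && j > 0L && abs(d[i + 1L, j + 1L] - (d[i, j] + sub_cost)) < eps) {
      push(a[i], b[j], sub_cost); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(d[i + 1L, j + 1L] - (d[i, j + 1L] + del_cost)) < eps) {
      push(a[i], gap_symbol, del_cost); i <- i - 1L
    } else {
      push(gap_symbol, b[j], ins_cost); j <- j - 1L
    }
  }
  total <- d[n + 1L, m + 1L]
  structure(
    list(
      pairs = tibble::tibble(a = pa, b = pb, cost = pc),
      total = total,
      normalized = if (normalize && length(pa) > 0L) total / length(pa) else NA_real_
    ),
    class = "ndl_alignment"
  )
}

#' @export
print.ndl_alignment <- function(x, ...) {
  cat(paste(format(x$pairs$a, width = 3), collapse = " "), "\n")
  cat(paste(format(x$pairs$b, width = 3), collapse = " "), "\n")
  cat(paste(format(round(x$pairs$cost, 3), width = 3), collapse = " "), "\n")
  cat(sprintf("total cost: %g\n", x$total))
  invisible(x)
}

#' Tidy an alignment into a per-position tibble
#' @param x An `ndl_alignment`.
#' @param ... Unused.
#' @return Tibble `position`, `a`, `b`, `cost`.
#' @method tidy ndl_alignment
#' @export
tidy.ndl_alignment <- function(x, ...) {
  tibble::tibble(
    position = seq_len(nrow(x$pairs)),
    a = x$pairs$a, b = x$pairs$b, cost = x$pairs$cost
  )
}

#' Edit distance between two transcriptions
#'
#' Total cost of the optimal [align()]ment (classic Levenshtein distance
#' under unit costs).
#'
#' @inheritParams align
#' @return A single number.
#' @export
edit_distance <- function(t1, t2, costs = NULL) {
  align(t1, t2, costs = costs)$total
}

# aligned segment-pair counts over all shared-outcome token pairs of all
# variety pairs; used by PMI cost learning
alignment_pair_counts <- function(word_pairs, costs) {
  counts <- new.env(parent = emptyenv())
  bump <- function(x, y) {
    key <- cost_key(x, y)
    assign(key, (if (exists(key, counts, inherits = FALSE)) get(key, counts) else 0) + 1,
      envir = counts
    )
  }
  for (wp in word_pairs) {
    al <- align(wp[[1]], wp[[2]], costs = costs)
    for (r in seq_len(nrow(al$pairs))) bump(al$pairs$a[r], al$pairs$b[r])
  }
  keys <- ls(counts)
  tibble::tibble(
    key = keys,
    count = vapply(keys, get, numeric(1), envir = counts)
  )
}

#' Learn segment costs by pointwise mutual information over alignments
#'
#' Iteratively aligns all shared-outcome token pairs across varieties,
#' counts which segments align with which (gaps count as a pseudo-segment),
#' and converts counts to costs: segment pairs that align more often than
#' chance (high PMI, base-2 log of smoothed joint over the product of
#' marginals) get low costs. The PMI-to-cost map is linear,
#' `(max PMI - PMI) / (max PMI - min PMI)` over observed pairs, so learned
#' costs lie in \[0, 1\]; identity pairs are forced to cost 0 and
#' unobserved pairs fall back to the default cost 1. Alignment and
#' counting repeat until the aligned-pair counts stop changing or
#' `n_iterations` is reached.
#'
#' @param corpus Corpus tibble; varieties are the distinct values of
#'   `by`. All token pairs of each outcome shared by a variety pair are
#'   aligned.
#' @param by Corpus column naming the varieties (default `"speaker"`).
#' @param n_iterations Maximum alignment/recount iterations (>= 1).
#' @param smoothing Additive smoothing constant for joint counts.
#' @param diacritics Segmentation mode for pronunciations.
#' @return A [segment_costs()] table with attributes `iterations` and
#'   `converged`.
#' @export
learn_pmi_costs <- function(corpus, by = "speaker", n_iterations = 10,
                            smoothing = 0.5, diacritics = c("strip", "keep")) {
  diacritics <- rlang::arg_match(diacritics)
  validate_corpus(corpus)
  if (n_iterations < 1L) rlang::abort("`n_iterations` must be >= 1.")
  vars <- unique(corpus[[by]])
  segs <- ipa_segment_list(corpus$pronunciation, diacritics = diacritics)
  word_pairs <- list()
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      rows_i <- which(corpus[[by]] == vars[i])
      rows_j <- which(corpus[[by]] == vars[j])
      shared <- intersect(corpus$outcome[rows_i], corpus$outcome[rows_j])
      for (o in shared) {
        for (ri in rows_i[corpus$outcome[rows_i] == o]) {
          for (rj in rows_j[corpus$outcome[rows_j] == o]) {
            word_pairs[[length(word_pairs) + 1L]] <- list(segs[[ri]], segs[[rj]])
          }
        }
      }
    }
  }
  if (length(word_pairs) == 0L) {
    rlang::abort("no alignable word pairs: varieties share no outcomes.")
  }
  costs <- NULL
  prev <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(n_iterations)) {
    tab <- alignment_pair_counts(word_pairs, costs)
    if (!is.null(prev) && identical(prev, tab)) {
      converged <- TRUE
      break
    }
    prev <- tab
    costs <- pmi_cost_table(tab, smoothing = smoothing)
  }
  attr(costs, "iterations") <- it
  attr(costs, "converged") <- converged
  costs
}

# PMI -> cost mapping over observed aligned pairs
pmi_cost_table <- function(tab, smoothing) {
  parts <- strsplit(tab$key, "\r", fixed = TRUE)
  seg1 <- vapply(parts, `[`, character(1), 1)
  seg2 <- vapply(parts, function(p) if (length(p) > 1L) p[2] else p[1], character(1))
  n_total <- sum(tab$count)
  symbols <- unique(c(seg1, seg2))
  k <- length(symbols)
  # marginal slot probabilities (each aligned pair fills two slots)
  marg <- stats::setNames(numeric(k), symbols)
  for (r in seq_along(seg1)) {
    marg[seg1[r]] <- marg[seg1[r]] + tab$count[r]
    marg[seg2[r]] <- marg[seg2[r]] + tab$count[r]
  }
  p_marg <- marg / (2 * n_total)
  n_cells <- k * (k + 1) / 2
  p_joint <- (tab$count + smoothing) / (n_total + smoothing * n_cells)
  pmi <- log2(p_joint / (p_marg[seg1] * p_marg[seg2]))
  rng <- range(pmi)
  cost <- if (diff(rng) > 0) (rng[2] - pmi) / diff(rng) else rep(0.5, length(pmi))
  cost[seg1 == seg2] <- 0
  segment_costs(
    tibble::tibble(seg1 = seg1, seg2 = seg2, cost = unname(cost)),
    default = 1
  )
}

#' Mean Levenshtein distance between two corpora
#'
#' Aligns every token pair of every outcome shared by the two corpora,
#' averages alignment costs within outcomes, then across outcomes.
#'
#' @param corpus_a,corpus_b Corpus tibbles.
#' @param costs [segment_costs()] table or `NULL` for unit costs.
#' @param normalize `"none"`, or `"length"` to divide each word's cost by
#'   its alignment length before averaging.
#' @param diacritics Segmentation mode.
#' @return A single number: the mean per-word distance.
#' @export
aggregate_levenshtein <- function(corpus_a, corpus_b, costs = NULL,
                                  normalize = c("none", "length"),
                                  diacritics = c("strip", "keep")) {
  normalize <- rlang::arg_match(normalize)
  diacritics <- rlang::arg_match(diacritics)
  validate_corpus(corpus_a)
  validate_corpus(corpus_b)
  shared <- intersect(unique(corpus_a$outcome), unique(corpus_b$outcome))
  if (length(shared) == 0L) rlang::abort("the corpora share no outcomes.")
  segs_a <- ipa_segment_list(corpus_a$pronunciation, diacritics = diacritics)
  segs_b <- ipa_segment_list(corpus_b$pronunciation, diacritics = diacritics)
  per_outcome <- vapply(shared, function(o) {
    ia <- which(corpus_a$outcome == o)
    ib <- which(corpus_b$outcome == o)
    vals <- numeric(0)
    for (i in ia) {
      for (j in ib) {
        al <- align(segs_a[[i]], segs_b[[j]], costs = costs, normalize = TRUE)
        vals <- c(vals, if (normalize == "length") al$normalized else al$total)
      }
    }
    mean(vals)
  }, numeric(1))
  mean(per_outcome)
}

#' Per-speaker Levenshtein aggregates against a reference corpus
#'
#' Convenience comparator for validation: each speaker's tokens are
#' aggregated against the reference corpus with [aggregate_levenshtein()].
#'
#' @param corpus Corpus of speakers to score.
#' @param reference_corpus Reference corpus.
#' @inheritParams aggregate_levenshtein
#' @return Tibble `speaker`, `distance`.
#' @export
speaker_levenshtein <- function(corpus, reference_corpus, costs = NULL,
                                normalize = c("none", "length"),
                                diacritics = c("strip", "keep")) {
  normalize <- rlang::arg_match(normalize)
  diacritics <- rlang::arg_match(diacritics)
  speakers <- unique(corpus$speaker)
  tibble::tibble(
    speaker = speakers,
    distance = vapply(speakers, function(s) {
      aggregate_levenshtein(
        corpus[corpus$speaker == s, , drop = FALSE], reference_corpus,
        costs = costs, normalize = normalize, diacritics = diacritics
      )
    }, numeric(1))
  )
}
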