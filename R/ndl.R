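#' Build frequency-weighted learning events from a corpus
#'
#' One pronunciation token (corpus row) becomes one learning event pairing
#' the token's cue set with its meaning outcome, carrying the token's
#' frequency. Records with identical cues and outcome stay separate events;
#' their frequencies add in the co-occurrence counts downstream.
#'
#' @param corpus Corpus tibble (see [read_corpus()]).
#' @param n n-gram order(s) for [extract_cues()].
#' @param diacritics `"strip"` or `"keep"`.
#' @param digraphs Optional digraph table for [parse_ipa()].
#' @return Tibble with columns `speaker`, `outcome`, `cues` (list of
#'   character vectors), `frequency`.
#' @export
build_events <- function(corpus, n = 3, diacritics = c("strip", "keep"),
                         digraphs = NULL) {
  diacritics <- rlang::arg_match(diacritics)
  validate_corpus(corpus)
  tibble::tibble(
    speaker = corpus$speaker,
    outcome = corpus$outcome,
    cues = cue_set_list(corpus$pronunciation,
      n = n, diacritics = diacritics, digraphs = digraphs
    ),
    frequency = corpus$frequency
  )
}

# dense event-by-cue incidence matrix (0/1) plus index vectors
event_incidence <- function(events) {
  cues <- sort(unique(unlist(events$cues, use.names = FALSE)), method = "radix")
  outcomes <- sort(unique(events$outcome), method = "radix")
  m <- matrix(0, nrow = nrow(events), ncol = length(cues),
    dimnames = list(NULL, cues)
  )
  for (e in seq_len(nrow(events))) {
    m[e, match(events$cues[[e]], cues)] <- 1
  }
  o <- matrix(0, nrow = nrow(events), ncol = length(outcomes),
    dimnames = list(NULL, outcomes)
  )
  o[cbind(seq_len(nrow(events)), match(events$outcome, outcomes))] <- 1
  list(cue = m, outcome = o, cues = cues, outcomes = outcomes)
}

#' Estimate equilibrium association strengths (Danks equations)
#'
#' Solves, for every outcome O, the parameter-free equilibrium of the
#' Rescorla-Wagner learning rule: the association strengths V satisfy
#' \deqn{\sum_j P(c_j \mid c_i)\, V_{jO} = P(O \mid c_i)}
#' over all cues \eqn{c_i}, where the conditional probabilities are
#' frequency-weighted co-occurrence ratios over the learning events. Only
#' conditional probabilities enter, so rescaling all event frequencies by a
#' positive constant leaves the solution unchanged.
#'
#' Cue n-grams routinely co-occur perfectly (every trigram of a word seen
#' only in that word), making the system singular; it is then solved in the
#' minimum-norm least-squares sense via the SVD pseudo-inverse, which is
#' deterministic and order-independent. The worst-case residual
#' \eqn{\max |PV - b|} is stored on the fit.
#'
#' @param events Event tibble from [build_events()].
#' @param tol Relative singular-value cutoff for the pseudo-inverse;
#'   defaults to machine-precision scaled by the matrix size.
#' @return An object of class `ndl_fit`: list with elements `weights`
#'   (cue x outcome matrix), `residual`, `cue_frequency`, `n_events`, and
#'   the cue-extraction settings when created via [ndl_train()].
#' @export
estimate_equilibrium <- function(events, tol = NULL) {
  if (!is.data.frame(events) || nrow(events) == 0L) {
    rlang::abort("`events` must contain at least one learning event.")
  }
  inc <- event_incidence(events)
  f <- events$frequency
  if (any(!is.finite(f) | f <= 0)) rlang::abort("event frequencies must be positive.")
  cooc <- crossprod(inc$cue, inc$cue * f)          # freq(c_i & c_j)
  totals <- diag(cooc)                             # freq(c_i) > 0 by construction
  pmat <- cooc / totals                            # row i: P(c_j | c_i)
  bmat <- crossprod(inc$cue, inc$outcome * f) / totals  # row i: P(O | c_i)
  sv <- svd(pmat)
  if (is.null(tol)) tol <- max(dim(pmat)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  w <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], bmat)) / sv$d[pos])
  dimnames(w) <- list(inc$cues, inc$outcomes)
  structure(
    list(
      weights = w,
      residual = max(abs(pmat %*% w - bmat)),
      cue_frequency = stats::setNames(totals, inc$cues),
      n_events = nrow(events)
    ),
    class = "ndl_fit"
  )
}

#' Train a naive-discriminative-learning listener model on a corpus
#'
#' Convenience wrapper: [build_events()] then [estimate_equilibrium()],
#' recording the cue-extraction settings on the fit so that activations of
#' new pronunciations are computed with the same cue registry.
#'
#' @inheritParams build_events
#' @param tol Passed to [estimate_equilibrium()].
#' @return An `ndl_fit` (see [estimate_equilibrium()]).
#' @examples
#' corpus <- tibble::tibble(
#'   speaker = "s1", outcome = c("pat", "bat"),
#'   pronunciation = c("pat", "bat"), frequency = 1
#' )
#' fit <- ndl_train(corpus)
#' tidy(fit)
#' @export
ndl_train <- function(corpus, n = 3, diacritics = c("strip", "keep"),
                      digraphs = NULL, tol = NULL) {
  diacritics <- rlang::arg_match(diacritics)
  events <- build_events(corpus, n = n, diacritics = diacritics, digraphs = digraphs)
  fit <- estimate_equilibrium(events, tol = tol)
  fit$n <- n
  fit$diacritics <- diacritics
  fit$digraphs <- digraphs
  fit
}

#' @export
print.ndl_fit <- function(x, ...) {
  cat(sprintf(
    "<ndl_fit> %d cues x %d outcomes from %d events (max residual %.3g)\n",
    nrow(x$weights), ncol(x$weights), x$n_events, x$residual
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NDL fit into a cue/outcome/weight tibble
#' @param x An `ndl_fit`.
#' @param ... Unused.
#' @return Tibble with columns `cue`, `outcome`, `weight`.
#' @method tidy ndl_fit
#' @export
tidy.ndl_fit <- function(x, ...) {
  w <- x$weights
  tibble::tibble(
    cue = rep(rownames(w), times = ncol(w)),
    outcome = rep(colnames(w), each = nrow(w)),
    weight = as.vector(w)
  )
}

#' One-row model summary of an NDL fit
#' @param x An `ndl_fit`.
#' @param ... Unused.
#' @return One-row tibble: cue/outcome/event counts and solver residual.
#' @method glance ndl_fit
#' @export
glance.ndl_fit <- function(x, ...) {
  tibble::tibble(
    n_cues = nrow(x$weights),
    n_outcomes = ncol(x$weights),
    n_events = x$n_events,
    residual = x$residual
  )
}

#' Rescorla-Wagner simulation parameters
#'
#' Standard settings: asymptote `lambda = 1`, all cue saliences equal, and
#' equal learning rates for outcome-present and outcome-absent trials. The
#' default step size `alpha * beta = 0.01` is small enough that long runs
#' approach the Danks equilibrium smoothly.
#'
#' @param lambda Asymptote of association (> 0).
#' @param alpha Cue salience.
#' @param beta_present,beta_absent Learning rates on outcome-present /
#'   outcome-absent trials.
#' @return A list of class `rw_params`.
#' @export
rw_params <- function(lambda = 1, alpha = 0.1, beta_present = 0.1,
                      beta_absent = beta_present) {
  if (!is.finite(lambda) || lambda <= 0) rlang::abort("`lambda` must be positive.")
  ab <- alpha * c(beta_present, beta_absent)
  if (any(!is.finite(ab) | ab <= 0 | ab > 1)) {
    rlang::abort("alpha * beta must lie in (0, 1].")
  }
  structure(
    list(
      lambda = lambda, alpha = alpha,
      beta_present = beta_present, beta_absent = beta_absent
    ),
    class = "rw_params"
  )
}

# deterministic frequency-proportional interleaving of events: largest-
# remainder apportionment of trial counts, then low-discrepancy ordering
interleave_stream <- function(freq, n_trials) {
  share <- freq / sum(freq) * n_trials
  counts <- floor(share)
  rem <- n_trials - sum(counts)
  if (rem > 0) {
    extra <- order(share - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  keep <- which(counts > 0)
  pos <- unlist(lapply(keep, function(e) (seq_len(counts[e]) - 0.5) / counts[e]))
  ev <- rep(keep, counts[keep])
  ev[order(pos, ev)]
}

#' Simulate incremental Rescorla-Wagner learning
#'
#' Trial-by-trial learning over an event stream. On each trial, for every
#' present cue and every outcome, the association strength moves by
#' `alpha * beta * (target - total)` where `total` is the summed strength
#' of the present cues for that outcome and `target` is `lambda` when the
#' outcome occurred on the trial and 0 otherwise; absent cues are
#' untouched. With small step sizes and long runs the weights approach the
#' Danks equilibrium computed by [estimate_equilibrium()].
#'
#' @param events Event tibble from [build_events()].
#' @param params An [rw_params()] object.
#' @param n_trials Number of learning trials (>= 1).
#' @param regime `"interleave"` for the deterministic frequency-
#'   proportional trial order (largest-remainder apportionment), or
#'   `"sample"` for multinomial sampling of events by frequency.
#' @param seed RNG seed, required for `regime = "sample"`.
#' @param init Optional starting weight matrix (e.g. a previous
#'   simulation's weights) for staged training designs such as blocking;
#'   its cues and outcomes are merged with those of `events`.
#' @return An `ndl_fit` with extra elements `params`, `n_trials`, `regime`.
#' @export
simulate_rw <- function(events, params = rw_params(), n_trials = 1000,
                        regime = c("interleave", "sample"), seed = NULL,
                        init = NULL) {
  regime <- rlang::arg_match(regime)
  if (!inherits(params, "rw_params")) rlang::abort("`params` must come from rw_params().")
  if (n_trials < 1) rlang::abort("`n_trials` must be >= 1.")
  if (!is.data.frame(events) || nrow(events) == 0L) {
    rlang::abort("`events` must contain at least one learning event.")
  }
  inc <- event_incidence(events)
  stream <- if (regime == "interleave") {
    interleave_stream(events$frequency, n_trials)
  } else {
    if (is.null(seed)) rlang::abort("`seed` is required for regime = \"sample\".")
    withr::with_seed(seed, sample.int(nrow(events), n_trials,
      replace = TRUE, prob = events$frequency
    ))
  }
  cues <- inc$cues
  outcomes <- inc$outcomes
  if (!is.null(init)) {
    init <- as_weight_matrix(init)
    cues <- sort(union(cues, rownames(init)), method = "radix")
    outcomes <- sort(union(outcomes, colnames(init)), method = "radix")
  }
  w <- matrix(0, nrow = length(cues), ncol = length(outcomes),
    dimnames = list(cues, outcomes)
  )
  if (!is.null(init)) w[rownames(init), colnames(init)] <- init
  cue_idx <- lapply(events$cues, match, cues)
  out_idx <- match(events$outcome, outcomes)
  gain_p <- params$alpha * params$beta_present
  gain_a <- params$alpha * params$beta_absent
  for (e in stream) {
    idx <- cue_idx[[e]]
    total <- colSums(w[idx, , drop = FALSE])
    target <- numeric(length(total))
    target[out_idx[e]] <- params$lambda
    gain <- ifelse(seq_along(total) == out_idx[e], gain_p, gain_a)
    delta <- gain * (target - total)
    w[idx, ] <- w[idx, , drop = FALSE] + rep(delta, each = length(idx))
    if (any(!is.finite(w[idx, ]))) {
      rlang::abort("association strengths diverged; reduce the learning rate.")
    }
  }
  structure(
    list(
      weights = w, residual = NA_real_,
      cue_frequency = stats::setNames(colSums(inc$cue * events$frequency), inc$cues),
      n_events = nrow(events),
      params = params, n_trials = n_trials, regime = regime
    ),
    class = "ndl_fit"
  )
}

#' Activation of one outcome given a set of cues
#'
#' The activation of a meaning is the sum of the association strengths
#' between the presented cues and that meaning. Cues never seen in
#' training have no row in the weight matrix and contribute exactly 0.
#'
#' @param weights An `ndl_fit` or a cue-by-outcome weight matrix.
#' @param cues Character vector of cue labels (e.g. from [extract_cues()]).
#' @param outcome A single known outcome label.
#' @return A single number.
#' @export
activation <- function(weights, cues, outcome) {
  w <- as_weight_matrix(weights)
  if (length(outcome) != 1L || !outcome %in% colnames(w)) {
    rlang::abort(sprintf(
      "unknown outcome '%s'; known outcomes: %s.",
      as.character(outcome)[1], paste(colnames(w), collapse = ", ")
    ))
  }
  known <- intersect(cues, rownames(w))
  if (length(known) == 0L) return(0)
  sum(w[known, outcome])
}

#' Activations of all outcomes for one cue set
#'
#' @inheritParams activation
#' @return Tibble with columns `outcome`, `activation`.
#' @export
activation_profile <- function(weights, cues) {
  w <- as_weight_matrix(weights)
  known <- intersect(cues, rownames(w))
  act <- if (length(known) == 0L) {
    stats::setNames(numeric(ncol(w)), colnames(w))
  } else {
    colSums(w[known, , drop = FALSE])
  }
  tibble::tibble(outcome = colnames(w), activation = unname(act))
}

#' Per-token activations of each token's own outcome
#'
#' Scores every corpus row against a listener model: the activation of the
#' row's meaning given the row's pronunciation cues. Tokens whose outcome
#' the listener never learned cannot be scored and are dropped with a
#' warning.
#'
#' @param weights An `ndl_fit` (cue settings are reused) or a weight
#'   matrix (supply `n`/`diacritics` to match training).
#' @param corpus Corpus tibble to score.
#' @param n,diacritics,digraphs Cue-extraction settings; defaults are taken
#'   from the fit when `weights` is an `ndl_fit`.
#' @return `corpus` with an added `activation` column (unknown-outcome rows
#'   removed).
#' @export
token_activations <- function(weights, corpus, n = NULL, diacritics = NULL,
                              digraphs = NULL) {
  if (inherits(weights, "ndl_fit")) {
    if (is.null(n)) n <- weights$n %||% 3
    if (is.null(diacritics)) diacritics <- weights$diacritics %||% "strip"
    if (is.null(digraphs)) digraphs <- weights$digraphs
  } else {
    if (is.null(n)) n <- 3
    if (is.null(diacritics)) diacritics <- "strip"
  }
  w <- as_weight_matrix(weights)
  validate_corpus(corpus)
  unknown <- !corpus$outcome %in% colnames(w)
  if (any(unknown)) {
    rlang::warn(sprintf(
      "dropping %d token(s) whose outcome the listener model never learned (e.g. '%s').",
      sum(unknown), corpus$outcome[which(unknown)[1]]
    ))
    corpus <- corpus[!unknown, , drop = FALSE]
    if (nrow(corpus) == 0L) rlang::abort("no scorable tokens: all outcomes unknown to the model.")
  }
  cues <- cue_set_list(corpus$pronunciation,
    n = n, diacritics = diacritics, digraphs = digraphs
  )
  corpus$activation <- vapply(
    seq_len(nrow(corpus)),
    function(i) activation(w, cues[[i]], corpus$outcome[i]),
    numeric(1)
  )
  corpus
}

`%||%` <- function(a, b) if (is.null(a)) b else a
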