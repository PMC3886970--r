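---
title: "Methods: discriminative-learning pronunciation distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminative-learning pronunciation distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prondist)
```

## The model

`prondist` measures how far one pronunciation of a word is from another
through the lens of a trained *listener*. The listener is a naive
discriminative learner: every pronunciation token is a learning event in
which a set of cues (phone n-grams over the transcription) co-occurs with
one outcome (the word's meaning). The Rescorla–Wagner rule adjusts the
association strength between each present cue and every outcome in
proportion to the prediction error; cues that reliably and *exclusively*
accompany a meaning end up with high weights, while cues shared across
meanings are discounted through cue competition.

Rather than simulating trials, training solves the equilibrium of that
process directly (the Danks equations): for each outcome $O$, the weights
$V$ satisfy

$$\sum_j P(c_j \mid c_i)\, V_{jO} \;=\; P(O \mid c_i)
\quad\text{for every cue } c_i,$$

with conditional probabilities computed as frequency-weighted
co-occurrence ratios over the events. Two consequences matter in
practice:

* **Scale invariance.** Only conditional probabilities enter, so
  multiplying every corpus frequency by a positive constant leaves the
  weights unchanged (tested to $10^{-10}$). Frequencies may therefore be
  corpus counts, per-million rates, or any positive real.
* **Order independence.** The equilibrium does not depend on trial
  order. The package still ships an incremental simulator
  (`simulate_rw()`) because it is the natural independent check: on
  small full-rank systems a long, small-step run must land on the
  equilibrium solution, and it does (see below).

The *activation* of a meaning given a pronunciation is the sum of the
weights of its cues. Cues absent from training have no stored weight and
contribute exactly 0 — this is the mechanism that makes foreign material
costly: it cannot add activation. Distances are activation differences
against a baseline listener profile, averaged over the word list; because
each listener has its own weight matrix, $d(i,j) \ne d(j,i)$ in general,
and self-distance is identically 0.

## Cues

Transcriptions are segmented one base IPA character per segment;
combining marks and a documented set of modifier letters
(`ipa_modifier_chars`) are diacritics, either stripped (default) or kept
attached to their base. Affricates and diphthongs stay two segments
unless the caller declares digraph units. The default cue is the
**boundary-padded trigram**: `#` is added at each word edge and every
window of three consecutive segments becomes one cue, so a $k$-segment
word contributes $k$ windows and a one-segment word the single cue
`#x#`. Trigrams make the measure sensitive to how a sound is realised in
its immediate context. Unigram and bigram registries are available for
comparison (`n = 1`, `2`), and orders can be unioned (`n = c(1, 3)`).
Two deliberate choices:

* Cue sets are **presence types**: a trigram occurring twice in a word
  counts once. The equilibrium formulation is in terms of cue presence.
* Unigram cues exclude the boundary marker, which would co-occur with
  every outcome and discriminate nothing; padded bigrams/trigrams keep
  it, as the `#x#` single-segment case requires.

## Distances

* `baseline_profile()` averages activations **within speaker first**
  (repeated word tokens), then across speakers, so prolific speakers do
  not dominate the baseline.
* `speaker_distances()` subtracts the speaker's per-outcome activation
  from the baseline. The default is the **signed** difference: test cues
  can only fail to add weight, so the aggregate is almost always
  positive and retains its sign as "foreignness"; an `absolute` mode is
  available since either convention is defensible. Outcomes a speaker
  never produces are skipped with a warning, not scored zero — inventing
  a penalty for missing words would conflate coverage with accent.
* `accent_distances()` guards against overfitting to a particular
  training sample: each repetition trains on a random half of the
  reference speakers (`ceiling(0.5 N)`), uses the other half as the
  baseline, and the per-speaker distance is the mean over repetitions
  (100 by default; the standard deviation over repetitions is reported
  alongside). All resampling is governed by one seed and is
  bit-reproducible.
* `dialect_distances()` trains one listener per variety, uses the
  variety's own speech as its baseline, and fills an asymmetric
  listener-by-speaker grid with an exactly-zero diagonal. With $k$
  varieties this yields $k(k-1)$ informative cells (210 for $k = 15$).
* `log_distance()` supports the log transform commonly applied before
  correlating with perceptual ratings. Zeros (self-distances) are
  dropped by default, or offset by an explicit epsilon; the correlation
  is invariant to the log base.

## The Levenshtein comparator

`align()` is a standard dynamic-programming alignment with pluggable
symmetric segment costs (unit costs reproduce the classic edit
distance). The backtrace is deterministic: match is preferred over
substitution over deletion over insertion, so identical inputs always
yield identical alignments. `learn_pmi_costs()` derives graded costs
from the data: all shared-outcome token pairs across varieties are
aligned, aligned segment pairs are counted (gaps as a pseudo-segment),
and pointwise mutual information — base-2 log of the smoothed joint
probability over the product of the marginal slot probabilities — is
mapped linearly onto $[0, 1]$ costs, high PMI meaning low cost. Identity
pairs are forced to cost 0 and unobserved pairs fall back to the default
cost 1. Alignment and counting iterate to a fixed point (typically 2–3
iterations on small corpora). The PMI-to-cost map is a documented,
pluggable choice, not a claim of equivalence to any particular published
cost schedule; additive smoothing (0.5 by default) keeps rare pairs
finite.

## Evaluation utilities

`pearson()` wraps the product-moment correlation with explicit
preconditions (≥ 3 complete pairs, non-zero variance).
`cronbach_alpha()` computes $\alpha = \frac{k}{k-1}\bigl(1 -
\mathrm{tr}(S)/\mathrm{sum}(S)\bigr)$ over the rater covariance matrix;
because raters typically judge overlapping subsets, the default policy
uses pairwise-complete covariances (which can push $\alpha$ marginally
above 1), with a complete-case policy available. `rater_agreement()`
correlates each rater with the consensus, leave-one-out by default so a
rater is not compared against themselves.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage is testable without external
recordings. `generate_lexicon()` builds a canonical variety: distinct
CV-alternating words (2–7 segments, 19-segment default inventory) with
Zipf-distributed frequencies (exponent 1 by default — the shape of real
word-frequency lists; exponent 0 gives a flat profile).
`perturb_speaker()` derives further varieties by i.i.d. per-segment
edits — substitution toward ring neighbours in the sorted inventory (a
deterministic stand-in for phonetic similarity), uniform insertions,
deletions with empty-word redraws. `generate_ratings()` emulates a
Likert panel: a monotone decreasing linear map from distance onto the
1–7 scale plus per-rater Gaussian noise, rounded and clipped.

These fixtures capture the *structural* properties the method relies on
(shared word lists, within-variety coherence, graded cross-variety
divergence, noisy monotone perceptions) but not the phonology of real
accents: edits are context-free, there is no suprasegmental variation,
and confusions are not acoustically motivated. Passing tests therefore
demonstrate that the machinery recovers planted structure under
controlled conditions — not that any particular real-data correlation
will be attained. Correlations against real perceptual ratings require
the corresponding recordings and rating studies, which are out of scope
here.

## Numerical choices

* **Singular systems.** Trigram cues routinely co-occur perfectly (each
  trigram of a word seen only in that word), so the conditional
  probability matrix is often rank-deficient. The solver uses the SVD
  pseudo-inverse (minimum-norm least squares) with the conventional
  cutoff `max(dim) * eps * max(singular value)`: deterministic,
  order-independent, and exact on full-rank systems, where the residual
  is at machine precision (tested below $10^{-8}$).
* **Simulation regimes.** The simulator's default trial order is a
  deterministic frequency-proportional interleave (largest-remainder
  apportionment, low-discrepancy ordering); multinomial sampling with an
  explicit seed is the alternative. The default step size
  $\alpha\beta = 0.01$ is small enough for smooth convergence; the
  equilibrium cross-check uses $\alpha\beta = 0.005$ over 50{,}000
  trials on systems kept reasonably well-conditioned (reciprocal
  condition number above 0.05), since convergence along the smallest
  eigendirection is what limits finite runs; agreement is required to
  0.05 and typically lands near $10^{-3}$.
* **Alignment ties** are broken match > substitution > deletion >
  insertion on the backtrace; with floating-point cost tables,
  comparisons use a $10^{-12}$ slack.
* **Degenerate inputs.** Empty transcriptions are a parse error; empty
  segment vectors are legal alignment inputs (distance = the other
  side's indel total); all-zero perturbation rates return an identical
  copy; zero distances are handled by an explicit policy in the log
  transform; unknown outcomes raise errors naming the known ones.
* **File formats.** All I/O is UTF-8 TSV. Provenance headers are
  prefixed `#%` because `#` itself is the word-boundary marker and a
  legal first character of a cue label. Weight tables round-trip
  bit-exactly via `%.17g` when written with `digits = NULL`.

## Problem sizes

The shipped tests and the acceptance script run at deliberately small
scale, chosen to exercise every code path while keeping a full run in
tens of seconds: lexica of 20–30 words for distance checks, 25-word
lexica across 20 seeds for the perturbation-monotonicity sign test, a
12-speaker graded panel for the rating and comparator correlations, a
15-variety grid for the matrix-shape check, and ≤ 6-cue systems for the
solver oracles. These sizes are the package's own test design; the
functions themselves have no such limits, and the resampling listener
construction mirrors the archive-scale design (115 reference speakers
splitting 58/57) at any corpus size.

## Known limitations

* Cues are discrete segment n-grams; intonation, duration and other
  continuous properties enter only if the user discretises them into
  additional cues.
* A single adult-state weight matrix per listener: no ongoing learning,
  no within-listener variation.
* Listener models trained on one speaker (the one-speaker-per-dialect
  design) inherit that speaker's idiosyncrasies; more speakers per
  variety sharpen the estimates.
* The PMI cost mapping is one reasonable choice among several; users
  comparing against published weighted-Levenshtein results should supply
  their own cost tables via `segment_costs()` / `read_costs()`.
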