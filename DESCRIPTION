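Package: prondist
Title: Pronunciation Distances from Naive Discriminative Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cognitively grounded pronunciation distances between
    speakers, accents and dialects from phonetically transcribed word lists.
    A listener model is trained by naive discriminative learning: phone
    n-gram cues (boundary-padded trigrams by default) are associated with
    word meanings at the Danks equilibrium of the Rescorla-Wagner learning
    rule, and the activation of a meaning given a pronunciation is the sum
    of the association strengths of its cues. Distances are activation
    differences relative to a baseline listener and may be asymmetric.
    Includes an incremental Rescorla-Wagner simulator, a plain and
    segment-cost-weighted Levenshtein comparator with pointwise mutual
    information cost learning, rating-based evaluation utilities
    (Pearson correlation, Cronbach's alpha), and seeded synthetic corpus
    generators for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
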