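Package: songvar
Title: Sequence Entropy and Variability Analysis of Birdsong Syllables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying variability in zebra-finch song from
    symbolically labeled syllable sequences and per-rendition acoustic
    features. Estimates first-order Markov transition probabilities from
    motif files or long syllable strings, computes per-syllable transition
    entropy with maximum-entropy normalization, frequency-weighted motif
    entropy and sequence stereotypy, and percent change between paired
    behavioral conditions. Summarizes acoustic-feature variability as
    coefficients of variation, aggregates all-vs-all similarity/accuracy
    score batches, and provides a simplified feature-trajectory similarity
    scorer with a sample-count stabilization procedure. Inference uses
    resampling statistics: a sign-flip paired bootstrap test on mean
    conditional differences, a permutation one-way ANOVA on absolute
    deviations, a Wilcoxon signed-rank cross-check, and Monte-Carlo power
    analysis with prospective sample sizes. A synthetic song generator
    (mixture Markov chains with closed-form entropy, paired two-condition
    designs, feature renditions with condition-dependent CV) supports
    estimator validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
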