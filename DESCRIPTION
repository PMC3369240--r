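Package: wpse
Title: Subband Sample-Entropy Analysis of Sustained-Vowel Voice Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies and classifies nonstationary voice signals by
    combining wavelet-packet decomposition with sample entropy. A sustained
    vowel recording is decomposed into frequency-ordered subbands with
    orthogonal Daubechies filter banks, the sample entropy of every subband
    coefficient sequence forms a 62-dimensional complexity profile, subbands
    whose entropy differs significantly between diagnostic groups are
    screened by one-way ANOVA, and subjects are classified with a
    radial-basis-function support-vector machine. Ships a seeded synthetic
    sustained-vowel generator (source-filter synthesis with jitter, shimmer
    and aspiration noise) so the full pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    e1071,
    jsonlite,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
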