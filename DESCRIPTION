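Package: convoturn
Title: Turn-Taking Timing Analysis and Resynthesis for Dyadic Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting and manipulating floor-transfer offsets
    (FTOs) in two-channel recordings of dyadic conversations. Provides
    energy-threshold voice activity detection, a communicative-state
    classifier that groups inter-pausal units into turns and
    overlaps-within, logistic modelling of FTO distributions (fitting,
    sampling, affine transforms between distributions, and the overlapping
    index between two densities), resynthesis of conversation segments
    under constant or distribution-drawn FTO schemes with loudness
    equalization and pause compression, balanced presentation-list
    construction for listening experiments, synthetic conversation and
    rating generators for end-to-end testing, and a ratings-analysis layer
    (mixed-effects models, Spearman correlations, matched-subset search,
    and Wilcoxon rank-sum tests with exact small-sample enumeration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    lme4,
    lmerTest,
    jsonlite,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
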