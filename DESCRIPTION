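Package: iscshare
Title: Dyadic Inter-Subject Correlation Analysis of Information Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links neural similarity between members of a social community to
    their likelihood of sharing content. Computes dyadic inter-subject
    correlations (ISC) of regional brain time series recorded during
    naturalistic viewing, Fisher z-transforms and normalizes them within
    region, builds dyad-level sharing categories and demographic-similarity
    covariates, and fits doubled-data linear mixed-effects models with
    fully crossed random effects, applying an N - k degrees-of-freedom
    correction for the redundancy introduced by doubling. Planned contrasts
    of sharing categories are corrected across regions with Holm-Bonferroni.
    Companion behavioral analyses model sharing likelihood from perceived
    similarity (crossed random intercepts for participant and item) and from
    an experimentally manipulated social context (linear model with planned
    pairwise contrasts under FDR correction). A seeded synthetic-data
    generator with known ground truth drives simulation-based testing and
    parameter recovery for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
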