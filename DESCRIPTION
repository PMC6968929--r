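Package: pclineage
Title: Quantitative Clonal Analysis of Pyramidal-Cell Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the quantitative analysis of pyramidal-cell lineages
    in the developing neocortex. Provides deterministic classification of
    clones by laminar configuration (translaminar versus deep- or
    superficial-layer restricted), neurogenic size filters and MADM
    subclone rules; a permutation null model that shuffles neurons among
    lineages while conserving laminar identities and clone sizes; Bayesian
    nonparametric inference of the number of progenitor types from
    layer-occupancy counts via a Dirichlet-process binomial mixture with a
    censoring mask and Gibbs sampling; a sequential stochastic simulator of
    lineage generation with one or two progenitor populations and a fitting
    loop that tunes generation probabilities to target summaries; and the
    summary statistics and z-score comparisons used to confront models with
    clonal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
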