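Package: smurfdeconv
Title: Two-Phase Ageing Model and Smurf/Age Transcriptome Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the two-phase (Smurf) model of ageing in Drosophila
    and for separating Smurfness-associated from chronological-age-associated
    transcriptional signal in bulk RNA-seq. Provides deterministic and
    stochastic demographic simulation with closed-form survival under the
    linear-prevalence approximation, a negative-binomial count simulator
    emulating biphasic cohort designs, differential expression with two
    independent estimators, preranked gene-set enrichment with a permutation
    null, transcriptional-noise (relative standard deviation) analysis, a
    two-dimensional Kolmogorov-Smirnov (Fasano-Franceschini) test over
    per-gene correlation maps, hallmark attribution, and Smurf-prevalence
    regression for longevity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    deSolve,
    yaml,
    DESeq2,
    edgeR,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
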