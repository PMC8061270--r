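Package: popland
Title: Population and Landscape Genetic Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing population genetic connectivity across
    heterogeneous landscapes: per-site nucleotide diversity, Watterson's
    theta and Tajima's D; Hudson's FST with a pooled-resampling permutation
    test of panmixia; population graphs built by conditional-independence
    edge exclusion on the among-locale genetic covariance, with conditional
    genetic distance (cGD); weighted network node metrics with
    edge-permutation and degree-preserving null models; straight-line raster
    transect resistance summaries with degree-constrained landscape
    permutation tests; and maximum-likelihood-population-effects (MLPE)
    regression of pairwise genetic distance on landscape predictors with AIC
    model comparison. Includes a Balding-Nichols synthetic-data generator
    emulating a multi-locale SNP sampling design so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    vcfR,
    geosphere,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
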