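Package: cwpsoil
Title: Soil Core Communities and Edaphoclimatic Ecoregions of Crop Wild
    Progenitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-kingdom soil community surveys
    of crop wild progenitor (CWP) habitats. Delineates edaphoclimatic
    ecoregions from site-level climate and soil tables (chained predictive
    mean matching imputation, scaled PCA with square-root-eigenvalue axis
    weighting, K-means with Calinski-Harabasz model selection), selects
    per-kingdom core phylotypes by joint abundance and prevalence criteria,
    builds probabilistic co-occurrence networks from presence-absence
    matrices with exact hypergeometric co-presence tests and walktrap module
    detection, quantifies module completeness and standardized module
    abundances across ecoregions, and fits linear mixed models with CWP
    random intercepts, backward AIC selection, parametric bootstrap
    confidence intervals and hierarchical variance partitioning over
    predictor groups. Includes a synthetic-data generator with planted
    ground truth (ecoregions, core taxa, co-occurrence modules,
    environmental effects) so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    vegan,
    lme4,
    emmeans,
    nortest,
    jsonlite,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
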