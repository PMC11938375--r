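Package: carma
Title: Calcium and RNA Multiplexed Activity (CaRMA) Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for joint single-neuron gene-expression and
    calcium-imaging ("CaRMA" imaging) data. From per-neuron quantitative
    multiplexed-FISH expression profiles and behavioral-state-annotated
    calcium traces, the package derives molecularly defined cell types by
    hierarchical clustering, quantifies state responses with a transformed
    auROC statistic, summarizes within-type response coherence with linear
    purity and consistent-response maps, screens for labeled-line neurons
    across state subsets, decodes behavioral state from single neurons and
    from grouped cell-type ensembles with dummy-type controls, clusters
    neurons into activated/inhibited functional classes with gene and
    cell-type enrichment tests, and predicts functional classes and full
    temporal responses from gene expression alone via sequential forward
    feature selection, shuffle nulls, Youden-J expression thresholds, and
    per-timestamp fraction-of-deviance-explained models. A synthetic-data
    generator with planted ground truth emulates the statistical structure
    of such datasets so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
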