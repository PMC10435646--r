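Package: scnet
Title: Structural Covariance Networks from Regional Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction and group comparison of structural covariance
    networks from regional cortical thickness and subcortical volume.
    Morphometry tables in the FreeSurfer aparcstats2table/asegstats2table
    dialect are ingested, volumes are corrected for intracranial volume,
    and measures are residualized for age; group-level inter-regional
    Pearson association matrices are thresholded to exact-density binary
    graphs, whose clustering, path length, transitivity, modularity,
    global efficiency and betweenness centrality are normalized against
    degree-preserving (Maslov-Sneppen) rewired null ensembles. Hubs are
    detected at standard-deviation thresholds on betweenness, and group
    differences are assessed by residual-reallocation permutation tests
    with maximal-statistic and false-discovery-rate corrections. A
    synthetic two-group cohort generator with planted covariance
    communities and hub regions provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
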