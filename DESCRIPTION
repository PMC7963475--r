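Package: nichedomains
Title: Climatic Niche Domains and Climate Regions from Species
    Distribution Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects climatic niche domains and their geographic climate
    regions from gridded species distributions. Species realized niches are
    binned in a quantile-discretized two-dimensional climate space (an energy
    axis such as potential evapotranspiration and a water axis such as annual
    precipitation), assembled into a weighted bipartite species-bin network,
    and clustered by minimizing the map equation with a multi-restart search.
    Domain robustness is quantified by bootstrap significance clustering with
    Jaccard module matching, domains are projected back to geography as
    climate regions, regionalizations are compared with adjusted mutual
    information, and transition zones are characterized with bin specificity,
    projected and actual specificity, and a scalar geographical signal. A
    synthetic-world generator with planted climate archetypes provides ground
    truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
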