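Package: pollinet
Title: Plant-Pollinator Network Analysis for Pollination Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing pollination of rare plants from
    community-wide visitation surveys. Builds quantitative bipartite
    plant-pollinator networks from long-format visitation records and
    computes connectance, nestedness (NODF and its weighted variant),
    complementary specialization (H2'), and quantitative bipartite
    modularity optimized by simulated annealing. Statistical significance
    of network-level metrics is judged against fixed-marginal (Patefield)
    null ensembles. Keystone species are ranked from unweighted degree,
    betweenness and closeness centrality. Daily networks of different
    sizes are compared through maximum-NODF normalization and the
    combined nestedness index NODF_c. Includes seed-deterministic
    generators of nested and modular visitation matrices, and a packaged
    fixture encoding the published summary tables of a Cypripedium
    guttatum pollination survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
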