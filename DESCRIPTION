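Package: percnet
Title: Percolation-Based Targeted-Attack Analysis of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-theoretical analysis of weighted functional brain networks
    with a percolation targeted-attack model. Provides proportional-density
    thresholding of correlation matrices, a battery of weighted global and
    nodal network quantifiers (characteristic path length, efficiency,
    modularity, participation, clustering, betweenness, collective influence,
    small-worldness), basis/iterative/random node-removal attack schemes with
    full quantifier trajectories, progression modelling against a diseased
    network baseline, nonparametric group statistics, BrainNet Viewer export,
    and a synthetic two-group connectome cohort generator for end-to-end
    testing without access to subject data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
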