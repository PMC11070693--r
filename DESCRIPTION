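Package: mindnet
Title: Information-Theoretic Causal Discovery for Mixed-Type Observational Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based causal network learning for tables mixing
    continuous and categorical variables. Edges are removed by iteratively
    collecting positive information contributors until the regularized
    conditional mutual information of a pair vanishes; mutual information
    involving continuous variables is estimated by an optimal-discretization
    supremum principle with a dynamic-programming search over cut-points.
    Orientations rely on rectified three-point information scores that remain
    rankable at very large sample sizes, distinguish genuine from putative
    causes and flag latent common causes as bidirected edges, with optional
    contextual-variable priors and indirect-path consistency of separating
    sets. Includes a mixed-type structural-equation benchmark generator with
    configurable discrete-variable proportion and a three-level
    (skeleton/CPDAG/oriented-subgraph) scoring harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
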