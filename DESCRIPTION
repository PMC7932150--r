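Package: zooregion
Title: Zoogeographic Regionalisation and Endemism Analysis from Species
    Incidence Matrices
Version: 0.1.0
Authors@R:
    person("Sandbox", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for numerical zoogeography from binary species-by-area
    incidence matrices: Jaccard/UPGMA bioregionalisation with phenon-line
    cuts and contiguity-enforced nested hierarchies, centres of (narrow)
    endemism, parsimony analysis of endemicity (Fitch parsimony with
    random-addition and tree-bisection-reconnection search, strict
    consensus, area-of-endemism extraction), biotic element analysis
    (Kulczynski range distances, the distratio clustering statistic, a
    spatially autocorrelated null model of connected ranges, nonmetric
    multidimensional scaling and Gaussian-mixture-with-noise clustering),
    and per-unit endemism surfaces (weighted and corrected weighted
    endemism, Fisher-Jenks natural-breaks classing).  Includes a synthetic
    incidence-data generator with planted vicariant structure so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
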