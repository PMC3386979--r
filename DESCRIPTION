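Package: dtnet
Title: Drug-Target Bipartite Networks, Projections, and Centrality-Sales Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds two-mode drug-target interaction networks from pair
    records, projects them into one-mode drug-drug and target-target
    networks whose edge weights count shared partners, computes normalized
    betweenness centrality (Brandes' algorithm with an exhaustive
    geodesic-enumeration oracle), ranks targets and drugs, and tests the
    association between drug betweenness centrality and market sales with
    parametric and permutation p-values. Includes a synthetic cohort
    generator (zero-truncated Poisson target counts, preferential-attachment
    hub targets, therapeutic-class blocks, planted centrality-sales
    correlation) and Pajek NET, GraphML and TSV input/output.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
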