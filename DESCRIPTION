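Package: mirnet
Title: MicroRNA Co-Expression Network Analysis for Paired Tumour-Normal Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and characterises microRNA co-expression networks from
    paired tumour/normal expression profiles. Provides paired differential
    expression with Benjamini-Hochberg false discovery control, significance
    gated Spearman correlation networks, global and local graph topology
    (density, centralization, heterogeneity, weighted betweenness and
    closeness, clustering and topological coefficients), MCODE molecular
    complex detection with a binomial density null, cross-condition network
    comparison and motif census (triangles, chains, pairs), hypergeometric
    target-gene set enrichment from GMT files, and a synthetic paired-design
    generator with planted differential expression and planted correlated
    modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
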