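Package: pathwaycrosstalk
Title: Pathway Crosstalk Analysis on Weighted Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies dysfunctional crosstalk among gene pathways by mapping
    case/control expression data onto a voting-ensemble protein-protein
    interaction network. Each interaction is scored with Fisher's combined
    probability method over the differential-expression p-values of its two
    endpoint genes and the disease-condition co-expression p-value of the
    pair. Pathway-pathway crosstalk is assessed by edge-set resampling
    permutation tests on overlapping interactions, pathways are clustered
    from the resulting significance distance matrix, intra-pathway
    dysregulation is ranked per region by the same resampling scheme, and
    functional enrichment is evaluated with the accumulative hypergeometric
    test. A synthetic-data module generates interaction databases, pathway
    collections, two-condition regional expression matrices with planted
    effects, and term annotations, so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
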