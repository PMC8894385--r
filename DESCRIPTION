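Package: vsmcscreen
Title: High-Content Cell-Shape Screening and miRNA Network Analysis for
    Vascular Smooth Muscle Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies vascular smooth muscle cell (VSMC) shape from
    two-channel fluorescence well images (elongation E and cell shape
    index CSI), classifies contractile versus synthetic phenotypes,
    aggregates wells into contractile/synthetic ratios and calls hits in
    replicated miRNA overexpression screens, performs logCPM moderated-t
    differential expression of miRNA count matrices with BH-FDR control,
    and integrates screen hits with expression candidates into
    shared-target, maximal-clique-centrality hub and drug-gene
    interaction networks. Ships a synthetic-data generator (well images
    with known per-cell geometry, negative-binomial count matrices with
    planted effects, and target/PPI/drug fixtures with planted
    structure) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
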