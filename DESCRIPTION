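Package: serumnetpharm
Title: Serum Pharmacochemistry and Network Pharmacology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational core of a serum-pharmacochemistry plus
    network-pharmacology study of multi-herb decoctions: ppm-tolerance
    annotation of MS1 peaks against a compound library with molecular formula
    enumeration, ligand-based compound-to-target prediction by Tanimoto
    similarity of binary structural fingerprints, construction and
    degree analysis of compound-target and compound-target-disease networks
    with core-constituent selection, protein-protein interaction network
    topology with a permutation subnetwork-enrichment test, and
    hypergeometric over-representation analysis with functional-group
    percentage shares. Includes a seeded synthetic-data generator with
    planted ground truth for end-to-end benchmarking, and a pipeline
    orchestrator driven by a flat configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
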