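Package: gwasnet
Title: Network-Based Pathway Analysis of GWAS with Consensus Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates gene-level genome-wide association p-values with a
    protein-protein interaction network. Nominally significant genes seed a
    random walk with restart over a p-value-weighted, column-normalized
    network; connected modules are scored by a node-weighted Liptak-Stouffer
    Z statistic standardized against random gene sets of the same size, and
    a greedy seed-and-grow search run under several random seeds is condensed
    into consensus modules by Dice-coefficient matching of top subnetworks
    across runs. Also provides a VEGAS-style gene-based association test with
    an adaptive multivariate-normal simulation schedule, genotype quality
    control, synthetic genotype and scale-free network generators with
    planted ground truth for benchmarking, and Fisher exact pathway
    enrichment with Benjamini-Hochberg adjustment, rank-deviation z-scores
    and combined scores for the resulting modules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
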