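Package: haplogen
Title: Generative Models and Fidelity/Privacy Auditing for Artificial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains generative models (a fully-connected generative adversarial
    network, a restricted Boltzmann machine with persistent contrastive
    divergence, and per-site Bernoulli and window Markov-chain baselines) on
    phased binary haplotype matrices and audits the resulting artificial
    genomes with a suite of fidelity and privacy statistics: allele-frequency
    correlation, linkage-disequilibrium matrices and binned decay curves,
    three-point correlations, pairwise-distance distributions, joint principal
    component embeddings with entropic optimal-transport distances,
    nearest-neighbour adversarial accuracy and privacy loss. Includes a
    structured-haplotype simulator (Balding-Nichols population structure plus a
    mosaic copying process) so the whole pipeline runs end-to-end on synthetic
    data, and readers/writers for a plain-text haplotype format and phased VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    cluster,
    clue
Config/testthat/edition: 3
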