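Package: snppop
Title: Population-Genomic Analysis of Diploid SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of diploid biallelic SNP
    genotype panels: quality control and allele-frequency computation,
    expected and observed heterozygosity, pairwise Weir-Cockerham F_ST,
    the VanRaden genomic relationship matrix with genomic inbreeding and
    group-block relatedness summaries, principal component decomposition
    of the relationship matrix, depth-limited linkage-disequilibrium decay,
    non-syntenic LD and its sample-size behaviour, and LD-based historical
    effective-population-size trajectories. Includes synthetic genotype
    simulators (Balding-Nichols divergence, forward Wright-Fisher with
    recombination, half-sib family structure) so that every estimator is
    testable by parameter recovery, and a config-driven pipeline that runs
    the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
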