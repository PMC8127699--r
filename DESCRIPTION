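Package: exsitu
Title: Designing Ex Situ Collections and Translocation Populations from
    SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for preserving the genetic diversity of wild plant
    populations facing imminent destruction. Implements a complete design
    workflow for biallelic SNP genotype data: quality filtering of
    reduced-representation loci, method-of-moments kinship estimation and
    pruning of clonal ramets, simulated-annealing selection of propagation
    populations that maximize gene diversity (expected heterozygosity),
    evaluation of allele capture against common-locus reference sets,
    forward Wright-Fisher simulation of allele retention in translocation
    populations founded from ramets, multiobjective trade-off analysis
    between diversity and local provenance, and spatial arrangement of
    conservation plantings so that genetically similar plants are kept
    apart. Includes a synthetic-data generator with planted ground truth
    for every stage of the workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
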