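Package: mtlineage
Title: Mitochondrial DNA Lineage Expansion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting and dating maternal lineage expansions
    from complete mitochondrial genomes. Calls haploid consensus sequences
    from samtools text pileups under coverage and allele-fraction rules,
    assigns haplogroups against a Phylotree-style definition tree, builds
    median-joining networks of coding-region haplotypes with star-cluster
    (expansion) detection, and estimates the age of each expansion with the
    rho statistic and its Saillard standard error under configurable
    molecular clocks, including a purifying-selection-corrected
    complete-genome clock and a linear synonymous clock. A seeded
    synthetic-data generator produces genealogies with known coalescence
    times, haplotypes from a toy haplogroup tree, and read pileups with
    known truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
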