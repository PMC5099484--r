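Package: mitokit
Title: Comparative Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Mitokit", "Developers", email = "mitokit@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative analysis of plant organelle genomes:
    contig-graph assembly of circular mitochondrial genomes with
    depth-window filtering and repeat-aware path walking; microsatellite
    (SSR), tandem and dispersed direct/inverted repeat detection; genome
    composition, codon and intron statistics; conserved gene-cluster
    detection; detection of intracellular DNA transfer (plastid-to-
    mitochondrion and mitochondrion-to-nucleus) and syntenic blocks;
    conservation-scored prediction of C-to-U RNA-editing sites;
    Nei-Gojobori (1986) Ka/Ks estimation and neighbor-joining phylogeny
    with bootstrap. Includes a synthetic-genome simulator that plants
    repeats, gene clusters, transfer blocks and editing sites with
    machine-readable truth tables so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
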