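Package: resistome
Title: Gene-Centric Profiling of Arsenic Resistance and Metabolism Genes in
    Soil Genomes and Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-centric profiling of the soil arsenic resistome:
    quality screening of homology-search hits against complete genomes with
    per-gene bit-score and alignment-coverage cascades, chromosome versus
    plasmid genotype matrices with phylum summaries, phylogenetic-signal
    testing of binary gene-presence traits with Blomberg's K and a
    permutation null, cultivation-weighted and rplB-normalized abundance
    estimation, greedy percent-identity clustering of assembled protein
    variants with endemic/cosmopolitan classification, and Mann-Whitney and
    Mantel comparisons of abundance and biogeography. A seeded synthetic-data
    generator with machine-readable truth ledgers emulates every input so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    geosphere,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
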