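Package: mitovar
Title: Contamination-Aware Mitochondrial Variant Calling and Mitotype Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for organellar population genomics from per-site
    read-composition tables: depth-class filtering of plastid (cpDNA) and
    nuclear-insertion (NUMT) contamination, consensus calling with a strict
    80 percent rule, reference refinement, SNP-site extraction across
    accessions, Bray-Curtis/UPGMA clustering, principal component analysis,
    neighbor-joining phylogeny with bootstrap supports, screening of
    assembled contigs for cytoplasmic-male-sterility-associated genes, and
    geographic association testing with a log-space Fisher exact test.
    Includes a synthetic-cohort generator emulating the three read-depth
    classes typical of plant mitochondrial resequencing so every stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    phangorn,
    testthat (>= 3.0.0),
    vcfR,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
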