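Package: orthomapr
Title: Orthology-Based Functional Annotation with Gene-Tree Aware
    Transfer and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Functional annotation of protein sequences by orthology
    assignment against a precomputed orthologous-group database. Each
    query is mapped to a best-matching seed ortholog, fine-grained
    orthologs are extracted from precomputed gene trees using
    species-overlap speciation/duplication labelling with in-paralog
    exclusion, and Gene Ontology terms, KEGG pathways, COG categories
    and gene names are transferred from orthologs within an
    automatically resolved taxonomic scope. Includes a GO DAG parser
    with ancestor propagation and taxon-constraint checking, parsers
    for HMMER domtblout and BLAST/DIAMOND tabular search output, a
    built-in Smith-Waterman search backend, an evaluation framework
    (true/false-positive term classification against evidence-coded
    gold standards, per-proteome coverage categories, CAFA-style F-max,
    metagenomic functional-profile correlation), and a fully seeded
    synthetic-database simulator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
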