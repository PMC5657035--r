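Package: gtasm
Title: Gene-Targeted Metagenomic Assembly with HMM-Guided de Bruijn Graph Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles targeted gene families from shotgun metagenomic reads by
    combining an exact, multiplicity-aware de Bruijn graph with a profile hidden
    Markov model of the gene family. The two structures form a combined weighted
    assembly graph whose highest-scoring path is found by A* search; a
    low-coverage penalty down-weights k-mers observed only once, and an
    iterative multi-k graph construction bridges coverage gaps by feeding
    contigs assembled at smaller k back into graphs at larger k. Includes a
    HMMER3 ASCII model reader/writer, profile-HMM construction from aligned
    FASTA, graph cleaning (tip removal, bubble merging), unitig spelling,
    length/identity post-processing of contigs, and a synthetic gene-family
    read simulator for offline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
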