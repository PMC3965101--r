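Package: prokann
Title: Subsystem-Driven Annotation of Prokaryotic, Phage and Plasmid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained annotation pipeline for prokaryotic, phage and
    plasmid genome assemblies. Protein function is assigned by scanning
    candidate gene products for signature amino-acid 8-mers built from a
    role-annotated reference protein collection; gene calling uses an
    iteratively retrained 3-periodic Markov model; remaining candidates are
    rescued by exact local protein alignment against the closest reference
    genomes, long gene-free stretches are backfilled by translated search,
    sequencing frameshifts are detected and optionally repaired by joining
    gene fragments against template proteins, and gene context is used to
    re-annotate genes flanked by conserved neighbors. Annotated genomes are
    projected onto subsystems (curated sets of functional roles) with variant
    estimation, and functional coupling is estimated from pairs of close
    bidirectional best hits. A synthetic-genome generator with exact truth
    tables makes every stage testable without external databases. Exports
    GFF3, GenBank, FASTA and tab-delimited formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
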