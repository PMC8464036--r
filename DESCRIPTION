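Package: txannot
Title: De Novo Transcriptome Characterization: Taxonomy, ORFs, Gene
    Families, Completeness and Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation engine for assembled transcriptomes. Provides
    protein-level taxonomic classification of transcripts by maximal
    exact amino-acid matches with lowest-common-ancestor resolution
    (including merging of split-index results and parsing of Kaiju
    output), homology-guided open reading frame prediction under any
    NCBI genetic code with putative frameshift detection and
    full-length meta-annotation, gene-family assignment from translated
    similarity searches with majority-vote functional transfer,
    non-coding RNA assignment from Infernal results with GO transfer,
    weighted core gene-family completeness scoring for arbitrary
    clades, and hypergeometric subset enrichment with
    Benjamini-Hochberg correction. Ships a deterministic synthetic
    fixture generator so every stage is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
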