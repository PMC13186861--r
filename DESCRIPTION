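Package: IsoScope
Title: Targeted Long-Read Splice Variant Discovery, Quantification and
    Coding-Potential Characterization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes the transcriptional landscape of a single gene
    from targeted long-read amplicon sequencing. Collapses spliced genomic
    alignments into transcript models by intron chain, classifies exons and
    splicing events (cassette exons, intron retention, alternative
    donor/acceptor sites, cryptic exons), quantifies each model per library
    in transcripts per million using only full-length reads, predicts
    ATG-anchored open reading frames with nonsense-mediated decay
    classification by the 50-nt rule, and calls conserved protein-domain
    retention by alignment to the canonical protein. Includes a seeded
    simulator of spliced amplicon alignments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Transcriptomics, AlternativeSplicing, LongRead, Sequencing,
    GenomeAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
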