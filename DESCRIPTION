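Package: tefseq
Title: Strand-Specific Nascent Transcription Profiling of Elongation Factor
    Occupancy (TEF-seq/NET-seq)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for TEF-seq and NET-seq data in budding yeast:
    strand-specific single-nucleotide 3'-end coverage from aligned reads,
    subtraction of non-tag-specific background calibrated on a Pol3-transcribed
    control gene, anchor-aligned metagene profiles with trimmed means
    (standard, Pol2-normalized and nucleosome-phased), negative-binomial
    differential elongation-factor-versus-polymerase occupancy with
    Benjamini-Hochberg correction, permutation enrichment of divergent
    promoter pairs, and a synthetic-data generator with ground-truth tables
    that makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
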