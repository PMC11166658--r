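Package: cpgmutspec
Title: CpG-Centric Mutation Spectrum and Enrichment Analysis for Clonal Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification filters for de novo single-nucleotide variants in
    clonally derived genomes (such as induced pluripotent stem cell lines),
    strand-collapsed 24-category mutation-spectrum statistics normalized by
    genomic dinucleotide abundance, CpG versus non-CpG C>T partition and
    correlation analysis, shared-variant detection across sister clones,
    regional enrichment statistics (retrotransposon classes and Alu
    subfamilies, CpG islands and shores, differentially methylated regions,
    distance to transcription start sites), codon-level consequence
    annotation of CpG C>T transitions, and a fully seeded synthetic-data
    generator (genome, annotation tracks, mutations, clone families with
    read-level metric noise) that gives every statistic a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
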