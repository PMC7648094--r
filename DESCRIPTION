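Package: SalivaDecoy
Title: Detection and Mitigation of Microbial Contamination Artifacts in
    Saliva-Derived Human Genome Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Saliva-derived DNA used for human whole-genome sequencing is
    frequently contaminated with oral-microbiome DNA. Short bacterial reads
    can align to the human reference through chance 19-25 bp identity cores,
    producing overlapping "atypical" read pairs with long soft-clipped flanks
    and template spans of at most 30 bp, which in turn distort genotype calls
    (typically turning homozygous-alternate loci heterozygous). SalivaDecoy
    identifies and optionally filters or annotates such atypical read pairs in
    SAM/BAM alignments, profiles their taxonomic origin from BLAST tabular
    output, selects decoy genera and species by frequency thresholds, builds a
    masked bacterial decoy contig (1000-N spacers; masking of human-similar,
    polynucleotide-repeat and internally duplicated regions), and quantifies
    the decoy's impact on alignment statistics and variant genotypes from
    pre/post VCF pairs. A seeded simulator generates reference sequences,
    alignments with planted atypical pairs, BLAST tables and VCF pairs with
    full truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Alignment, SequenceMatching, QualityControl, Microbiome,
    VariantDetection, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
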