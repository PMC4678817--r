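Package: hiddensplice
Title: Discovery of Hidden Personal-Specific Splice Junctions from
    Personal Genome RNA-Seq Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies 'hidden' splice junctions created by single
    nucleotide polymorphisms at splice-site dinucleotides.  Builds two
    haplotype-resolved personal genomes from a phased VCF, extracts
    splice junctions from spliced alignments against the reference and
    both haplotype genomes, classifies junctions as personal-specific
    (hap1, hap2 or hap1hap2) or reference-specific, annotates the
    splice-site SNP responsible, quantifies relative junction usage
    against overlapping annotated junctions, scores splice-site strength
    with maximum-entropy models, and links splice-site SNPs to GWAS
    catalog variants through haplotype linkage-disequilibrium r2.  A
    deterministic simulator with an exact-match spliced toy aligner
    provides fully self-contained end-to-end test scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    GenomicFeatures,
    IRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
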