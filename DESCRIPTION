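Package: HapDip
Title: Heterozygosity and Haplotype Diagnostics for Highly Heterozygous
    Diploid Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for diploid genomes with very
    high heterozygosity, where the two haplotypes of many regions assemble
    independently. Provides a ground-truthed diploid genome, read,
    transcript and long-fragment simulator; k-mer spectrum construction
    with error/heterozygous/homozygous peak detection, genome-size
    estimation, cross-library k-mer intersection and de Bruijn branch
    classification; allelic-contig (haplotig) detection and collapse with
    primary/secondary partitioning and assembly summary statistics;
    per-gene heterozygosity and laboratory-population variance calling via
    transcript-guided two-locus analysis and read pileups; pairwise overlap
    SNP/indel accounting for BAC-like long fragments; and splice-isoform
    combinatorics for hypervariable mutually exclusive exon arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
SystemRequirements: minimap2, samtools
biocViews: Software, Genetics, Sequencing, Alignment, Coverage,
    SNP, GenomeAssembly
Config/testthat/edition: 3
RoxygenNote: 7.3.3
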