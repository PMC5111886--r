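#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement writeXStringSet
#'   readDNAStringSet pairwiseAlignment nucleotideSubstitutionMatrix GENETIC_CODE
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats rbinom rnorm runif setNames quantile sd
#' @importFrom utils head tail write.table read.table
#' @useDynLib HapDip, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom data.table data.table as.data.table setorderv :=
NULL

.datatable.aware <- TRUE

#' Simulation configuration for a ground-truthed diploid genome
#'
#' Holds every tunable of the simulator: haplotype divergence (SNP and
#' small/large indel rates), interspersed repeat content, gene models,
#' paired-end read generation, transcript-level population variants and
#' BAC-like long-fragment tiling.  Defaults describe a highly heterozygous
#' diploid in the regime the package targets: per-base SNP heterozygosity
#' 2.5\%, 75-fold read coverage per haplotype with 150 nt paired reads, a
#' laboratory-population variant rate of 0.8\% of transcribed bases, and
#' interspersed repeat families at 3\% internal divergence.
#'
#' @slot haploid_length total haploid genome length in bases
#' @slot n_sequences number of chromosomes/sequences the haploid length is
#'   split into
#' @slot snp_rate genome-wide mean per-base SNP heterozygosity between the
#'   two haplotypes
#' @slot het_block_len length of the blocks over which the local SNP rate
#'   varies (the heterozygosity mosaic)
#' @slot het_cv coefficient of variation of the per-block SNP-rate
#'   multipliers (lognormal, normalized to genome-wide mean 1); 0 gives a
#'   uniform rate
#' @slot small_indel_rate per-base rate of 1-20 bp haplotype indels
#' @slot small_indel_len_dist probability weights for indel lengths 1-20
#' @slot large_indel_rate per-base rate of large (polynucleotide) indels
#' @slot large_indel_min_len minimum large-indel length (default 100 bp)
#' @slot large_indel_mean_extra mean geometric excess over the minimum
#' @slot repeat_fraction target fraction of the haploid genome covered by
#'   interspersed repeats
#' @slot repeat_unit_len length of one repeat unit in bases
#' @slot n_repeat_families number of distinct repeat families
#' @slot repeat_divergence per-base substitution divergence of each planted
#'   copy from its family consensus
#' @slot n_genes number of gene models to place
#' @slot exons_per_gene_range min/max exon count per gene
#' @slot exon_len_range min/max exon length (bases)
#' @slot intron_len_range min/max intron length (bases)
#' @slot read_len read length in bases
#' @slot fragment_mean,fragment_sd insert-size distribution of read pairs
#' @slot coverage_per_haplotype fold sequencing depth generated from each
#'   haplotype
#' @slot seq_error_rate per-base substitution sequencing error rate
#' @slot population_variant_rate per-transcribed-base rate of extra
#'   (population-level) variants planted on transcripts
#' @slot n_fragments number of BAC-like fragments in the tiling path
#' @slot fragment_len length of each BAC-like fragment
#' @slot fragment_overlap ancestral overlap between consecutive fragments
#' @slot seed integer seed; identical configurations give bit-identical
#'   outputs
#' @export
setClass("SimConfig", representation(
    haploid_length = "numeric",
    n_sequences = "numeric",
    snp_rate = "numeric",
    het_block_len = "numeric",
    het_cv = "numeric",
    small_indel_rate = "numeric",
    small_indel_len_dist = "numeric",
    large_indel_rate = "numeric",
    large_indel_min_len = "numeric",
    large_indel_mean_extra = "numeric",
    repeat_fraction = "numeric",
    repeat_unit_len = "numeric",
    n_repeat_families = "numeric",
    repeat_divergence = "numeric",
    n_genes = "numeric",
    exons_per_gene_range = "numeric",
    exon_len_range = "numeric",
    intron_len_range = "numeric",
    read_len = "numeric",
    fragment_mean = "numeric",
    fragment_sd = "numeric",
    coverage_per_haplotype = "numeric",
    seq_error_rate = "numeric",
    population_variant_rate = "numeric",
    n_fragments = "numeric",
    fragment_len = "numeric",
    fragment_overlap = "numeric",
    seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    rates <- c(snp_rate = object@snp_rate,
               small_indel_rate = object@small_indel_rate,
               large_indel_rate = object@large_indel_rate,
               seq_error_rate = object@seq_error_rate,
               population_variant_rate = object@population_variant_rate,
               repeat_divergence = object@repeat_divergence)
    bad <- rates < 0 | rates > 1
    if (any(bad))
        msg <- c(msg, paste("rates must lie in [0,1]:",
                            paste(names(rates)[bad], collapse = ", ")))
    if (object@repeat_fraction < 0 || object@repeat_fraction >= 1)
        msg <- c(msg, "repeat_fraction must lie in [0,1)")
    if (object@fragment_overlap >= object@fragment_len)
        msg <- c(msg, "fragment_overlap must be smaller than fragment_len")
    if (object@haploid_length < 1 || object@n_sequences < 1)
        msg <- c(msg, "haploid_length and n_sequences must be positive")
    if (length(object@small_indel_len_dist) != 20 ||
        any(object@small_indel_len_dist < 0))
        msg <- c(msg, "small_indel_len_dist must be 20 non-negative weights")
    if (object@read_len < 1)
        msg <- c(msg, "read_len must be positive")
    if (length(msg)) msg else TRUE
})

#' A simulated diploid genome with complete ground truth
#'
#' Haplotype A is the reference haplotype; haplotype B is obtained by
#' applying the planted variant table to haplotype A, so
#' \code{applyVariants(hapA(x), plantedVariants(x))} reconstructs
#' \code{hapB(x)} exactly.
#'
#' @slot hapA,hapB named \code{DNAStringSet}s, one entry per sequence
#' @slot variants \code{data.frame} with columns seqid, pos (1-based on
#'   haplotype A; insertions occur after pos), type (snp/ins/del), ref, alt
#' @slot repeats \code{GRanges} of planted repeat copies on haplotype A with
#'   a \code{family} metadata column
#' @slot genes \code{GRanges} of exons on haplotype A with \code{gene_id}
#'   and \code{exon_rank} metadata columns; strand is the gene strand
#' @export
setClass("DiploidGenome", representation(
    hapA = "DNAStringSet",
    hapB = "DNAStringSet",
    variants = "data.frame",
    repeats = "GRanges",
    genes = "GRanges"))

setValidity("DiploidGenome", function(object) {
    msg <- character()
    if (!identical(names(object@hapA), names(object@hapB)))
        msg <- c(msg, "hapA and hapB must carry identical sequence names")
    v <- object@variants
    need <- c("seqid", "pos", "type", "ref", "alt")
    if (!all(need %in% names(v)))
        msg <- c(msg, "variants must have columns seqid, pos, type, ref, alt")
    else {
        if (!all(v$type %in% c("snp", "ins", "del")))
            msg <- c(msg, "variant type must be snp, ins or del")
        if (nrow(v) && any(unlist(tapply(v$pos, v$seqid, function(p) diff(p) <= 0))))
            msg <- c(msg, "variant positions must be strictly increasing per sequence")
    }
    if (length(msg)) msg else TRUE
})

#' Simulated paired-end reads with origin truth
#'
#' @slot reads1,reads2 mate 1 / mate 2 sequences (\code{DNAStringSet})
#' @slot truth \code{data.frame}: id, hap ("A"/"B"), seqid, frag_start,
#'   frag_end (1-based on the source haplotype), plus read length
#' @slot read_len uniform read length
#' @export
setClass("ReadSet", representation(
    reads1 = "DNAStringSet",
    reads2 = "DNAStringSet",
    truth = "data.frame",
    read_len = "numeric"))

setValidity("ReadSet", function(object) {
    msg <- character()
    if (length(object@reads1) != length(object@reads2))
        msg <- c(msg, "mate sets must have equal length")
    w <- unique(c(Biostrings::width(object@reads1),
                  Biostrings::width(object@reads2)))
    if (length(w) > 1 || (length(w) == 1 && w != object@read_len))
        msg <- c(msg, "all reads must have length read_len")
    if (length(msg)) msg else TRUE
})

#' BAC-like long fragments tiling a genomic region
#'
#' Each fragment derives from exactly one haplotype; consecutive fragments
#' share a declared ancestral overlap.  Truth coordinates (\code{startA},
#' \code{endA}) are on haplotype A regardless of the source haplotype.
#'
#' @slot sequences fragment sequences (\code{DNAStringSet})
#' @slot truth per-fragment \code{data.frame}: id, hap, seqid, startA, endA
#' @slot overlaps declared-overlap \code{data.frame}: id1, id2, startA,
#'   endA, n_snp, n_indel, n_indel_large (planted differences inside the
#'   overlap when the two fragments come from different haplotypes)
#' @export
setClass("FragmentSet", representation(
    sequences = "DNAStringSet",
    truth = "data.frame",
    overlaps = "data.frame"))

#' K-mer multiplicity spectrum
#'
#' @slot k odd k-mer size in 15..63
#' @slot histogram \code{data.frame} mapping multiplicity to the number of
#'   distinct canonical k-mers observed at that multiplicity
#' @slot total_kmers total k-mer occurrences,
#'   \eqn{\sum multiplicity \times count}
#' @export
setClass("KmerSpectrum", representation(
    k = "numeric",
    histogram = "data.frame",
    total_kmers = "numeric"))

setValidity("KmerSpectrum", function(object) {
    msg <- character()
    if (object@k %% 2 == 0 || object@k < 15 || object@k > 63)
        msg <- c(msg, "k must be odd and within 15..63")
    h <- object@histogram
    if (!all(c("multiplicity", "count") %in% names(h)))
        msg <- c(msg, "histogram needs columns multiplicity and count")
    else {
        if (any(h$count < 0)) msg <- c(msg, "histogram counts must be >= 0")
        tot <- sum(as.numeric(h$multiplicity) * as.numeric(h$count))
        if (nrow(h) && abs(tot - object@total_kmers) > 0.5)
            msg <- c(msg, "total_kmers must equal sum(multiplicity * count)")
    }
    if (length(msg)) msg else TRUE
})

#' Detected peaks of a k-mer spectrum
#'
#' @slot error_cutoff multiplicity of the first local minimum separating
#'   sequencing-error k-mers from genomic k-mers
#' @slot het_peak multiplicity of the heterozygous (one-haplotype) peak;
#'   \code{NA} when the spectrum is unimodal
#' @slot hom_peak multiplicity of the homozygous (two-haplotype) peak
#' @slot peak_ratio het_peak / hom_peak (about 0.5 for a diploid)
#' @export
setClass("SpectrumPeaks", representation(
    error_cutoff = "numeric",
    het_peak = "numeric",
    hom_peak = "numeric",
    peak_ratio = "numeric"))

setValidity("SpectrumPeaks", function(object) {
    msg <- character()
    if (!is.na(object@het_peak)) {
        if (!(object@error_cutoff < object@het_peak &&
              object@het_peak < object@hom_peak))
            msg <- c(msg, "need error_cutoff < het_peak < hom_peak")
        if (!(object@peak_ratio > 0 && object@peak_ratio < 1))
            msg <- c(msg, "peak_ratio must lie in (0,1)")
    }
    if (length(msg)) msg else TRUE
})

#' de Bruijn branch statistics of a read set
#'
#' @slot sampled_kmers number of distinct above-error k-mers examined
#' @slot variant_branch_rate variant (haplotype-difference) branches per
#'   sampled k-mer; \code{NA} when no heterozygous peak was available
#' @slot repeat_branch_rate repeat branches per sampled k-mer
#' @slot het_available whether a heterozygous peak was available, enabling
#'   variant classification
#' @export
setClass("BranchStats", representation(
    sampled_kmers = "numeric",
    variant_branch_rate = "numeric",
    repeat_branch_rate = "numeric",
    het_available = "logical"))

setValidity("BranchStats", function(object) {
    msg <- character()
    r <- c(object@variant_branch_rate, object@repeat_branch_rate)
    r <- r[!is.na(r)]
    if (any(r < 0) || any(r > 2))
        msg <- c(msg, "branch rates must lie in [0,2] (two strands)")
    if (length(msg)) msg else TRUE
})

#' Primary/secondary partition of an assembly after allelic collapse
#'
#' @slot primary ids of primary contigs (kept for scaffolding)
#' @slot secondary ids of secondary (heterozygous/allelic) contigs
#' @slot mapping \code{data.frame} with columns secondary, primary
#' @slot lengths named contig lengths of the full input set
#' @slot params list of thresholds used
#' @export
setClass("CollapseResult", representation(
    primary = "character",
    secondary = "character",
    mapping = "data.frame",
    lengths = "numeric",
    params = "list"))

setValidity("CollapseResult", function(object) {
    msg <- character()
    if (length(intersect(object@primary, object@secondary)))
        msg <- c(msg, "primary and secondary sets must be disjoint")
    if (!setequal(c(object@primary, object@secondary), names(object@lengths)))
        msg <- c(msg, "primary + secondary must partition the input contig set")
    m <- object@mapping
    if (nrow(m)) {
        if (!all(m$secondary %in% object@secondary) ||
            !all(m$primary %in% object@primary))
            msg <- c(msg, "mapping must link secondary ids to primary ids")
        else if (any(object@lengths[m$primary] < object@lengths[m$secondary]))
            msg <- c(msg, "each primary must be at least as long as its secondary")
    }
    if (length(msg)) msg else TRUE
})

#' Pairwise-overlap polymorphism report for two long fragments
#'
#' Counts SNP and indel differences between the overlapping regions of two
#' BAC-like fragments, cross-checked against read pileups on each fragment.
#'
#' @slot pair_id label of the fragment pair
#' @slot overlap_length aligned overlap length in bases
#' @slot identity percent identity of the overlap alignment (gaps count as
#'   mismatch columns)
#' @slot snps_pairwise SNP columns in the pairwise alignment
#' @slot snps_read_supported heterozygous sites called from read pileups
#'   inside the overlap
#' @slot snps_both_supported pairwise SNPs also called from reads
#' @slot third_allele_sites sites where reads show an allele carried by
#'   neither fragment
#' @slot indels \code{data.frame} of indel events: pos1, pos2, length, type
#' @slot n_indels_large number of indels >= large threshold (default 100 bp)
#' @slot large_threshold the threshold used
#' @export
setClass("OverlapReport", representation(
    pair_id = "character",
    overlap_length = "numeric",
    identity = "numeric",
    snps_pairwise = "numeric",
    snps_read_supported = "numeric",
    snps_both_supported = "numeric",
    third_allele_sites = "numeric",
    indels = "data.frame",
    n_indels_large = "numeric",
    large_threshold = "numeric"))

setValidity("OverlapReport", function(object) {
    msg <- character()
    if (!is.na(object@snps_both_supported) &&
        object@snps_both_supported >
        min(object@snps_pairwise, object@snps_read_supported))
        msg <- c(msg, "both-supported SNPs cannot exceed either source count")
    if (object@n_indels_large > nrow(object@indels))
        msg <- c(msg, "large indels must be a subset of all indels")
    if (length(msg)) msg else TRUE
})
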