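#' @rdname DiploidGenome-class
#' @param x a \code{DiploidGenome}
#' @export
setGeneric("hapA", function(x) standardGeneric("hapA"))
#' @rdname DiploidGenome-class
#' @export
setGeneric("hapB", function(x) standardGeneric("hapB"))
#' @rdname DiploidGenome-class
#' @export
setGeneric("plantedVariants", function(x) standardGeneric("plantedVariants"))
#' @rdname DiploidGenome-class
#' @export
setGeneric("plantedRepeats", function(x) standardGeneric("plantedRepeats"))
#' @rdname DiploidGenome-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname ReadSet-class
#' @param x a \code{ReadSet}
#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))

#' @rdname FragmentSet-class
#' @param x a \code{FragmentSet}
#' @export
setGeneric("fragmentSeqs", function(x) standardGeneric("fragmentSeqs"))
#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentTruth", function(x) standardGeneric("fragmentTruth"))
#' @rdname FragmentSet-class
#' @export
setGeneric("declaredOverlaps", function(x) standardGeneric("declaredOverlaps"))

#' @rdname KmerSpectrum-class
#' @param x a \code{KmerSpectrum}
#' @export
setGeneric("spectrumHistogram", function(x) standardGeneric("spectrumHistogram"))
#' @rdname KmerSpectrum-class
#' @export
setGeneric("totalKmers", function(x) standardGeneric("totalKmers"))

#' @rdname SpectrumPeaks-class
#' @param x a \code{SpectrumPeaks}
#' @export
setGeneric("errorCutoff", function(x) standardGeneric("errorCutoff"))
#' @rdname SpectrumPeaks-class
#' @export
setGeneric("hetPeak", function(x) standardGeneric("hetPeak"))
#' @rdname SpectrumPeaks-class
#' @export
setGeneric("homPeak", function(x) standardGeneric("homPeak"))
#' @rdname SpectrumPeaks-class
#' @export
setGeneric("peakRatio", function(x) standardGeneric("peakRatio"))

#' @rdname CollapseResult-class
#' @param x a \code{CollapseResult}
#' @export
setGeneric("primaryContigs", function(x) standardGeneric("primaryContigs"))
#' @rdname CollapseResult-class
#' @export
setGeneric("secondaryContigs", function(x) standardGeneric("secondaryContigs"))
#' @rdname CollapseResult-class
#' @export
setGeneric("allelicMap", function(x) standardGeneric("allelicMap"))

setMethod("hapA", "DiploidGenome", function(x) x@hapA)
setMethod("hapB", "DiploidGenome", function(x) x@hapB)
setMethod("plantedVariants", "DiploidGenome", function(x) x@variants)
setMethod("plantedRepeats", "DiploidGenome", function(x) x@repeats)
setMethod("geneModels", "DiploidGenome", function(x) x@genes)

setMethod("readTruth", "ReadSet", function(x) x@truth)

setMethod("fragmentSeqs", "FragmentSet", function(x) x@sequences)
setMethod("fragmentTruth", "FragmentSet", function(x) x@truth)
setMethod("declaredOverlaps", "FragmentSet", function(x) x@overlaps)

setMethod("spectrumHistogram", "KmerSpectrum", function(x) x@histogram)
setMethod("totalKmers", "KmerSpectrum", function(x) x@total_kmers)

setMethod("errorCutoff", "SpectrumPeaks", function(x) x@error_cutoff)
setMethod("hetPeak", "SpectrumPeaks", function(x) x@het_peak)
setMethod("homPeak", "SpectrumPeaks", function(x) x@hom_peak)
setMethod("peakRatio", "SpectrumPeaks", function(x) x@peak_ratio)

setMethod("primaryContigs", "CollapseResult", function(x) x@primary)
setMethod("secondaryContigs", "CollapseResult", function(x) x@secondary)
setMethod("allelicMap", "CollapseResult", function(x) x@mapping)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", format(object@haploid_length, big.mark = ","),
        "bp haploid /", object@n_sequences, "sequence(s)\n")
    cat("  SNP rate", object@snp_rate,
        "| small indel", object@small_indel_rate,
        "| large indel", object@large_indel_rate,
        paste0("(>=", object@large_indel_min_len, " bp)\n"))
    cat("  repeats", object@repeat_fraction, "of genome in",
        object@n_repeat_families, "families | genes", object@n_genes, "\n")
    cat("  reads", object@read_len, "nt paired,",
        object@coverage_per_haplotype, "x per haplotype, error",
        object@seq_error_rate, "\n")
    cat("  transcripts: population variant rate",
        object@population_variant_rate, "\n")
    cat("  fragments:", object@n_fragments, "x",
        object@fragment_len, "bp, overlap", object@fragment_overlap,
        "| seed", object@seed, "\n")
})

setMethod("show", "DiploidGenome", function(object) {
    cat("DiploidGenome:", length(object@hapA), "sequence(s),",
        format(sum(Biostrings::width(object@hapA)), big.mark = ","),
        "bp haploid (A)\n")
    tt <- table(factor(object@variants$type, c("snp", "ins", "del")))
    cat("  planted variants:", tt[["snp"]], "SNPs,", tt[["ins"]], "ins,",
        tt[["del"]], "del\n")
    cat("  repeats:", length(object@repeats), "copies |",
        length(unique(object@genes$gene_id)), "gene model(s)\n")
})

setMethod("show", "ReadSet", function(object) {
    cat("ReadSet:", length(object@reads1), "pairs of", object@read_len,
        "nt reads\n")
})

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet:", length(object@sequences), "fragment(s),",
        nrow(object@overlaps), "declared overlap(s)\n")
})

setMethod("show", "KmerSpectrum", function(object) {
    cat("KmerSpectrum: k =", object@k, "|",
        format(object@total_kmers, big.mark = ","), "k-mer occurrences,",
        format(sum(object@histogram$count), big.mark = ","), "distinct\n")
})

setMethod("show", "SpectrumPeaks", function(object) {
    cat("SpectrumPeaks: error cutoff", object@error_cutoff,
        "| het", object@het_peak, "| hom", object@hom_peak,
        "| ratio", round(object@peak_ratio, 3), "\n")
})

setMethod("show", "BranchStats", function(object) {
    cat("BranchStats:", format(object@sampled_kmers, big.mark = ","),
        "k-mers sampled | variant rate",
        signif(object@variant_branch_rate, 3), "| repeat rate",
        signif(object@repeat_branch_rate, 3), "\n")
})

setMethod("show", "CollapseResult", function(object) {
    cat("CollapseResult:", length(object@primary), "primary /",
        length(object@secondary), "secondary contig(s)\n")
    cat("  thresholds: identity >", object@params$min_identity,
        ", overlap >", object@params$min_overlap, "\n")
})

setMethod("show", "OverlapReport", function(object) {
    cat("OverlapReport", object@pair_id, ":", object@overlap_length,
        "bp overlap,", round(object@identity, 2), "% identity\n")
    cat("  SNPs pairwise/read/both:", object@snps_pairwise, "/",
        object@snps_read_supported, "/", object@snps_both_supported,
        "| third allele:", object@third_allele_sites, "\n")
    cat("  indels:", nrow(object@indels), paste0("(>=",
        object@large_threshold, " bp: "), object@n_indels_large, ")\n")
})
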