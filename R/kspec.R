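## K-mer spectrum diagnostics: spectrum construction, error/het/hom peak
## detection, genome-size estimation, cross-library intersection and de
## Bruijn branch classification.

## Coerce reads input (ReadSet, DNAStringSet, character, FASTQ path(s)) to
## a character vector of sequences.
.asSeqChar <- function(reads) {
    if (is(reads, "ReadSet"))
        return(c(as.character(reads@reads1), as.character(reads@reads2)))
    if (is(reads, "XStringSet"))
        return(as.character(reads))
    if (is.character(reads) && length(reads) &&
        all(file.exists(reads))) {
        out <- lapply(reads, function(f)
            as.character(Biostrings::readDNAStringSet(f, format = "fastq")))
        return(unlist(out, use.names = FALSE))
    }
    as.character(reads)
}

#' Build a canonical k-mer multiplicity spectrum
#'
#' Counts canonical k-mers (the lexicographic minimum of each k-mer and
#' its reverse complement) across a read set and tabulates how many
#' distinct k-mers occur at each multiplicity.  For a diploid read set the
#' spectrum of error-free k-mers is bimodal: a peak at the per-haplotype
#' depth (k-mers on one haplotype, i.e. heterozygous regions) and a peak
#' at twice that depth (k-mers shared by both haplotypes).
#'
#' @param reads a [ReadSet-class], \code{DNAStringSet}, character vector of
#'   sequences, or FASTQ path(s)
#' @param k odd k-mer size in 15..63 (default 31)
#' @return a [KmerSpectrum-class]
#' @examples
#' sp <- buildSpectrum(c("ACGTACGTACGTACGTACG"), k = 15)
#' spectrumHistogram(sp)
#' @export
buildSpectrum <- function(reads, k = 31) {
    if (k %% 2 == 0 || k < 15 || k > 63)
        stop("k must be odd and within 15..63")
    seqs <- .asSeqChar(reads)
    if (!length(seqs))
        stop("empty read set")
    h <- .cpp_kmer_histogram(seqs, as.integer(k))
    new("KmerSpectrum", k = k, histogram = h,
        total_kmers = sum(as.numeric(h$multiplicity) * as.numeric(h$count)))
}

## Moving-average smoothing of the dense (zero-filled) histogram.
.smoothHist <- function(hist, window = 3) {
    maxm <- max(hist$multiplicity)
    dense <- numeric(maxm)
    dense[hist$multiplicity] <- hist$count
    if (window > 1) {
        kern <- rep(1 / window, window)
        sm <- stats::filter(dense, kern, sides = 2)
        sm[is.na(sm)] <- dense[is.na(sm)]
        as.numeric(sm)
    } else dense
}

#' Detect error, heterozygous and homozygous peaks of a k-mer spectrum
#'
#' The error cutoff is the first local minimum of the smoothed histogram
#' (sequencing-error k-mers decay from multiplicity 1; genomic k-mers rise
#' towards the coverage peaks).  Above the cutoff, the two highest local
#' maxima separated by at least \code{min_sep}-fold in multiplicity are
#' reported; the larger-multiplicity one is the homozygous peak.  A
#' unimodal spectrum yields a missing heterozygous peak (\code{NA}).
#'
#' @param spectrum a [KmerSpectrum-class]
#' @param window moving-average window (multiplicity bins)
#' @param min_sep minimum multiplicity ratio between the two peaks
#' @param min_peak_frac minimum height of the secondary peak relative to
#'   the highest peak; smaller bumps (e.g. repeat-multiplicity shoulders)
#'   are not treated as a heterozygous/homozygous peak pair
#' @return a [SpectrumPeaks-class]
#' @export
detectPeaks <- function(spectrum, window = 3, min_sep = 1.5,
                        min_peak_frac = 0.15) {
    h <- spectrum@histogram
    if (nrow(h) < 3)
        stop("spectrum too degenerate for peak detection")
    sm <- .smoothHist(h, window)
    n <- length(sm)
    if (n < 5)
        stop("spectrum too degenerate for peak detection")
    ## first local minimum scanning from multiplicity 1
    cutoff <- NA_integer_
    for (i in 2:(n - 1)) {
        if (sm[i] <= sm[i - 1] && sm[i] < sm[i + 1]) {
            cutoff <- i
            break
        }
        if (sm[i] > sm[i - 1]) break  # rising from the start: no error tail
    }
    if (is.na(cutoff)) {
        if (sm[1] < sm[2]) cutoff <- 1L
        else stop("no error/genomic minimum found: spectrum looks like pure ",
                  "noise (monotone decay)")
    }
    idx <- seq(cutoff + 1L, n)
    is_max <- vapply(idx, function(i) {
        l <- if (i == 1L) -Inf else sm[i - 1]
        r <- if (i == n) -Inf else sm[i + 1]
        sm[i] > 0 && sm[i] >= l && sm[i] > r
    }, TRUE)
    cand <- idx[is_max]
    if (!length(cand))
        stop("no peaks above the error cutoff")
    cand <- cand[order(sm[cand], decreasing = TRUE)]
    p1 <- cand[1]
    p2 <- NA_integer_
    for (p in cand[-1]) {
        if (max(p, p1) / min(p, p1) >= min_sep &&
            sm[p] >= min_peak_frac * sm[p1]) {
            p2 <- p
            break
        }
    }
    if (is.na(p2)) {
        new("SpectrumPeaks", error_cutoff = as.numeric(cutoff),
            het_peak = NA_real_, hom_peak = as.numeric(p1),
            peak_ratio = NA_real_)
    } else {
        hom <- max(p1, p2); het <- min(p1, p2)
        new("SpectrumPeaks", error_cutoff = as.numeric(cutoff),
            het_peak = as.numeric(het), hom_peak = as.numeric(hom),
            peak_ratio = het / hom)
    }
}

#' Estimate haploid genome size from a k-mer spectrum
#'
#' The total k-mer mass above the error cutoff (\eqn{\sum m \cdot c_m})
#' equals haploid length times the homozygous-peak depth, irrespective of
#' heterozygosity or repeat content, so the estimate is mass divided by
#' the homozygous peak.
#'
#' @param spectrum a [KmerSpectrum-class]
#' @param peaks a [SpectrumPeaks-class] for the same spectrum
#' @return estimated haploid genome length in bases
#' @export
estimateGenomeSize <- function(spectrum, peaks) {
    if (is.na(peaks@hom_peak))
        stop("homozygous peak missing; cannot estimate genome size")
    h <- spectrum@histogram
    keep <- h$multiplicity > peaks@error_cutoff
    mass <- sum(as.numeric(h$multiplicity[keep]) * as.numeric(h$count[keep]))
    mass / peaks@hom_peak
}

#' Fraction of distinct above-error k-mers shared by two read sets
#'
#' Computes \eqn{|A \cap B| / |A \cup B|} over distinct canonical k-mers
#' with multiplicity at or above a per-set error floor.  Two libraries
#' sequenced from the same genome share most of their informational
#' content; the statistic drops towards zero for unrelated genomes.
#'
#' @param reads_a,reads_b the two read sets (any form accepted by
#'   [buildSpectrum()])
#' @param k odd k-mer size
#' @param min_count minimum multiplicity for a k-mer to count as
#'   above-error; \code{NULL} detects each set's error cutoff from its
#'   spectrum (falling back to 2 when no error tail exists)
#' @return list: \code{jaccard}, \code{intersection}, \code{union},
#'   \code{n_a}, \code{n_b}
#' @export
intersectKmers <- function(reads_a, reads_b, k = 31, min_count = NULL) {
    sa <- .asSeqChar(reads_a)
    sb <- .asSeqChar(reads_b)
    if (!length(sa) || !length(sb))
        stop("empty read set")
    if (is.null(min_count)) {
        mc <- vapply(list(sa, sb), function(s) {
            pk <- tryCatch(detectPeaks(buildSpectrum(s, k)),
                           error = function(e) NULL)
            if (is.null(pk)) 2 else pk@error_cutoff + 1
        }, 1)
    } else mc <- rep(min_count, 2L)
    r <- .cpp_kmer_intersect(sa, sb, as.integer(k),
                             as.integer(mc[1]), as.integer(mc[2]))
    list(jaccard = unname(r["intersection"] / r["union"]),
         intersection = unname(r["intersection"]),
         union = unname(r["union"]),
         n_a = unname(r["n_a"]), n_b = unname(r["n_b"]))
}

#' Classify de Bruijn branches into variant and repeat branches
#'
#' Every stored above-error k-mer is probed on both outgoing sides for
#' multiple extensions.  A two-way branch whose extensions both sit at or
#' below \code{var_mult} times the heterozygous peak is a variant branch
#' (a haplotype difference: balanced, one-haplotype coverage); a branch
#' with three or more extensions, or any extension above \code{rep_mult}
#' times the homozygous peak, is a repeat branch (excess copy number).
#' When the spectrum has no heterozygous peak, variant classification is
#' disabled and its rate reported as \code{NA}.
#'
#' @param reads read set (any form accepted by [buildSpectrum()])
#' @param k odd k-mer size
#' @param peaks a [SpectrumPeaks-class] for these reads
#' @param var_mult variant-branch multiplicity ceiling, in units of the
#'   heterozygous peak
#' @param rep_mult repeat-branch multiplicity floor, in units of the
#'   homozygous peak
#' @param max_sample cap on the number of k-mers examined (deterministic
#'   thinning)
#' @return a [BranchStats-class]
#' @export
classifyBranches <- function(reads, k = 31, peaks, var_mult = 1.5,
                             rep_mult = 1.75, max_sample = 2e6) {
    seqs <- .asSeqChar(reads)
    het_ok <- !is.na(peaks@het_peak)
    r <- .cpp_branch_stats(seqs, as.integer(k), peaks@error_cutoff,
                           if (het_ok) peaks@het_peak else 0,
                           peaks@hom_peak, var_mult, rep_mult, max_sample)
    if (!het_ok)
        warning("no heterozygous peak: variant-branch classification disabled")
    new("BranchStats",
        sampled_kmers = r$sampled_kmers,
        variant_branch_rate = if (het_ok) r$variant_branch_rate else NA_real_,
        repeat_branch_rate = r$repeat_branch_rate,
        het_available = het_ok)
}

#' Write spectrum and peak outputs
#'
#' Histogram as two-column TSV (multiplicity, count), peaks and branch
#' statistics as JSON.
#'
#' @param spectrum a [KmerSpectrum-class]
#' @param path output TSV path
#' @return invisibly, \code{path}
#' @export
writeSpectrumTsv <- function(spectrum, path) {
    utils::write.table(spectrum@histogram, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeSpectrumTsv
#' @param peaks a [SpectrumPeaks-class]
#' @export
writePeaksJson <- function(peaks, path) {
    jsonlite::write_json(list(error_cutoff = peaks@error_cutoff,
                              het_peak = peaks@het_peak,
                              hom_peak = peaks@hom_peak,
                              peak_ratio = peaks@peak_ratio),
                         path, auto_unbox = TRUE, na = "null")
    invisible(path)
}
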