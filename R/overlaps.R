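## BAC-style long-fragment analysis: overlap detection between consecutive
## fragments, pairwise-overlap SNP/indel accounting with read support and
## third-allele detection, and per-fragment heterozygosity from pileups.

#' Detect end-to-end overlaps between long fragments
#'
#' For a [FragmentSet-class] with declared truth, returns the declared
#' overlap coordinates converted to fragment-local positions.  For a bare
#' sequence set, candidate ordered pairs are detected by end-free
#' (overlap-type) alignment of the terminal windows of every pair and
#' reported when the aligned block reaches \code{min_len} bases at
#' \code{min_identity} percent identity.
#'
#' @param fragments a [FragmentSet-class] or named \code{DNAStringSet}
#' @param window terminal window searched on each fragment (bases)
#' @param min_len minimum overlap length to report
#' @param min_identity minimum percent identity of the overlap block
#' @return \code{data.frame}: id1, id2, start1, end1, start2, end2
#'   (1-based, local to each fragment), length
#' @export
findFragmentOverlaps <- function(fragments, window = 20000, min_len = 100,
                                 min_identity = 90) {
    if (is(fragments, "FragmentSet"))
        fragments <- fragments@sequences
    seqs <- fragments
    n <- length(seqs)
    out <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        ## does the end of i overlap the start of j?
        li <- Biostrings::width(seqs)[i]
        lj <- Biostrings::width(seqs)[j]
        wi <- min(window, li); wj <- min(window, lj)
        si <- Biostrings::subseq(seqs[[i]], li - wi + 1L, li)
        sj <- Biostrings::subseq(seqs[[j]], 1L, wj)
        aln <- Biostrings::pairwiseAlignment(si, sj, type = "overlap",
            substitutionMatrix =
                Biostrings::nucleotideSubstitutionMatrix(2, -3),
            gapOpening = 10, gapExtension = 1)
        cols <- Biostrings::nchar(aln)
        if (cols < min_len) next
        ident <- 100 * Biostrings::nmatch(aln) / cols
        if (ident < min_identity) next
        rp <- aln@pattern@range
        rs <- aln@subject@range
        ## require terminal placement (suffix of i, prefix of j)
        if (IRanges::start(rs) > 50L || (wi - IRanges::end(rp)) > 50L)
            next
        out[[length(out) + 1L]] <- data.frame(
            id1 = names(seqs)[i], id2 = names(seqs)[j],
            start1 = li - wi + IRanges::start(rp),
            end1 = li - wi + IRanges::end(rp),
            start2 = IRanges::start(rs), end2 = IRanges::end(rs),
            length = cols, stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(id1 = character(), id2 = character(),
                          start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer(),
                          length = integer(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Fragment-local coordinates of declared overlaps
#'
#' Converts the ancestral (haplotype A) overlap coordinates declared by
#' [simulateFragments()] into local positions on each fragment, lifting
#' through the planted variant table for haplotype-B fragments.
#'
#' @param frags a [FragmentSet-class]
#' @param genome the [DiploidGenome-class] the fragments were drawn from
#' @return \code{data.frame}: id1, id2, start1, end1, start2, end2, length
#' @export
declaredOverlapCoords <- function(frags, genome) {
    ov <- frags@overlaps
    tr <- frags@truth
    loc <- function(id, pA) {
        t <- tr[tr$id == id, ]
        if (t$hap == "A")
            as.integer(pA - t$startA + 1L)
        else {
            v <- genome@variants[genome@variants$seqid == t$seqid, ,
                                 drop = FALSE]
            as.integer(liftA2B(pA, v) - liftA2B(t$startA, v) + 1L)
        }
    }
    out <- lapply(seq_len(nrow(ov)), function(i) {
        s1 <- loc(ov$id1[i], ov$startA[i]); e1 <- loc(ov$id1[i], ov$endA[i])
        s2 <- loc(ov$id2[i], ov$startA[i]); e2 <- loc(ov$id2[i], ov$endA[i])
        data.frame(id1 = ov$id1[i], id2 = ov$id2[i],
                   start1 = s1, end1 = e1, start2 = s2, end2 = e2,
                   length = e1 - s1 + 1L, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Analyze one fragment-pair overlap: SNP/indel accounting with read
#' support
#'
#' Globally aligns the two overlap sequences (affine gaps) and counts SNP
#' (mismatch) columns and indel events (gap runs; runs interrupted by up
#' to \code{merge_gap} match columns are \emph{not} merged, so each event
#' keeps its own length).  Each pairwise SNP is cross-checked against the
#' read pileups of both fragments: it is read-supported when both alleles
#' are seen (each on at least \code{min_reads} reads, minor fraction at
#' least \code{min_maf}) on at least one fragment.  Sites where reads
#' reveal an allele carried by neither fragment are tallied as third
#' alleles.  Indels of at least \code{large_threshold} bases are counted
#' separately.
#'
#' @param seq1,seq2 the two fragment sequences (\code{DNAString} or
#'   character)
#' @param coords one row of overlap coordinates (start1, end1, start2,
#'   end2) as from [declaredOverlapCoords()] or [findFragmentOverlaps()]
#' @param bam1,bam2 BAMs of all reads mapped to fragment 1 / fragment 2
#'   individually (may be \code{NULL}: read-dependent counts are
#'   \code{NA})
#' @param id1,id2 fragment names as they appear in the BAMs
#' @param min_depth,min_reads,min_maf pileup thresholds (shared with the
#'   gene-level caller)
#' @param large_threshold large-indel threshold in bases (inclusive)
#' @param pair_id label for the report
#' @return an [OverlapReport-class]
#' @export
analyzeOverlap <- function(seq1, seq2, coords, bam1 = NULL, bam2 = NULL,
                           id1 = "frag1", id2 = "frag2",
                           min_depth = 10, min_reads = 2, min_maf = 0.2,
                           large_threshold = 100, pair_id = NULL) {
    if (coords$length < 100)
        stop("overlap shorter than 100 bases is uninformative; refusing")
    o1 <- substring(as.character(seq1), coords$start1, coords$end1)
    o2 <- substring(as.character(seq2), coords$start2, coords$end2)
    aln <- Biostrings::pairwiseAlignment(o1, o2, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
        gapOpening = 10, gapExtension = 1)
    p1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    p2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    pos1 <- coords$start1 - 1L + cumsum(p1 != "-")
    pos2 <- coords$start2 - 1L + cumsum(p2 != "-")
    aligned <- p1 != "-" & p2 != "-"
    mism <- which(aligned & p1 != p2)
    ncols <- length(p1)
    identity <- 100 * sum(aligned & p1 == p2) / ncols

    ## indel events: maximal runs of gap columns
    gapc <- !aligned
    indels <- data.frame(pos1 = integer(), pos2 = integer(),
                         length = integer(), type = character(),
                         stringsAsFactors = FALSE)
    if (any(gapc)) {
        r <- rle(gapc)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        gi <- which(r$values)
        indels <- data.frame(
            pos1 = pos1[starts[gi]],
            pos2 = pos2[starts[gi]],
            length = r$lengths[gi],
            type = ifelse(p1[starts[gi]] == "-", "ins2", "ins1"),
            stringsAsFactors = FALSE)
    }
    n_large <- sum(indels$length >= large_threshold)

    snps_read <- NA_real_; snps_both <- NA_real_; third <- NA_real_
    if (!is.null(bam1) && !is.null(bam2)) {
        w1 <- GenomicRanges::GRanges(id1, IRanges::IRanges(coords$start1,
                                                           coords$end1))
        w2 <- GenomicRanges::GRanges(id2, IRanges::IRanges(coords$start2,
                                                           coords$end2))
        pile1 <- basePileup(bam1, w1)
        pile2 <- basePileup(bam2, w2)
        het1 <- .hetSitesFromPileup(pile1, min_depth, min_reads, min_maf)
        het2 <- .hetSitesFromPileup(pile2, min_depth, min_reads, min_maf)
        ## read-supported SNP sites inside the overlap, by alignment column
        het1c <- match(het1$pos, pos1[aligned])
        het2c <- match(het2$pos, pos2[aligned])
        snps_read <- length(union(het1c[!is.na(het1c)],
                                  het2c[!is.na(het2c)]))
        ## both-supported: pairwise SNP columns whose two alleles are the
        ## called heterozygous alleles on either fragment
        if (length(mism)) {
            alleles <- function(het, p) {
                m <- match(p, het$pos)
                cbind(het$a1[m], het$a2[m])
            }
            a1m <- alleles(het1, pos1[mism])
            a2m <- alleles(het2, pos2[mism])
            okpair <- function(am, x, y) {
                !is.na(am[, 1]) & ((am[, 1] == x & am[, 2] == y) |
                                   (am[, 1] == y & am[, 2] == x))
            }
            b1 <- okpair(a1m, p1[mism], p2[mism])
            b2 <- okpair(a2m, p1[mism], p2[mism])
            snps_both <- sum(b1 | b2)
        } else snps_both <- 0
        ## third alleles: any adequately supported read allele absent from
        ## both fragment bases at an aligned column
        third <- .thirdAlleles(pile1, pile2, pos1, pos2, p1, p2, aligned,
                               min_reads, min_maf)
    }
    new("OverlapReport",
        pair_id = if (is.null(pair_id)) paste(id1, id2, sep = "|") else
            pair_id,
        overlap_length = ncols, identity = identity,
        snps_pairwise = length(mism),
        snps_read_supported = snps_read,
        snps_both_supported = snps_both,
        third_allele_sites = third,
        indels = indels, n_indels_large = n_large,
        large_threshold = large_threshold)
}

## Sites carrying more than two distinct alleles once the two fragment
## bases and the adequately supported read alleles of both pileups are
## pooled.  The second haplotype allele revealed by reads on a
## same-haplotype overlap is the second allele, not a third; only an
## allele beyond the two haplotypes (e.g. a population variant carried by
## reads) counts.
.thirdAlleles <- function(pile1, pile2, pos1, pos2, p1, p2, aligned,
                          min_reads, min_maf) {
    cols <- which(aligned)
    bases1 <- p1[cols]; bases2 <- p2[cols]
    supported <- function(pile, posmap) {
        out <- vector("list", length(cols))
        if (!nrow(pile)) return(out)
        dp <- .depthFromPileup(pile)
        depth <- dp$depth[match(posmap, dp$pos)]
        idx <- split(seq_len(nrow(pile)), pile$pos)
        for (i in seq_along(cols)) {
            rows <- idx[[as.character(posmap[i])]]
            if (is.null(rows) || is.na(depth[i]) || depth[i] == 0) next
            d <- pile[rows, , drop = FALSE]
            ok <- d$count >= min_reads & d$count / depth[i] >= min_maf
            out[[i]] <- d$nucleotide[ok]
        }
        out
    }
    s1 <- supported(pile1, pos1[cols])
    s2 <- supported(pile2, pos2[cols])
    cnt <- 0L
    for (i in seq_along(cols)) {
        alleles <- unique(c(bases1[i], bases2[i], s1[[i]], s2[[i]]))
        if (length(alleles) > 2L) cnt <- cnt + 1L
    }
    cnt
}

#' Per-fragment heterozygosity and population variance from read pileups
#'
#' Maps-based accounting for a single long fragment representing one
#' haplotype: diploid reads piled on it reveal heterozygous sites (the
#' shared site rule) and sites with more than two adequately supported
#' alleles (population variance).
#'
#' @param fragment fragment sequence (\code{DNAString} or character)
#' @param bam BAM of all reads mapped to this fragment individually
#' @param id fragment name as it appears in the BAM
#' @param min_depth,min_reads,min_maf pileup thresholds
#' @return \code{data.frame}: id, length, mean_depth, het_sites,
#'   het_percent, popvar_sites, popvar_percent, low_conf
#' @export
fragmentHet <- function(fragment, bam, id, min_depth = 10, min_reads = 2,
                        min_maf = 0.2) {
    len <- nchar(as.character(fragment))
    w <- GenomicRanges::GRanges(id, IRanges::IRanges(1L, len))
    pile <- basePileup(bam, w)
    dp <- .depthFromPileup(pile)
    mean_depth <- sum(as.numeric(dp$depth)) / len
    het <- .hetSitesFromPileup(pile, min_depth, min_reads, min_maf)
    ## >2 alleles: third allele beyond the two best-supported ones
    key <- split(seq_len(nrow(pile)), pile$pos)
    pv <- 0L
    for (rows in key) {
        d <- pile[rows, , drop = FALSE]
        depth <- sum(d$count)
        if (depth < min_depth || nrow(d) < 3) next
        d <- d[order(-d$count), , drop = FALSE]
        if (d$count[3] >= min_reads && d$count[3] / depth >= min_maf / 2)
            pv <- pv + 1L
    }
    data.frame(id = id, length = len, mean_depth = mean_depth,
               het_sites = nrow(het), het_percent = 100 * nrow(het) / len,
               popvar_sites = pv, popvar_percent = 100 * pv / len,
               low_conf = mean_depth < min_depth,
               stringsAsFactors = FALSE)
}

#' Overlap reports as a summary table
#'
#' @param reports list of [OverlapReport-class] objects
#' @return \code{data.frame} with one row per pair, in the shape of a
#'   per-overlap polymorphism table (overlap length, identity, SNP
#'   classes, third alleles, indel counts)
#' @export
overlapTable <- function(reports) {
    do.call(rbind, lapply(reports, function(r)
        data.frame(pair = r@pair_id, overlap_length = r@overlap_length,
                   identity = r@identity, snps_pairwise = r@snps_pairwise,
                   snps_read_supported = r@snps_read_supported,
                   snps_both_supported = r@snps_both_supported,
                   third_allele_sites = r@third_allele_sites,
                   n_indels = nrow(r@indels),
                   n_indels_large = r@n_indels_large,
                   stringsAsFactors = FALSE)))
}
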