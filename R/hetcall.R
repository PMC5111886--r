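## Per-gene heterozygosity and population variance via transcript-guided
## two-locus analysis: coverage grouping of transcribed regions, transcript
## multi-mapping filters, pileup- and alignment-based heterozygous-site
## calling, third-allele (population) accounting and synonymous /
## non-synonymous classification.

#' Mean read depth over transcribed regions
#'
#' @param bam sorted, indexed BAM of reads mapped to the assembly
#' @param regions named \code{GRangesList}: gene id -> exonic/aligned
#'   blocks on the assembly
#' @return \code{data.frame}: gene_id, depth (mean over block bases,
#'   zero-coverage bases included), length
#' @export
regionCoverage <- function(bam, regions) {
    ids <- names(regions)
    gr <- unlist(regions, use.names = FALSE)
    S4Vectors::mcols(gr)$gene_id <- rep(ids, lengths(regions))
    pile <- basePileup(bam, gr)
    depth <- .depthFromPileup(pile)
    out <- data.frame(gene_id = ids, depth = 0, length = 0,
                      stringsAsFactors = FALSE)
    for (i in seq_along(ids)) {
        blocks <- regions[[i]]
        blen <- sum(IRanges::width(blocks))
        d <- depth[depth$seqnames %in%
                   as.character(GenomicRanges::seqnames(blocks)), ,
                   drop = FALSE]
        if (nrow(d)) {
            hit <- IRanges::overlapsAny(
                GenomicRanges::GRanges(d$seqnames,
                                       IRanges::IRanges(d$pos, d$pos)),
                blocks)
            tot <- sum(d$depth[hit])
        } else tot <- 0
        out$depth[i] <- tot / blen
        out$length[i] <- blen
    }
    out
}

#' Classify transcribed regions into coverage groups
#'
#' A heterozygous assembly shows two depth regimes for transcribed
#' regions: split-haplotype loci at the per-haplotype depth and
#' merged-haplotype loci at twice that.  The two modes are detected from
#' the depth distribution (kernel density; the two highest local maxima at
#' least \code{min_sep}-fold apart); the group boundary is their geometric
#' mean (about 106 for modes 75/150) and the high-group upper bound is the
#' high mode times \code{upper_mult} (250 for a mode of 150).  Regions at
#' the boundary go to the high (merged) group; regions above the upper
#' bound are unassigned.
#'
#' @param coverage \code{data.frame} from [regionCoverage()]
#' @param modes optional length-2 numeric: force the two depth modes
#' @param upper_mult high-group upper bound in units of the high mode
#' @param min_sep minimum mode separation (fold)
#' @return \code{data.frame}: gene_id, depth, group ("split", "merged" or
#'   "unassigned"), with attributes \code{modes}, \code{boundary},
#'   \code{upper}
#' @export
classifyCoverageGroups <- function(coverage, modes = NULL,
                                   upper_mult = 5 / 3, min_sep = 1.3) {
    d <- coverage$depth
    if (is.null(modes)) {
        if (length(d) < 4)
            stop("too few regions to detect coverage modes")
        dens <- stats::density(d, n = 512)
        y <- dens$y; x <- dens$x
        ismax <- which(diff(sign(diff(y))) == -2) + 1L
        if (!length(ismax))
            ismax <- which.max(y)
        cand <- ismax[order(y[ismax], decreasing = TRUE)]
        m1 <- x[cand[1]]
        m2 <- NA_real_
        for (p in cand[-1]) {
            if (max(x[p], m1) / min(x[p], m1) >= min_sep) {
                m2 <- x[p]
                break
            }
        }
        if (is.na(m2)) {
            warning("depth distribution unimodal: all regions in one group")
            out <- data.frame(gene_id = coverage$gene_id, depth = d,
                              group = "merged", stringsAsFactors = FALSE)
            attr(out, "modes") <- m1
            return(out)
        }
        modes <- sort(c(m1, m2))
    }
    modes <- sort(modes)
    boundary <- sqrt(modes[1] * modes[2])
    upper <- modes[2] * upper_mult
    group <- ifelse(d < boundary, "split",
             ifelse(d <= upper, "merged", "unassigned"))
    out <- data.frame(gene_id = coverage$gene_id, depth = d, group = group,
                      stringsAsFactors = FALSE)
    attr(out, "modes") <- modes
    attr(out, "boundary") <- boundary
    attr(out, "upper") <- upper
    out
}

#' Map transcripts to an assembly and apply the multi-mapping filters
#'
#' Spliced alignment of every transcript, then: alignments spanning fewer
#' than \code{min_aln} genomic bases are discarded; transcripts with more
#' than \code{max_loci} remaining loci are dropped as likely repetitive or
#' highly conserved; the rest are sorted by ascending edit distance (ties:
#' longer alignment, then target name) and the top \code{top_n} loci
#' retained.
#'
#' @param assembly FASTA path or named \code{DNAStringSet}
#' @param transcripts FASTA path or named \code{DNAStringSet}
#' The loci of one transcript must describe the same transcribed region
#' for a two-locus (allelic) comparison to make sense, so beyond the top
#' locus, only loci whose transcript span overlaps the top locus span by
#' at least \code{min_span_frac} are eligible for the remaining
#' \code{top_n - 1} slots; other placements (e.g. the continuation of a
#' gene split across a contig boundary) still count towards the locus
#' total but are not retained.
#'
#' @param min_aln minimum genomic alignment span (bases)
#' @param max_loci maximum mapping loci before a transcript is dropped
#' @param top_n loci retained per transcript
#' @param min_span_frac minimum transcript-span overlap with the top
#'   locus for secondary loci
#' @param paf optional precomputed alignment table (as returned by
#'   [alignTranscripts()]); skips the alignment step
#' @return list: \code{hits} (\code{data.frame} with locus_rank and
#'   n_loci), \code{dropped} (\code{data.frame}: tx_id, reason --
#'   "unplaced" or "too_many_loci")
#' @export
mapTranscriptsAndFilter <- function(assembly, transcripts, min_aln = 30,
                                    max_loci = 5, top_n = 2,
                                    min_span_frac = 0.5, paf = NULL) {
    if (is.null(paf))
        paf <- alignTranscripts(assembly, transcripts)
    tx_ids <- if (is.null(transcripts))
        unique(paf$qname)
    else if (is.character(transcripts))
        names(Biostrings::readDNAStringSet(transcripts))
    else names(transcripts)
    paf <- paf[(paf$tend - paf$tstart + 1L) >= min_aln, , drop = FALSE]
    dropped <- list()
    hits <- list()
    for (tx in tx_ids) {
        h <- paf[paf$qname == tx, , drop = FALSE]
        if (!nrow(h)) {
            dropped[[tx]] <- data.frame(tx_id = tx, reason = "unplaced",
                                        stringsAsFactors = FALSE)
            next
        }
        ## placements much shorter than the transcript's best placement
        ## are continuations of a gene split across records, not
        ## independent loci; drop them before ranking by mismatches
        span <- h$qend - h$qstart + 1L
        h <- h[span >= min_span_frac * max(span), , drop = FALSE]
        if (nrow(h) > max_loci) {
            dropped[[tx]] <- data.frame(tx_id = tx,
                                        reason = "too_many_loci",
                                        stringsAsFactors = FALSE)
            next
        }
        h <- h[order(h$nm, -h$aln_len, h$tname), , drop = FALSE]
        n_loci <- nrow(h)
        top_span <- c(h$qstart[1], h$qend[1])
        ov <- pmin(h$qend, top_span[2]) - pmax(h$qstart, top_span[1]) + 1L
        eligible <- ov >= min_span_frac * (top_span[2] - top_span[1] + 1L)
        eligible[1] <- TRUE
        h <- utils::head(h[eligible, , drop = FALSE], top_n)
        h$locus_rank <- seq_len(nrow(h))
        h$n_loci <- n_loci
        hits[[tx]] <- h
    }
    empty_hits <- data.frame(qname = character(), qlen = integer(),
                             qstart = integer(), qend = integer(),
                             strand = character(), tname = character(),
                             tlen = integer(), tstart = integer(),
                             tend = integer(), nmatch = integer(),
                             aln_len = integer(), mapq = integer(),
                             nm = integer(), cigar = character(),
                             locus_rank = integer(), n_loci = integer(),
                             stringsAsFactors = FALSE)
    list(hits = if (length(hits)) do.call(rbind, hits) else empty_hits,
         dropped = if (length(dropped)) do.call(rbind, dropped) else
             data.frame(tx_id = character(), reason = character(),
                        stringsAsFactors = FALSE))
}

## Paired per-column coordinates of the transcript-vs-locus alignment:
## for each aligned (M) column, the original transcript position, the
## target contig position, the transcript base (in target orientation)
## and the target base.
.txLocusColumns <- function(tx_seq, contig_seq, hit) {
    blocks <- .cigarBlocks(hit$cigar)
    if (is.null(blocks))
        return(NULL)
    tx_aln <- substring(as.character(tx_seq), hit$qstart, hit$qend)
    if (hit$strand == "-")
        tx_aln <- .revcompChar(tx_aln)
    t_aln <- substring(as.character(contig_seq), hit$tstart, hit$tend)
    txc <- strsplit(tx_aln, "", fixed = TRUE)[[1L]]
    tc <- strsplit(t_aln, "", fixed = TRUE)[[1L]]
    qi <- unlist(lapply(seq_len(nrow(blocks)), function(i)
        blocks[i, "qs"]:blocks[i, "qe"]))
    ti <- unlist(lapply(seq_len(nrow(blocks)), function(i)
        blocks[i, "ts"]:blocks[i, "te"]))
    tpos_orig <- if (hit$strand == "+") hit$qstart + qi - 1L
                 else hit$qend - qi + 1L
    data.frame(tpos = tpos_orig,
               gpos = hit$tstart + ti - 1L,
               tx_base = txc[qi],
               g_base = tc[ti],
               stringsAsFactors = FALSE)
}

#' Call per-gene heterozygosity from transcript loci and read pileups
#'
#' Implements the two-arm procedure for a partially collapsed assembly.
#' \emph{Merged} genes (one genomic locus) collect reads from both
#' haplotypes, so heterozygous sites are called from the read pileup over
#' the transcript-aligned blocks (site rule: depth at least
#' \code{min_depth}, two alleles each on at least \code{min_reads} reads,
#' minor-allele fraction at least \code{min_maf}); the assessed length is
#' the number of block bases at adequate depth.  \emph{Split} genes (two
#' loci, i.e. the haplotypes assembled separately) are scored from the
#' global pairwise alignment of the two genomic segments; each difference
#' column must be supported by reads on its own contig; the assessed
#' length is the number of aligned (gap-free) columns.  Indel events in
#' the split-locus alignment count as one polymorphic site each.
#'
#' @param hits \code{hits} table of [mapTranscriptsAndFilter()]
#' @param assembly named \code{DNAStringSet} of the assembly
#' @param transcripts named \code{DNAStringSet} of transcripts
#' @param bam sorted, indexed BAM of genomic reads on the assembly
#' @param min_depth,min_reads,min_maf pileup heterozygous-site thresholds
#' @param min_span_frac minimum fraction of the top-locus transcript span
#'   the second locus must cover to be treated as allelic
#' @return \code{data.frame}, one row per transcript: gene_id, n_loci
#'   used, arm ("merged"/"split"), het_sites, assessed, het_percent,
#'   low_conf, plus per-site attribute \code{sites} (list-column of
#'   called-site tables used downstream)
#' @export
callHeterozygosity <- function(hits, assembly, transcripts, bam,
                               min_depth = 10, min_reads = 2,
                               min_maf = 0.2, min_span_frac = 0.5) {
    tx_ids <- unique(hits$qname)
    ## one pileup over every hit region
    all_gr <- GenomicRanges::GRanges(hits$tname,
        IRanges::IRanges(hits$tstart, hits$tend))
    pile <- basePileup(bam, GenomicRanges::reduce(all_gr))
    out <- vector("list", length(tx_ids))
    sites_list <- vector("list", length(tx_ids))
    names(sites_list) <- tx_ids
    for (ti in seq_along(tx_ids)) {
        tx <- tx_ids[ti]
        h <- hits[hits$qname == tx, , drop = FALSE]
        top <- h[h$locus_rank == 1L, , drop = FALSE]
        arm <- "merged"
        second <- NULL
        if (nrow(h) > 1L) {
            s <- h[h$locus_rank == 2L, , drop = FALSE]
            span_top <- c(top$qstart, top$qend)
            ov <- min(s$qend, span_top[2]) - max(s$qstart, span_top[1]) + 1L
            if (ov >= min_span_frac * (span_top[2] - span_top[1] + 1L)) {
                arm <- "split"
                second <- s
            }
        }
        if (arm == "merged") {
            r <- .hetMergedArm(top, transcripts, pile, min_depth,
                               min_reads, min_maf)
        } else {
            r <- .hetSplitArm(top, second, assembly, transcripts, pile,
                              min_reads)
        }
        sites_list[[tx]] <- r$sites
        out[[ti]] <- data.frame(gene_id = tx, n_loci = nrow(h), arm = arm,
                                het_sites = r$het_sites,
                                assessed = r$assessed,
                                het_percent = if (r$assessed > 0)
                                    100 * r$het_sites / r$assessed
                                else NA_real_,
                                low_conf = r$low_conf,
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    attr(res, "sites") <- sites_list
    res
}

## Merged arm: heterozygous sites from the pileup over cigar blocks.
.hetMergedArm <- function(top, transcripts, pile, min_depth, min_reads,
                          min_maf) {
    blocks <- .cigarBlocks(top$cigar)
    gpos_rng <- IRanges::IRanges(top$tstart + blocks[, "ts"] - 1L,
                                 top$tstart + blocks[, "te"] - 1L)
    blen <- sum(IRanges::width(gpos_rng))
    p <- pile[pile$seqnames == top$tname, , drop = FALSE]
    p <- p[IRanges::overlapsAny(IRanges::IRanges(p$pos, p$pos), gpos_rng), ,
           drop = FALSE]
    dp <- .depthFromPileup(p)
    assessed <- sum(dp$depth >= min_depth)
    het <- .hetSitesFromPileup(p, min_depth, min_reads, min_maf)
    list(het_sites = nrow(het), assessed = assessed,
         low_conf = assessed < 0.5 * blen,
         sites = if (nrow(het)) data.frame(
             contig = het$seqnames, gpos = het$pos, a1 = het$a1,
             a2 = het$a2, type = "snp", stringsAsFactors = FALSE)
         else NULL)
}

## Split arm: global alignment of the two genomic segments; difference
## columns require read support on each contig.
.hetSplitArm <- function(top, second, assembly, transcripts, pile,
                         min_reads) {
    s1 <- substring(as.character(assembly[[top$tname]]), top$tstart,
                    top$tend)
    s2 <- substring(as.character(assembly[[second$tname]]), second$tstart,
                    second$tend)
    rc <- top$strand != second$strand
    if (rc)
        s2 <- .revcompChar(s2)
    aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
        gapOpening = 10, gapExtension = 1)
    p1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    p2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    o1 <- cumsum(p1 != "-")
    o2 <- cumsum(p2 != "-")
    aligned <- p1 != "-" & p2 != "-"
    assessed <- sum(aligned)
    mism <- which(aligned & p1 != p2)
    ## read support: each contig's reads must carry its own allele
    supp <- function(contig, gpos, allele) {
        q <- pile[pile$seqnames == contig & pile$pos %in% gpos, ,
                  drop = FALSE]
        cnt <- numeric(length(gpos))
        if (nrow(q)) {
            key <- paste(q$pos, q$nucleotide)
            m <- match(paste(gpos, allele), key)
            cnt[!is.na(m)] <- q$count[m[!is.na(m)]]
        }
        cnt >= min_reads
    }
    sites <- NULL
    n_snp <- 0L
    if (length(mism)) {
        g1 <- top$tstart + o1[mism] - 1L
        pos2_seg <- o2[mism]
        g2 <- if (!rc) second$tstart + pos2_seg - 1L
              else second$tend - pos2_seg + 1L
        a1 <- p1[mism]
        a2seg <- p2[mism]
        a2 <- if (!rc) a2seg else unname(.COMP[a2seg])
        ok <- supp(top$tname, g1, a1) & supp(second$tname, g2, a2)
        n_snp <- sum(ok)
        if (n_snp)
            sites <- data.frame(contig = top$tname, gpos = g1[ok],
                                a1 = a1[ok], a2 = a2seg[ok], type = "snp",
                                stringsAsFactors = FALSE)
    }
    ## indel events: runs of gap columns, one polymorphic site each
    gapcols <- which(!aligned)
    n_indel <- 0L
    if (length(gapcols)) {
        runs <- cumsum(c(1L, diff(gapcols) != 1L))
        n_indel <- length(unique(runs))
    }
    list(het_sites = n_snp + n_indel, assessed = assessed,
         low_conf = FALSE, sites = sites)
}

#' Population variance: transcript alleles absent from both haplotypes
#'
#' For every transcript position aligned to the genome, the observed
#' transcript base is compared with the genomic allele set at that site:
#' the contig base(s) at the mapped position of each retained locus plus
#' any read-pileup allele seen on at least \code{min_reads} reads there.
#' Sites whose transcript base matches neither haplotype allele are
#' population-variant sites (a third allele contributed by the wider
#' population the transcriptome samples); the rate is reported per
#' assessed transcribed base.  A third allele at an already heterozygous
#' site still counts once.
#'
#' @inheritParams callHeterozygosity
#' @param min_depth minimum summed pileup depth across loci for a
#'   transcript position to be assessed
#' @return \code{data.frame}: gene_id, popvar_sites, assessed,
#'   popvar_percent; attribute \code{sites} holds per-gene site tables
#'   (tpos, tx_base)
#' @export
populationVariance <- function(hits, assembly, transcripts, bam,
                               min_depth = 10, min_reads = 2) {
    tx_ids <- unique(hits$qname)
    all_gr <- GenomicRanges::GRanges(hits$tname,
        IRanges::IRanges(hits$tstart, hits$tend))
    pile <- basePileup(bam, GenomicRanges::reduce(all_gr))
    out <- vector("list", length(tx_ids))
    sites_list <- vector("list", length(tx_ids))
    names(sites_list) <- tx_ids
    for (ti in seq_along(tx_ids)) {
        tx <- tx_ids[ti]
        h <- hits[hits$qname == tx, , drop = FALSE]
        cols <- lapply(seq_len(nrow(h)), function(i)
            .txLocusColumns(transcripts[[tx]],
                            assembly[[h$tname[i]]], h[i, , drop = FALSE]))
        keep <- !vapply(cols, is.null, TRUE)
        h <- h[keep, , drop = FALSE]; cols <- cols[keep]
        if (!nrow(h)) next
        ## allele sets as 4-bit masks per transcript position, pooled
        ## over the retained loci
        tp <- sort(unique(unlist(lapply(cols, `[[`, "tpos"))))
        allele_mask <- integer(length(tp))
        depth_tot <- numeric(length(tp))
        tx_base <- character(length(tp))
        for (i in seq_along(cols)) {
            cc <- cols[[i]]
            idx <- match(cc$tpos, tp)
            strand_minus <- h$strand[i] == "-"
            q <- pile[pile$seqnames == h$tname[i] &
                      pile$count >= min_reads, , drop = FALSE]
            pos_mask <- rowsum(.ALLELE_BIT[q$nucleotide], q$pos)
            qd <- pile[pile$seqnames == h$tname[i], , drop = FALSE]
            pos_depth <- rowsum(qd$count, qd$pos)
            pm <- pos_mask[match(cc$gpos, as.integer(rownames(pos_mask)))]
            pm[is.na(pm)] <- 0L
            m <- bitwOr(.ALLELE_BIT[cc$g_base], as.integer(pm))
            tb <- cc$tx_base
            if (strand_minus) {
                m <- .COMP_MASK[m + 1L]
                tb <- unname(.COMP[tb])
            }
            allele_mask[idx] <- bitwOr(allele_mask[idx], m)
            dd <- pos_depth[match(cc$gpos, as.integer(rownames(pos_depth)))]
            dd[is.na(dd)] <- 0
            depth_tot[idx] <- depth_tot[idx] + dd
            tx_base[idx] <- tb
        }
        ok <- depth_tot >= min_depth
        assessed <- sum(ok)
        is_pv <- ok & bitwAnd(allele_mask, .ALLELE_BIT[tx_base]) == 0L
        pv <- sum(is_pv)
        if (pv)
            sites_list[[tx]] <- data.frame(tpos = tp[is_pv],
                                           tx_base = tx_base[is_pv],
                                           stringsAsFactors = FALSE)
        out[[ti]] <- data.frame(gene_id = tx, popvar_sites = pv,
                                assessed = assessed,
                                popvar_percent = if (assessed > 0)
                                    100 * pv / assessed else NA_real_,
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    attr(res, "sites") <- sites_list
    res
}

## 4-bit allele masks and their complement-strand mapping
.ALLELE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.COMP_MASK <- vapply(0:15, function(m) {
    out <- 0L
    if (bitwAnd(m, 1L)) out <- bitwOr(out, 8L)  # A -> T
    if (bitwAnd(m, 2L)) out <- bitwOr(out, 4L)  # C -> G
    if (bitwAnd(m, 4L)) out <- bitwOr(out, 2L)  # G -> C
    if (bitwAnd(m, 8L)) out <- bitwOr(out, 1L)  # T -> A
    out
}, 1L)

#' Classify substitutions between two in-frame coding sequences
#'
#' Codon-by-codon comparison of two equal-length, in-frame nucleotide
#' sequences: a nucleotide difference that changes the encoded amino acid
#' is non-synonymous, one that does not is synonymous.  Sequences of
#' unequal length are first decomposed by global alignment; each gap run
#' is counted as one indel event and the flanking in-frame segments are
#' compared codon-wise (an error is raised if the decomposition leaves a
#' segment length not divisible by three, i.e. a frameshift).
#'
#' @param coding_a,coding_b character or \code{DNAString} coding sequences
#'   (frame starting at base 1)
#' @return named integer vector: syn, nonsyn, indel_events
#' @examples
#' classifySubstitutions("GCTGGG", "GCCGAG")  # 1 synonymous, 1 Gly->Glu
#' @export
classifySubstitutions <- function(coding_a, coding_b) {
    a <- toupper(as.character(coding_a))
    b <- toupper(as.character(coding_b))
    if (nchar(a) == nchar(b))
        return(c(.codonCompare(a, b), indel_events = 0L))
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
        gapOpening = 10, gapExtension = 1)
    p1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    p2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    gap <- p1 == "-" | p2 == "-"
    runs <- rle(gap)
    idx <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
    n_indel <- sum(runs$values)
    syn <- 0L; nonsyn <- 0L
    segs <- which(!runs$values)
    for (s in segs) {
        cols <- idx[s]:(idx[s] + runs$lengths[s] - 1L)
        sa <- paste0(p1[cols], collapse = "")
        sb <- paste0(p2[cols], collapse = "")
        if (nchar(sa) %% 3L != 0L)
            stop("frameshifting decomposition: segment length not a ",
                 "multiple of three")
        cc <- .codonCompare(sa, sb)
        syn <- syn + cc["syn"]; nonsyn <- nonsyn + cc["nonsyn"]
    }
    c(syn = unname(syn), nonsyn = unname(nonsyn),
      indel_events = as.integer(n_indel))
}

.codonCompare <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    if (nchar(a) %% 3L != 0L)
        stop("coding sequence length not divisible by three")
    n <- nchar(a) %/% 3L
    if (n == 0L)
        return(c(syn = 0L, nonsyn = 0L))
    st <- 3L * (seq_len(n) - 1L) + 1L
    ca <- substring(a, st, st + 2L)
    cb <- substring(b, st, st + 2L)
    diffc <- ca != cb
    aa_a <- Biostrings::GENETIC_CODE[ca[diffc]]
    aa_b <- Biostrings::GENETIC_CODE[cb[diffc]]
    c(syn = sum(diffc) - sum(aa_a != aa_b, na.rm = TRUE) -
          sum(is.na(aa_a) | is.na(aa_b)),
      nonsyn = sum(aa_a != aa_b, na.rm = TRUE) +
          sum(is.na(aa_a) | is.na(aa_b)))
}

#' Per-gene heterozygosity, coverage group, population variance and
#' substitution classes in one table
#'
#' Orchestrates the gene-level pipeline on a mapped assembly:
#' transcript mapping and filtering, coverage grouping over the top-locus
#' blocks, heterozygosity calling, population variance and, for genes
#' with called heterozygous sites, synonymous/non-synonymous
#' classification of the coding differences (the transcript versus the
#' transcript with the alternate alleles substituted).
#'
#' @param assembly named \code{DNAStringSet}
#' @param transcripts named \code{DNAStringSet} (one coding transcript per
#'   gene, frame 1)
#' @param bam sorted, indexed BAM of genomic reads on the assembly
#' @param modes optional forced coverage modes (see
#'   [classifyCoverageGroups()])
#' @param min_depth,min_reads,min_maf heterozygous-site thresholds
#' @param classify_subst whether to run codon classification per gene
#' @return \code{data.frame}, one row per retained transcript: gene_id,
#'   group, depth, arm, het_percent, het_sites, assessed, popvar_percent,
#'   syn, nonsyn, low_conf
#' @export
geneHetTable <- function(assembly, transcripts, bam, modes = NULL,
                         min_depth = 10, min_reads = 2, min_maf = 0.2,
                         classify_subst = TRUE) {
    mp <- mapTranscriptsAndFilter(assembly, transcripts)
    hits <- mp$hits
    if (!nrow(hits))
        stop("no transcript could be placed on the assembly")
    ## coverage over top-locus blocks
    tops <- hits[hits$locus_rank == 1L, , drop = FALSE]
    regions <- stats::setNames(lapply(seq_len(nrow(tops)), function(i) {
        b <- .cigarBlocks(tops$cigar[i])
        GenomicRanges::GRanges(tops$tname[i],
            IRanges::IRanges(tops$tstart[i] + b[, "ts"] - 1L,
                             tops$tstart[i] + b[, "te"] - 1L))
    }), tops$qname)
    cov <- regionCoverage(bam, GenomicRanges::GRangesList(regions))
    grp <- classifyCoverageGroups(cov, modes = modes)
    het <- callHeterozygosity(hits, assembly, transcripts, bam,
                              min_depth, min_reads, min_maf)
    pv <- populationVariance(hits, assembly, transcripts, bam,
                             min_depth, min_reads)
    res <- merge(merge(grp, het, by = "gene_id"),
                 pv[, c("gene_id", "popvar_percent")], by = "gene_id",
                 all.x = TRUE)
    res$syn <- NA_integer_; res$nonsyn <- NA_integer_
    if (classify_subst) {
        sites <- attr(het, "sites")
        for (i in seq_len(nrow(res))) {
            tx <- res$gene_id[i]
            s <- sites[[tx]]
            txseq <- as.character(transcripts[[tx]])
            if (is.null(s) || !nrow(s) || nchar(txseq) %% 3L != 0L) {
                if (nchar(txseq) %% 3L == 0L) {
                    res$syn[i] <- 0L; res$nonsyn[i] <- 0L
                }
                next
            }
            alt <- .substituteAltAlleles(txseq, s,
                hits[hits$qname == tx & hits$locus_rank == 1L, ,
                     drop = FALSE], transcripts[[tx]], res$arm[i])
            if (is.null(alt)) next
            cc <- tryCatch(classifySubstitutions(txseq, alt),
                           error = function(e) NULL)
            if (!is.null(cc)) {
                res$syn[i] <- cc["syn"]; res$nonsyn[i] <- cc["nonsyn"]
            }
        }
    }
    res[order(res$gene_id),
        c("gene_id", "group", "depth", "arm", "het_percent", "het_sites",
          "assessed", "popvar_percent", "syn", "nonsyn", "low_conf")]
}

## Substitute the alternate allele of every called heterozygous SNP into
## the transcript sequence (transcript coordinates via the top-locus
## alignment), giving the "polymorphism-annotated" sequence for codon
## classification.
.substituteAltAlleles <- function(txseq, sites, top, tx_xs, arm) {
    blocks <- .cigarBlocks(top$cigar)
    if (is.null(blocks))
        return(NULL)
    ## map genomic position -> transcript position
    qi <- unlist(lapply(seq_len(nrow(blocks)), function(i)
        blocks[i, "qs"]:blocks[i, "qe"]))
    ti <- unlist(lapply(seq_len(nrow(blocks)), function(i)
        blocks[i, "ts"]:blocks[i, "te"]))
    gpos <- top$tstart + ti - 1L
    tpos <- if (top$strand == "+") top$qstart + qi - 1L
            else top$qend - qi + 1L
    ch <- strsplit(txseq, "", fixed = TRUE)[[1L]]
    s <- sites[sites$type == "snp" & sites$contig == top$tname, ,
               drop = FALSE]
    if (!nrow(s))
        return(paste0(ch, collapse = ""))
    m <- match(s$gpos, gpos)
    s <- s[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
    if (!nrow(s))
        return(paste0(ch, collapse = ""))
    tp <- tpos[m]
    cur <- ch[tp]
    for (j in seq_along(tp)) {
        alleles <- c(s$a1[j], s$a2[j])
        if (top$strand == "-")
            alleles <- unname(.COMP[alleles])
        alt <- setdiff(alleles, cur[j])
        if (length(alt) == 1L)
            ch[tp[j]] <- alt
        else if (length(alt) > 1L)
            ch[tp[j]] <- alt[1L]
    }
    paste0(ch, collapse = "")
}
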