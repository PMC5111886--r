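## Variant application and haplotype coordinate liftover.
##
## Variants are expressed against haplotype A (the reference haplotype),
## 1-based: a SNP replaces base `pos`; a deletion removes `pos .. pos +
## nchar(ref) - 1`; an insertion places `alt` immediately after `pos`.
## Indels are left-normalized at generation time.

#' Apply a planted-variant table to a reference haplotype sequence
#'
#' Reconstructs haplotype B from haplotype A and the variant table.  This
#' is the defining identity of [DiploidGenome-class]: for every simulated
#' genome, \code{applyVariants} over haplotype A reproduces haplotype B
#' exactly.
#'
#' @param seq a single sequence (character or \code{DNAString})
#' @param variants \code{data.frame} with columns pos, type (snp/ins/del),
#'   ref, alt, for this sequence only, sorted by pos
#' @return character: the alternate haplotype sequence
#' @export
applyVariants <- function(seq, variants) {
    seq <- as.character(seq)
    if (is.null(variants) || nrow(variants) == 0L)
        return(seq)
    stopifnot(!is.unsorted(variants$pos, strictly = TRUE))
    pos <- variants$pos
    type <- variants$type
    removed <- ifelse(type == "snp", 1L,
               ifelse(type == "del", nchar(variants$ref), 0L))
    cut_start <- ifelse(type == "ins", pos + 1L, pos)
    repl <- ifelse(type == "del", "", variants$alt)
    keep_start <- c(1L, cut_start + removed)
    keep_end <- c(cut_start - 1L, nchar(seq))
    keep <- substring(seq, keep_start, keep_end)
    n <- length(pos)
    pieces <- character(2L * n + 1L)
    pieces[seq(1L, 2L * n + 1L, by = 2L)] <- keep
    pieces[seq(2L, 2L * n, by = 2L)] <- repl
    paste0(pieces, collapse = "")
}

## Offset events (indels only) of a variant table, precomputed for liftover.
.liftEvents <- function(variants) {
    ev <- variants[variants$type != "snp", , drop = FALSE]
    if (nrow(ev) == 0L)
        return(NULL)
    is_ins <- ev$type == "ins"
    len <- ifelse(is_ins, nchar(ev$alt), nchar(ev$ref))
    delta <- ifelse(is_ins, len, -len)
    cum <- cumsum(delta)
    cum_prev <- c(0, head(cum, -1L))
    list(pos = ev$pos, is_ins = is_ins, len = len,
         a_end = ifelse(is_ins, ev$pos, ev$pos + len - 1L),
         b_thr = ifelse(is_ins, ev$pos + cum, ev$pos - 1L + cum_prev),
         cum = cum)
}

#' Lift positions between the two haplotypes of a simulated genome
#'
#' \code{liftA2B} maps 1-based haplotype-A positions to haplotype B;
#' positions falling inside a deletion map to the last retained base before
#' it.  \code{liftB2A} is the inverse; positions inside an insertion map to
#' the anchor base of the insertion.
#'
#' @param pos integer vector of 1-based positions
#' @param variants variant table for one sequence (sorted by pos)
#' @return integer vector of lifted positions
#' @export
liftA2B <- function(pos, variants) {
    ev <- .liftEvents(variants)
    if (is.null(ev))
        return(as.integer(pos))
    idx <- findInterval(pos - 0.5, ev$a_end)
    out <- pos + c(0, ev$cum)[idx + 1L]
    nxt <- idx + 1L
    in_del <- nxt <= length(ev$pos) & !ev$is_ins[pmin(nxt, length(ev$pos))] &
        pos >= ev$pos[pmin(nxt, length(ev$pos))]
    if (any(in_del))
        out[in_del] <- ev$pos[nxt[in_del]] - 1L +
            c(0, ev$cum)[idx[in_del] + 1L]
    as.integer(pmax(out, 1L))
}

#' @rdname liftA2B
#' @export
liftB2A <- function(pos, variants) {
    ev <- .liftEvents(variants)
    if (is.null(ev))
        return(as.integer(pos))
    idx <- findInterval(pos - 0.5, ev$b_thr)
    out <- pos - c(0, ev$cum)[idx + 1L]
    nxt <- idx + 1L
    k <- pmin(nxt, length(ev$pos))
    in_ins <- nxt <= length(ev$pos) & ev$is_ins[k] &
        pos > ev$pos[k] + c(0, ev$cum)[idx + 1L]
    if (any(in_ins))
        out[in_ins] <- ev$pos[nxt[in_ins]]
    as.integer(pmax(out, 1L))
}

## Extract the subsequence of the requested haplotype homologous to the
## haplotype-A interval [startA, endA] on sequence `seqid`.
.extractHomologous <- function(genome, seqid, startA, endA, hap) {
    if (hap == "A")
        return(substring(as.character(genome@hapA[[seqid]]), startA, endA))
    v <- genome@variants[genome@variants$seqid == seqid, , drop = FALSE]
    bs <- liftA2B(startA, v)
    be <- liftA2B(endA, v)
    substring(as.character(genome@hapB[[seqid]]), bs, be)
}

.BASES <- c("A", "C", "G", "T")

## Uniform random DNA of length n as a single character string.
.randomDNA <- function(n) {
    paste0(sample(.BASES, n, replace = TRUE), collapse = "")
}

## Substitute bases at `rate`, never to the original base.
.mutateSeq <- function(seq, rate) {
    n <- nchar(seq)
    nmut <- rbinom(1L, n, rate)
    if (nmut == 0L)
        return(seq)
    pos <- sort(sample.int(n, nmut))
    old <- substring(seq, pos, pos)
    new <- vapply(old, function(b) sample(setdiff(.BASES, b), 1L), "")
    s <- strsplit(seq, "", fixed = TRUE)[[1L]]
    s[pos] <- new
    paste0(s, collapse = "")
}

.revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## N50-style statistics: the length L such that records of length >= L hold
## at least `frac` of the total assembly length.
.nStat <- function(lengths, frac) {
    if (length(lengths) == 0L)
        return(NA_real_)
    l <- sort(lengths, decreasing = TRUE)
    l[which(cumsum(as.numeric(l)) >= frac * sum(as.numeric(l)))[1L]]
}

#' Assembly summary statistics
#'
#' Per-record-class summary in the shape of a standard assembly metrics
#' table: number of sequences, N90, N50, N10, total and maximum length.
#'
#' @param lengths numeric vector of record lengths
#' @return one-row \code{data.frame}
#' @export
assemblyStats <- function(lengths) {
    data.frame(n = length(lengths),
               N90 = .nStat(lengths, 0.9),
               N50 = .nStat(lengths, 0.5),
               N10 = .nStat(lengths, 0.1),
               sum_length = sum(as.numeric(lengths)),
               max_length = if (length(lengths)) max(lengths) else NA_real_)
}
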