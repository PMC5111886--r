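## Paired-end read simulation.  Reads carry substitution errors only (no
## sequencing indels), so pileup truth stays exact; fragment origin is
## recorded per pair.

## Core generator over an arbitrary set of source sequences.  `hap` is a
## label stored in the truth table.  Optional population variants are
## planted per overlapping mate with the given carrier frequency.
.simulateReadsCore <- function(seqs, hap, coverage, read_len, frag_mean,
                               frag_sd, error_rate, pop_variants = NULL) {
    r1 <- character(0); r2 <- character(0)
    truth <- list()
    for (sid in names(seqs)) {
        s <- as.character(seqs[[sid]])
        len <- nchar(s)
        if (read_len > len)
            stop("read_len exceeds length of sequence ", sid)
        n <- as.integer(round(coverage * len / (2 * read_len)))
        if (n == 0L) next
        fl <- pmin(pmax(as.integer(round(rnorm(n, frag_mean, frag_sd))),
                        read_len), len)
        start <- floor(runif(n) * (len - fl + 1)) + 1L
        end <- start + fl - 1L
        flip <- runif(n) < 0.5
        left <- substring(s, start, start + read_len - 1L)
        right <- substring(s, end - read_len + 1L, end)
        right_rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(right)))
        left_rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(left)))
        m1 <- ifelse(flip, right_rc, left)
        m2 <- ifelse(flip, left, right_rc)
        ## mate2 as written is the reverse strand of its genomic span;
        ## when flipped, mate1 is.  (left_rc kept for symmetry checks.)
        ids <- sprintf("%s_%s_%06d", hap, sid, seq_along(start))
        if (!is.null(pop_variants)) {
            pv <- pop_variants[pop_variants$seqid == sid, , drop = FALSE]
            for (k in seq_len(nrow(pv))) {
                p <- pv$pos_hap[k]
                carrier <- runif(n) < pv$freq[k]
                ## mate 1 span and orientation
                sp1s <- ifelse(flip, end - read_len + 1L, start)
                sp1e <- sp1s + read_len - 1L
                hit1 <- carrier & p >= sp1s & p <= sp1e
                if (any(hit1)) {
                    rp <- ifelse(flip[hit1], sp1e[hit1] - p + 1L,
                                 p - sp1s[hit1] + 1L)
                    nb <- ifelse(flip[hit1], .COMP[pv$alt[k]], pv$alt[k])
                    m1[hit1] <- as.character(mapply(function(x, q, b) {
                        substr(x, q, q) <- b; x
                    }, m1[hit1], rp, nb))
                }
                sp2s <- ifelse(flip, start, end - read_len + 1L)
                sp2e <- sp2s + read_len - 1L
                hit2 <- carrier & p >= sp2s & p <= sp2e
                if (any(hit2)) {
                    rp <- ifelse(flip[hit2], p - sp2s[hit2] + 1L,
                                 sp2e[hit2] - p + 1L)
                    nb <- ifelse(flip[hit2], pv$alt[k], .COMP[pv$alt[k]])
                    m2[hit2] <- as.character(mapply(function(x, q, b) {
                        substr(x, q, q) <- b; x
                    }, m2[hit2], rp, nb))
                }
            }
        }
        r1 <- c(r1, m1); r2 <- c(r2, m2)
        truth[[sid]] <- data.frame(id = ids, hap = hap, seqid = sid,
                                   frag_start = start, frag_end = end,
                                   flipped = flip, stringsAsFactors = FALSE)
    }
    list(r1 = r1, r2 = r2,
         truth = if (length(truth)) do.call(rbind, truth) else
             data.frame(id = character(), hap = character(),
                        seqid = character(), frag_start = integer(),
                        frag_end = integer(), flipped = logical()))
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

## Inject substitution errors into a character vector of reads.
.injectErrors <- function(reads, read_len, error_rate) {
    if (error_rate <= 0 || !length(reads))
        return(reads)
    total <- length(reads) * read_len
    n_err <- rbinom(1L, total, error_rate)
    if (n_err == 0L)
        return(reads)
    ridx <- sample.int(length(reads), n_err, replace = TRUE)
    rpos <- sample.int(read_len, n_err, replace = TRUE)
    cur <- substring(reads[ridx], rpos, rpos)
    new <- .BASES[(match(cur, .BASES) - 1L +
                   sample.int(3L, n_err, replace = TRUE)) %% 4L + 1L]
    .cpp_substitute_bases(reads, ridx, rpos, new)
}

#' Simulate paired-end shotgun reads from a diploid genome
#'
#' Generates fragments from each haplotype at
#' \code{coverage_per_haplotype}, so homozygous regions see about twice
#' that total depth, the structure that produces the characteristic
#' two-peak contig/gene coverage histogram of a highly heterozygous
#' assembly.  Errors are substitutions only.
#'
#' @param genome a [DiploidGenome-class]
#' @param cfg the [SimConfig-class] used to build it
#' @param haplotypes haplotypes to sequence (default both)
#' @param error_rate override for \code{seq_error_rate}
#' @param pop_variants optional \code{data.frame} (seqid, pos, alt, freq)
#'   of population alleles, positions on haplotype A; carried by reads of
#'   either haplotype with the given frequency
#' @return a [ReadSet-class]
#' @export
simulateReads <- function(genome, cfg, haplotypes = c("A", "B"),
                          error_rate = cfg@seq_error_rate,
                          pop_variants = NULL) {
    if (cfg@coverage_per_haplotype <= 0)
        stop("coverage_per_haplotype must be positive")
    set.seed(cfg@seed + 1L)
    parts <- list()
    for (h in haplotypes) {
        seqs <- if (h == "A") genome@hapA else genome@hapB
        pv <- NULL
        if (!is.null(pop_variants)) {
            pv <- pop_variants
            pv$pos_hap <- pv$pos
            if (h == "B")
                for (sid in unique(pv$seqid)) {
                    vv <- genome@variants[genome@variants$seqid == sid, ,
                                          drop = FALSE]
                    sel <- pv$seqid == sid
                    pv$pos_hap[sel] <- liftA2B(pv$pos[sel], vv)
                }
        }
        parts[[h]] <- .simulateReadsCore(seqs, h, cfg@coverage_per_haplotype,
                                         cfg@read_len, cfg@fragment_mean,
                                         cfg@fragment_sd, 0, pv)
    }
    r1 <- unlist(lapply(parts, `[[`, "r1"), use.names = FALSE)
    r2 <- unlist(lapply(parts, `[[`, "r2"), use.names = FALSE)
    truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
    rownames(truth) <- NULL
    r1 <- .injectErrors(r1, cfg@read_len, error_rate)
    r2 <- .injectErrors(r2, cfg@read_len, error_rate)
    s1 <- Biostrings::DNAStringSet(r1); names(s1) <- paste0(truth$id, "/1")
    s2 <- Biostrings::DNAStringSet(r2); names(s2) <- paste0(truth$id, "/2")
    new("ReadSet", reads1 = s1, reads2 = s2, truth = truth,
        read_len = cfg@read_len)
}

#' Simulate reads from an arbitrary sequence set
#'
#' Haploid-style generator used for single-fragment coverage and for
#' cross-library comparisons; same error model as [simulateReads()].
#'
#' @param seqs named \code{DNAStringSet} (or character)
#' @param coverage fold coverage
#' @param read_len read length
#' @param frag_mean,frag_sd insert-size distribution
#' @param error_rate substitution error rate
#' @param seed integer seed
#' @param label haplotype/source label stored in the truth table
#' @return a [ReadSet-class]
#' @export
simulateReadsFrom <- function(seqs, coverage, read_len = 150,
                              frag_mean = 400, frag_sd = 40,
                              error_rate = 0, seed = 1, label = "A") {
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)))
        names(seqs) <- paste0("seq", seq_along(seqs))
    set.seed(seed)
    p <- .simulateReadsCore(seqs, label, coverage, read_len, frag_mean,
                            frag_sd, 0)
    r1 <- .injectErrors(p$r1, read_len, error_rate)
    r2 <- .injectErrors(p$r2, read_len, error_rate)
    s1 <- Biostrings::DNAStringSet(r1); names(s1) <- paste0(p$truth$id, "/1")
    s2 <- Biostrings::DNAStringSet(r2); names(s2) <- paste0(p$truth$id, "/2")
    new("ReadSet", reads1 = s1, reads2 = s2, truth = p$truth,
        read_len = read_len)
}

#' Write a read set as a paired FASTQ
#'
#' @param reads a [ReadSet-class]
#' @param prefix output path prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq} with constant base quality
#' @return invisibly, the two file paths
#' @export
writeReadsFastq <- function(reads, prefix) {
    f1 <- paste0(prefix, "_1.fastq")
    f2 <- paste0(prefix, "_2.fastq")
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads@reads1)))
    Biostrings::writeXStringSet(reads@reads1, f1, format = "fastq",
                                qualities = q)
    q2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads@reads2)))
    Biostrings::writeXStringSet(reads@reads2, f2, format = "fastq",
                                qualities = q2)
    invisible(c(f1, f2))
}
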