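#' Simulate transcripts carrying extra population-level variants
#'
#' Each gene yields one transcript: the spliced exons of one randomly
#' chosen haplotype, on the gene strand.  On top of the haplotype's own
#' alleles, extra variants are planted at
#' \code{population_variant_rate} per transcribed base, emulating a
#' transcriptome assembled from many individuals of a laboratory
#' population.  A planted population allele never coincides with either
#' haplotype allele at its site, so it is a genuine third allele.
#'
#' @param genome a [DiploidGenome-class]
#' @param cfg the [SimConfig-class] used to build it
#' @param rate override for \code{population_variant_rate}
#' @return list with elements \code{transcripts} (named
#'   \code{DNAStringSet}), \code{truth} (\code{data.frame}: tx_id, gene_id,
#'   hap, tpos, seqid, posA, refA, refB, alt -- alt in genomic plus-strand
#'   terms) and \code{origin} (\code{data.frame}: tx_id, gene_id, hap,
#'   strand, spliced_len)
#' @export
simulateTranscripts <- function(genome, cfg,
                                rate = cfg@population_variant_rate) {
    ex <- geneModels(genome)
    if (!length(ex))
        stop("genome has no gene models")
    set.seed(cfg@seed + 2L)
    ids <- unique(S4Vectors::mcols(ex)$gene_id)
    seqs <- character(length(ids))
    origin <- vector("list", length(ids))
    truth <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        g <- ids[i]
        e <- ex[S4Vectors::mcols(ex)$gene_id == g]
        e <- e[order(GenomicRanges::start(e))]
        sid <- as.character(GenomicRanges::seqnames(e))[1L]
        strand <- as.character(GenomicRanges::strand(e))[1L]
        hap <- sample(c("A", "B"), 1L)
        v <- genome@variants[genome@variants$seqid == sid, , drop = FALSE]
        starts <- GenomicRanges::start(e)
        ends <- GenomicRanges::end(e)
        if (hap == "A") {
            src <- as.character(genome@hapA[[sid]])
            pieces <- substring(src, starts, ends)
        } else {
            src <- as.character(genome@hapB[[sid]])
            pieces <- substring(src, liftA2B(starts, v), liftA2B(ends, v))
        }
        spliced <- paste0(pieces, collapse = "")
        slen <- nchar(spliced)
        ## spliced plus-strand position -> haplotype-A genomic position
        cumw <- cumsum(c(0L, ends - starts + 1L))
        sp2a <- function(sp) {
            k <- findInterval(sp, cumw + 1L)
            starts[k] + (sp - cumw[k] - 1L)
        }
        npv <- rbinom(1L, slen, rate)
        if (npv > 0L) {
            sp <- sort(sample.int(slen, npv))
            posA <- sp2a(sp)
            refA <- substring(as.character(genome@hapA[[sid]]), posA, posA)
            snp <- v[v$type == "snp", , drop = FALSE]
            refB <- refA
            m <- match(posA, snp$pos)
            refB[!is.na(m)] <- snp$alt[m[!is.na(m)]]
            alt <- vapply(seq_along(sp), function(j) {
                choices <- setdiff(.BASES, c(refA[j], refB[j]))
                sample(choices, 1L)
            }, "")
            ch <- strsplit(spliced, "", fixed = TRUE)[[1L]]
            ch[sp] <- alt
            spliced <- paste0(ch, collapse = "")
            tpos <- if (strand == "-") slen - sp + 1L else sp
            truth[[i]] <- data.frame(tx_id = paste0("tx_", g), gene_id = g,
                                     hap = hap, tpos = tpos, seqid = sid,
                                     posA = posA, refA = refA, refB = refB,
                                     alt = alt, stringsAsFactors = FALSE)
        }
        if (strand == "-")
            spliced <- .revcompChar(spliced)
        seqs[i] <- spliced
        origin[[i]] <- data.frame(tx_id = paste0("tx_", g), gene_id = g,
                                  hap = hap, strand = strand,
                                  spliced_len = slen,
                                  stringsAsFactors = FALSE)
    }
    tx <- Biostrings::DNAStringSet(seqs)
    names(tx) <- paste0("tx_", ids)
    tr <- truth[!vapply(truth, is.null, TRUE)]
    list(transcripts = tx,
         truth = if (length(tr)) do.call(rbind, tr) else
             data.frame(tx_id = character(), gene_id = character(),
                        hap = character(), tpos = integer(),
                        seqid = character(), posA = integer(),
                        refA = character(), refB = character(),
                        alt = character(), stringsAsFactors = FALSE),
         origin = do.call(rbind, origin))
}
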