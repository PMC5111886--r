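## Thin wrappers around minimap2 and samtools (read and transcript
## alignment) plus Rsamtools pileup helpers shared by the heterozygosity
## and overlap modules.

.findTool <- function(name) {
    p <- Sys.which(name)
    if (!nzchar(p))
        stop(name, " not found on PATH; required for alignment steps")
    unname(p)
}

#' Map paired-end reads to a reference with minimap2
#'
#' Runs minimap2 (short-read preset), sorts and indexes with samtools, and
#' returns the BAM path.
#'
#' @param ref reference: FASTA path or named \code{DNAStringSet}
#' @param reads a [ReadSet-class] or length-2 character of FASTQ paths
#' @param out_bam output BAM path (default: tempfile)
#' @param preset minimap2 preset (default \code{sr})
#' @param extra extra minimap2 options.  The defaults re-seed with
#'   shorter, denser minimizers and a milder mismatch penalty than the
#'   stock short-read preset: reads drawn from the other haplotype of a
#'   highly heterozygous region (locally 5\% divergence and more) fail
#'   to seed at the preset's k=21 and would drop out of pileups exactly
#'   where heterozygosity is highest
#' @param max_clip drop alignments with more than this many soft-clipped
#'   bases (\code{NULL}: keep everything).  Useful when mapping to a
#'   single fragment: reads spanning a large haplotype indel junction
#'   align with long clips and their frayed ends contaminate pileup
#'   columns near the junction
#' @return path of the sorted, indexed BAM
#' @export
mapReads <- function(ref, reads, out_bam = tempfile(fileext = ".bam"),
                     preset = "sr",
                     extra = c("-k15", "-w5", "-A2", "-B5"),
                     max_clip = NULL) {
    mm2 <- .findTool("minimap2")
    st <- .findTool("samtools")
    if (!is.character(ref)) {
        fa <- tempfile(fileext = ".fasta")
        Biostrings::writeXStringSet(ref, fa)
        ref <- fa
    }
    if (is(reads, "ReadSet")) {
        prefix <- tempfile()
        writeReadsFastq(reads, prefix)
        fq <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    } else fq <- reads
    sam <- tempfile(fileext = ".sam")
    status <- system2(mm2, c("-ax", preset, extra, "-t", "1",
                             "--secondary=no",
                             shQuote(ref), shQuote(fq[1]), shQuote(fq[2])),
                      stdout = sam, stderr = FALSE)
    if (status != 0)
        stop("minimap2 failed (exit ", status, ")")
    if (!is.null(max_clip)) {
        flt <- tempfile(fileext = ".sam")
        status <- system2(st, c("view", "-h", "-e",
                                shQuote(paste0("sclen <= ", max_clip)),
                                shQuote(sam)),
                          stdout = flt, stderr = FALSE)
        if (status != 0)
            stop("samtools view failed (exit ", status, ")")
        unlink(sam)
        sam <- flt
    }
    status <- system2(st, c("sort", "-o", shQuote(out_bam), shQuote(sam)),
                      stderr = FALSE)
    if (status != 0)
        stop("samtools sort failed (exit ", status, ")")
    unlink(sam)
    system2(st, c("index", shQuote(out_bam)))
    out_bam
}

#' Align transcripts to an assembly (spliced) and return hit records
#'
#' Runs minimap2 in spliced mode with secondary alignments enabled and
#' parses the PAF (with CIGAR and edit distance) into one row per
#' alignment.
#'
#' @param assembly FASTA path or named \code{DNAStringSet}
#' @param transcripts FASTA path or named \code{DNAStringSet}
#' @param max_secondary secondary alignment cap passed to minimap2
#' @return \code{data.frame}: qname, qlen, qstart, qend (1-based closed),
#'   strand, tname, tlen, tstart, tend (1-based closed), nmatch, aln_len,
#'   mapq, nm (edit distance), cigar
#' @export
alignTranscripts <- function(assembly, transcripts, max_secondary = 10) {
    mm2 <- .findTool("minimap2")
    if (!is.character(assembly)) {
        fa <- tempfile(fileext = ".fasta")
        Biostrings::writeXStringSet(assembly, fa)
        assembly <- fa
    }
    if (!is.character(transcripts)) {
        fa <- tempfile(fileext = ".fasta")
        Biostrings::writeXStringSet(transcripts, fa)
        transcripts <- fa
    }
    ## -P retains all chains: the near-identical allelic locus is
    ## otherwise suppressed by secondary-chain selection
    paf <- tempfile(fileext = ".paf")
    status <- system2(mm2, c("-c", "-x", "splice", "-t", "1", "-P",
                             shQuote(assembly), shQuote(transcripts)),
                      stdout = paf, stderr = FALSE)
    if (status != 0)
        stop("minimap2 failed (exit ", status, ")")
    .parsePaf(paf)
}

.parsePaf <- function(path) {
    lines <- readLines(path)
    empty <- data.frame(qname = character(), qlen = integer(),
                        qstart = integer(), qend = integer(),
                        strand = character(), tname = character(),
                        tlen = integer(), tstart = integer(),
                        tend = integer(), nmatch = integer(),
                        aln_len = integer(), mapq = integer(),
                        nm = integer(), cigar = character(),
                        stringsAsFactors = FALSE)
    if (!length(lines))
        return(empty)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- lapply(parts, function(f) {
        tags <- f[-(1:12)]
        nm <- sub("NM:i:", "", grep("^NM:i:", tags, value = TRUE)[1])
        cg <- sub("cg:Z:", "", grep("^cg:Z:", tags, value = TRUE)[1])
        data.frame(qname = f[1], qlen = as.integer(f[2]),
                   qstart = as.integer(f[3]) + 1L, qend = as.integer(f[4]),
                   strand = f[5], tname = f[6], tlen = as.integer(f[7]),
                   tstart = as.integer(f[8]) + 1L, tend = as.integer(f[9]),
                   nmatch = as.integer(f[10]), aln_len = as.integer(f[11]),
                   mapq = as.integer(f[12]),
                   nm = as.integer(nm), cigar = cg,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

## Parse a PAF cigar into per-block target/query intervals (1-based,
## relative to tstart/qstart on the target strand).
.cigarBlocks <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSH=X]", cigar))[[1]]
    len <- as.integer(sub("[MIDNSH=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    q <- 0L; t <- 0L
    blocks <- list()
    for (i in seq_along(op)) {
        if (op[i] %in% c("M", "=", "X")) {
            blocks[[length(blocks) + 1L]] <-
                c(qs = q + 1L, qe = q + len[i], ts = t + 1L, te = t + len[i])
            q <- q + len[i]; t <- t + len[i]
        } else if (op[i] == "I") {
            q <- q + len[i]
        } else if (op[i] %in% c("D", "N")) {
            t <- t + len[i]
        }
    }
    do.call(rbind, blocks)
}

#' Per-position nucleotide pileup over regions of a BAM
#'
#' @param bam path of a sorted, indexed BAM
#' @param which \code{GRanges} of regions
#' @param max_depth pileup depth cap
#' @return \code{data.frame}: seqnames, pos, nucleotide, count (summed over
#'   strands)
#' @export
basePileup <- function(bam, which, max_depth = 10000) {
    p <- Rsamtools::pileup(bam,
        scanBamParam = Rsamtools::ScanBamParam(which = which),
        pileupParam = Rsamtools::PileupParam(
            max_depth = max_depth, min_base_quality = 0L,
            min_mapq = 0L, min_nucleotide_depth = 1L,
            distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
            include_deletions = FALSE, include_insertions = FALSE))
    if (!nrow(p))
        return(data.frame(seqnames = character(), pos = integer(),
                          nucleotide = character(), count = integer(),
                          stringsAsFactors = FALSE))
    dt <- data.table::data.table(seqnames = as.character(p$seqnames),
                                 pos = p$pos,
                                 nucleotide = as.character(p$nucleotide),
                                 count = p$count)
    agg <- dt[, list(count = sum(count)),
              by = c("seqnames", "pos", "nucleotide")]
    data.table::setorderv(agg, c("seqnames", "pos"))
    as.data.frame(agg)
}

## Heterozygous-site calls from a nucleotide pileup, shared by the gene
## and fragment modules: a site is heterozygous when depth >= min_depth,
## the two top alleles each have >= min_reads reads, and the minor of the
## two has frequency >= min_maf among all reads at the site.
.hetSitesFromPileup <- function(pile, min_depth = 10, min_reads = 2,
                                min_maf = 0.2) {
    empty <- data.frame(seqnames = character(), pos = integer(),
                        a1 = character(), a2 = character(),
                        depth = integer(), stringsAsFactors = FALSE)
    if (!nrow(pile))
        return(empty)
    dt <- data.table::as.data.table(pile)
    data.table::setorderv(dt, c("seqnames", "pos", "count"),
                          order = c(1L, 1L, -1L))
    dt[, `:=`(depth = sum(count), rank = seq_len(.N)),
       by = c("seqnames", "pos")]
    top2 <- dt[dt$rank <= 2L & dt$depth >= min_depth]
    n2 <- top2[, list(n = .N, a1 = nucleotide[1L],
                      a2 = nucleotide[pmin(2L, .N)],
                      c2 = count[pmin(2L, .N)], depth = depth[1L]),
               by = c("seqnames", "pos")]
    het <- n2[n2$n == 2L & n2$c2 >= min_reads & n2$c2 / n2$depth >= min_maf]
    if (!nrow(het))
        return(empty)
    res <- as.data.frame(het[, c("seqnames", "pos", "a1", "a2", "depth")])
    res[order(res$seqnames, res$pos), , drop = FALSE]
}

## Per-position total depth from a nucleotide pileup.
.depthFromPileup <- function(pile) {
    if (!nrow(pile))
        return(data.frame(seqnames = character(), pos = integer(),
                          depth = integer(), stringsAsFactors = FALSE))
    agg <- stats::aggregate(count ~ seqnames + pos, data = pile, FUN = sum)
    names(agg)[3] <- "depth"
    agg$seqnames <- as.character(agg$seqnames)
    agg[order(agg$seqnames, agg$pos), , drop = FALSE]
}
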