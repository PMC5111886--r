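## Serialization of simulated truth in standard formats: FASTA/FASTQ via
## Biostrings, GFF3/BED via rtracklayer, VCF via VariantAnnotation, plain
## TSV for the remaining truth tables.

#' Write a simulated genome and its ground truth to a directory
#'
#' Emits haplotype FASTAs, the planted variant table as a VCF (against
#' haplotype A), repeat copies as BED, gene models as GFF3 and the
#' per-gene truth as TSV.
#'
#' @param genome a [DiploidGenome-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of file paths
#' @export
writeGenomeTruth <- function(genome, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(hapA = file.path(dir, "hapA.fasta"),
               hapB = file.path(dir, "hapB.fasta"),
               variants = file.path(dir, "variants.vcf"),
               repeats = file.path(dir, "repeats.bed"),
               genes = file.path(dir, "genes.gff3"),
               gene_truth = file.path(dir, "gene_truth.tsv"))
    Biostrings::writeXStringSet(genome@hapA, paths["hapA"])
    Biostrings::writeXStringSet(genome@hapB, paths["hapB"])
    writeVariantsVcf(genome, paths["variants"])
    if (length(genome@repeats)) {
        rtracklayer::export(genome@repeats, paths["repeats"], format = "BED")
    } else file.create(paths["repeats"])
    if (length(genome@genes)) {
        ex <- genome@genes
        S4Vectors::mcols(ex)$type <- "exon"
        S4Vectors::mcols(ex)$ID <- sprintf("%s.e%d",
            S4Vectors::mcols(ex)$gene_id, S4Vectors::mcols(ex)$exon_rank)
        S4Vectors::mcols(ex)$Parent <- S4Vectors::mcols(ex)$gene_id
        rtracklayer::export(ex, paths["genes"], format = "GFF3")
    } else file.create(paths["genes"])
    writeTruthTsv(geneTruth(genome), paths["gene_truth"])
    invisible(paths)
}

#' Write the planted variant table as a VCF against haplotype A
#'
#' Indels are emitted with the usual anchor-base convention (POS is the
#' base before the event); internal positions are already left-normalized.
#'
#' @param genome a [DiploidGenome-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeVariantsVcf <- function(genome, path) {
    v <- genome@variants
    if (!nrow(v)) {
        vr <- VariantAnnotation::VRanges()
    } else {
        hapA <- genome@hapA
        pos <- integer(nrow(v)); ref <- character(nrow(v))
        alt <- character(nrow(v))
        for (i in seq_len(nrow(v))) {
            s <- as.character(hapA[[v$seqid[i]]])
            if (v$type[i] == "snp") {
                pos[i] <- v$pos[i]; ref[i] <- v$ref[i]; alt[i] <- v$alt[i]
            } else if (v$type[i] == "del") {
                p <- max(v$pos[i] - 1L, 1L)
                anchor <- substring(s, p, p)
                pos[i] <- p
                ref[i] <- paste0(anchor, v$ref[i])
                alt[i] <- anchor
            } else {
                p <- v$pos[i]
                anchor <- substring(s, p, p)
                pos[i] <- p
                ref[i] <- anchor
                alt[i] <- paste0(anchor, v$alt[i])
            }
        }
        vr <- VariantAnnotation::VRanges(
            seqnames = v$seqid,
            ranges = IRanges::IRanges(pos, width = nchar(ref)),
            ref = ref, alt = alt, sampleNames = "sim")
    }
    VariantAnnotation::writeVcf(vr, path)
    invisible(path)
}

#' Write/read a truth table as TSV
#'
#' Plain tab-separated serialization used for every simulator truth table;
#' \code{readTruthTsv(writeTruthTsv(x, f))} reproduces \code{x}.
#'
#' @param x a \code{data.frame}
#' @param path file path
#' @return \code{writeTruthTsv}: invisibly, \code{path};
#'   \code{readTruthTsv}: the \code{data.frame}
#' @export
writeTruthTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}

#' Write a fragment set (FASTA + truth TSVs)
#'
#' @param frags a [FragmentSet-class]
#' @param dir output directory
#' @return invisibly, the named vector of file paths
#' @export
writeFragments <- function(frags, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "fragments.fasta"),
               truth = file.path(dir, "fragment_truth.tsv"),
               overlaps = file.path(dir, "overlap_truth.tsv"))
    Biostrings::writeXStringSet(frags@sequences, paths["fasta"])
    writeTruthTsv(frags@truth, paths["truth"])
    writeTruthTsv(frags@overlaps, paths["overlaps"])
    invisible(paths)
}
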