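## Allelic contig (haplotig) detection and collapse: candidate discovery by
## shared-k-mer seeding + pairwise alignment, threshold selection, cluster
## resolution, primary/secondary partitioning and reintegration with
## assembly summary statistics.

#' All-vs-all contig similarity for allelic-pair discovery
#'
#' Reports, for every contig pair with detectable homology, the percent
#' identity of the best local alignment (matches over alignment columns;
#' gap columns count as mismatches) and the overlap fraction (aligned span
#' of the shorter contig over its length).
#'
#' Two engines are available.  \code{method = "minimap2"} (default) runs
#' an all-vs-all minimizer-seeded alignment, the standard approach for
#' haplotig detection at assembly scale; identity is taken as
#' nmatch/alignment-length from the base-level alignment, which is exactly
#' matches/columns.  \code{method = "dp"} seeds candidate pairs by shared
#' canonical \code{seed_k}-mers (at least \code{min_seed} distinct ones)
#' and computes the exact best local alignment by dynamic programming;
#' quadratic in contig length, intended for small inputs and
#' cross-validation.
#'
#' @param contigs named \code{DNAStringSet}
#' @param method \code{"minimap2"} or \code{"dp"}
#' @param seed_k seed k-mer size (dp engine)
#' @param min_seed minimum shared distinct k-mers to trigger alignment
#'   (dp engine)
#' @param max_occ k-mers present in more than this many contigs are
#'   ignored as repeat-derived (dp engine)
#' @param gap_open,gap_extend,match,mismatch alignment scoring (dp engine)
#' @return \code{data.frame}: idA, idB (lexicographically ordered, each
#'   unordered pair once), identity, aln_len, overlap_frac
#' @export
pairwiseSimilarity <- function(contigs, method = c("minimap2", "dp"),
                               seed_k = 21, min_seed = 10,
                               max_occ = 10, gap_open = 10, gap_extend = 1,
                               match = 2, mismatch = -3) {
    method <- match.arg(method)
    if (length(contigs) < 2)
        stop("need at least two contigs")
    if (anyDuplicated(names(contigs)))
        stop("duplicate contig ids")
    if (method == "minimap2")
        .similarityMinimap(contigs)
    else
        .similarityDp(contigs, seed_k, min_seed, max_occ, gap_open,
                      gap_extend, match, mismatch)
}

.emptySimilarity <- function() {
    data.frame(idA = character(), idB = character(), identity = numeric(),
               aln_len = integer(), overlap_frac = numeric(),
               stringsAsFactors = FALSE)
}

.similarityMinimap <- function(contigs) {
    mm2 <- .findTool("minimap2")
    fa <- tempfile(fileext = ".fasta")
    Biostrings::writeXStringSet(contigs, fa)
    paf <- tempfile(fileext = ".paf")
    status <- system2(mm2, c("-c", "-x", "asm20", "-t", "1", "-D",
                             shQuote(fa), shQuote(fa)),
                      stdout = paf, stderr = FALSE)
    if (status != 0)
        stop("minimap2 failed (exit ", status, ")")
    hits <- .parsePaf(paf)
    unlink(c(fa, paf))
    hits <- hits[hits$qname != hits$tname, , drop = FALSE]
    if (!nrow(hits))
        return(.emptySimilarity())
    lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
    a <- pmin(hits$qname, hits$tname)
    b <- pmax(hits$qname, hits$tname)
    key <- paste(a, b)
    out <- lapply(split(seq_len(nrow(hits)), key), function(ix) {
        h <- hits[ix, , drop = FALSE]
        best <- which.max(h$aln_len)
        h <- h[best, , drop = FALSE]
        short_is_q <- lens[h$qname] <= lens[h$tname]
        span <- if (short_is_q) h$qend - h$qstart + 1L
                else h$tend - h$tstart + 1L
        short_len <- min(lens[h$qname], lens[h$tname])
        ids <- sort(c(h$qname, h$tname))
        data.frame(idA = ids[1], idB = ids[2],
                   identity = 100 * h$nmatch / h$aln_len,
                   aln_len = h$aln_len,
                   overlap_frac = min(span / short_len, 1),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$idA, res$idB), , drop = FALSE]
}

.similarityDp <- function(contigs, seed_k, min_seed, max_occ, gap_open,
                          gap_extend, match, mismatch) {
    cand <- .cpp_shared_kmer_pairs(as.character(contigs),
                                   as.integer(seed_k), as.integer(min_seed),
                                   as.integer(max_occ))
    if (!nrow(cand))
        return(.emptySimilarity())
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch)
    lens <- Biostrings::width(contigs)
    out <- vector("list", nrow(cand))
    for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        ## pattern = shorter contig
        if (lens[i] <= lens[j]) { pi <- i; sj <- j } else { pi <- j; sj <- i }
        aln <- Biostrings::pairwiseAlignment(contigs[[pi]], contigs[[sj]],
            type = "local", substitutionMatrix = mat,
            gapOpening = gap_open, gapExtension = gap_extend)
        cols <- Biostrings::nchar(aln)
        nm <- Biostrings::nmatch(aln)
        span <- Biostrings::width(Biostrings::pattern(aln))
        ids <- sort(names(contigs)[c(i, j)])
        out[[r]] <- data.frame(idA = ids[1], idB = ids[2],
                               identity = 100 * nm / cols,
                               aln_len = cols,
                               overlap_frac = min(span / lens[pi], 1),
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res[order(res$idA, res$idB), , drop = FALSE]
}

## Union-find over contig ids.
.ufFind <- function(parent, x) {
    while (parent[[x]] != x) {
        parent[[x]] <- parent[[parent[[x]]]]
        x <- parent[[x]]
    }
    x
}

#' Select allelic pairs and resolve clusters to one primary each
#'
#' Keeps candidate pairs exceeding both thresholds (strictly by default),
#' then resolves connected clusters of passing pairs so that each
#' secondary contig maps to exactly one primary: the longest contig of its
#' cluster, ties broken by lexicographically smaller id.
#'
#' @param candidates output of [pairwiseSimilarity()]
#' @param lengths named contig lengths
#' @param min_identity identity threshold (percent)
#' @param min_overlap overlap-fraction threshold
#' @param inclusive treat thresholds as \code{>=} instead of \code{>}
#' @return \code{data.frame}: secondary, primary
#' @export
selectAllelicPairs <- function(candidates, lengths, min_identity = 95,
                               min_overlap = 0.95, inclusive = FALSE) {
    if (inclusive)
        keep <- candidates$identity >= min_identity &
            candidates$overlap_frac >= min_overlap
    else
        keep <- candidates$identity > min_identity &
            candidates$overlap_frac > min_overlap
    p <- candidates[keep, , drop = FALSE]
    if (!nrow(p))
        return(data.frame(secondary = character(), primary = character(),
                          stringsAsFactors = FALSE))
    ids <- unique(c(p$idA, p$idB))
    parent <- stats::setNames(as.list(ids), ids)
    for (r in seq_len(nrow(p))) {
        ra <- .ufFind(parent, p$idA[r])
        rb <- .ufFind(parent, p$idB[r])
        if (ra != rb) parent[[ra]] <- rb
    }
    root <- vapply(ids, function(x) .ufFind(parent, x), "")
    out <- lapply(unique(root), function(rt) {
        memb <- ids[root == rt]
        l <- lengths[memb]
        prim <- memb[order(-l, memb)][1]
        data.frame(secondary = setdiff(memb, prim), primary = prim,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$secondary), , drop = FALSE]
}

#' Collapse an assembly into primary and secondary contigs
#'
#' Partitions the input contig set: contigs named as secondary in the
#' allelic mapping are set aside, everything else is primary and kept for
#' scaffolding.  Total sequence is conserved: primary plus secondary
#' lengths always sum to the input.
#'
#' @param contigs named \code{DNAStringSet}
#' @param pairs mapping \code{data.frame} (secondary, primary) from
#'   [selectAllelicPairs()]
#' @param min_identity,min_overlap thresholds recorded in the result
#' @return a [CollapseResult-class]
#' @export
collapseContigs <- function(contigs, pairs, min_identity = 95,
                            min_overlap = 0.95) {
    ids <- names(contigs)
    unknown <- setdiff(unique(c(pairs$secondary, pairs$primary)), ids)
    if (length(unknown))
        stop("pairs reference unknown contig(s): ",
             paste(unknown, collapse = ", "))
    lens <- stats::setNames(as.numeric(Biostrings::width(contigs)), ids)
    secondary <- unique(pairs$secondary)
    primary <- setdiff(ids, secondary)
    new("CollapseResult", primary = primary, secondary = secondary,
        mapping = pairs, lengths = lens,
        params = list(min_identity = min_identity,
                      min_overlap = min_overlap))
}

#' Detect and collapse allelic contigs in one call
#'
#' Convenience wrapper: [pairwiseSimilarity()] then
#' [selectAllelicPairs()] then [collapseContigs()].
#'
#' @inheritParams pairwiseSimilarity
#' @inheritParams selectAllelicPairs
#' @return a [CollapseResult-class]
#' @export
collapseAssembly <- function(contigs, min_identity = 95, min_overlap = 0.95,
                             seed_k = 21, min_seed = 10, inclusive = FALSE) {
    cand <- pairwiseSimilarity(contigs, seed_k = seed_k, min_seed = min_seed)
    lens <- stats::setNames(as.numeric(Biostrings::width(contigs)),
                            names(contigs))
    pairs <- selectAllelicPairs(cand, lens, min_identity, min_overlap,
                                inclusive)
    collapseContigs(contigs, pairs, min_identity, min_overlap)
}

#' Reintegrate secondary contigs after scaffolding
#'
#' Takes the scaffolded primary set and the collapse result and produces
#' the final assembly record classes: scaffolds, unplaced (primary)
#' contigs, and heterozygous (secondary) contigs, with per-class summary
#' statistics (number of sequences, N90, N50, N10, total and maximum
#' length).
#'
#' @param scaffold_members named list: scaffold id -> character vector of
#'   member primary contig ids.  Primaries in no scaffold are "unplaced".
#' @param result a [CollapseResult-class]
#' @param scaffold_lengths optional named scaffold lengths; defaults to the
#'   sum of member contig lengths
#' @return list: \code{records} (\code{data.frame}: id, class, length) and
#'   \code{summary} (\code{data.frame}, one row per class)
#' @export
reintegrate <- function(scaffold_members, result, scaffold_lengths = NULL) {
    members <- unlist(scaffold_members, use.names = FALSE)
    if (anyDuplicated(members))
        stop("a primary contig appears in more than one scaffold")
    bad <- setdiff(members, result@primary)
    if (length(bad))
        stop("scaffold member(s) not in the primary set: ",
             paste(bad, collapse = ", "))
    lens <- result@lengths
    if (is.null(scaffold_lengths))
        scaffold_lengths <- vapply(scaffold_members,
                                   function(m) sum(lens[m]), 1)
    unplaced <- setdiff(result@primary, members)
    records <- rbind(
        if (length(scaffold_members))
            data.frame(id = names(scaffold_members), class = "scaffold",
                       length = as.numeric(scaffold_lengths),
                       stringsAsFactors = FALSE),
        if (length(unplaced))
            data.frame(id = unplaced, class = "unplaced_contig",
                       length = as.numeric(lens[unplaced]),
                       stringsAsFactors = FALSE),
        if (length(result@secondary))
            data.frame(id = result@secondary, class = "hetero_contig",
                       length = as.numeric(lens[result@secondary]),
                       stringsAsFactors = FALSE))
    classes <- c("scaffold", "unplaced_contig", "hetero_contig")
    summ <- do.call(rbind, lapply(classes, function(cl) {
        st <- assemblyStats(records$length[records$class == cl])
        cbind(data.frame(class = cl, stringsAsFactors = FALSE), st)
    }))
    list(records = records, summary = summ)
}

#' Write collapse outputs
#'
#' Primary-contig FASTA (for external scaffolding) and the partition TSV.
#'
#' @param contigs the input \code{DNAStringSet}
#' @param result a [CollapseResult-class]
#' @param dir output directory
#' @return invisibly, the named vector of file paths
#' @export
writeCollapse <- function(contigs, result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(primary = file.path(dir, "primary.fasta"),
               partition = file.path(dir, "collapse.tsv"))
    Biostrings::writeXStringSet(contigs[result@primary], paths["primary"])
    part <- rbind(data.frame(id = result@primary, class = "primary",
                             primary = NA_character_,
                             stringsAsFactors = FALSE),
                  data.frame(id = result@mapping$secondary,
                             class = "secondary",
                             primary = result@mapping$primary,
                             stringsAsFactors = FALSE))
    writeTruthTsv(part, paths["partition"])
    invisible(paths)
}
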