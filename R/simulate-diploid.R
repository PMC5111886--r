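#' Simulate a diploid genome with complete ground truth
#'
#' Generates haplotype A (random sequence with interspersed repeat families
#' and gene models), plants SNP and indel variants at the configured rates,
#' and derives haplotype B by applying the variant table.  Every planted
#' feature is recorded, so downstream estimates of heterozygosity, repeat
#' content, coverage structure and overlap polymorphism can be scored
#' against truth.
#'
#' Placement rules: repeat copies are divergent copies (default 3\%
#' substitution) of a family consensus, tiled with random gaps on haplotype
#' A; because haplotype B is derived from A, copies sit at homologous
#' positions on both haplotypes.  Gene models are placed in repeat-free
#' gaps and indels are kept out of exons, so every spliced product stays in
#' frame on both haplotypes.  Indels are left-normalized and separated from
#' each other by a guard window so that each planted event corresponds to
#' one alignment gap.
#'
#' @param cfg a [SimConfig-class]
#' @return a [DiploidGenome-class]
#' @examples
#' g <- simulateDiploid(SimConfig(haploid_length = 2e4, n_genes = 2,
#'                                repeat_fraction = 0.1, seed = 7))
#' g
#' @export
simulateDiploid <- function(cfg) {
    validObject(cfg)
    set.seed(cfg@seed)
    n_seq <- as.integer(cfg@n_sequences)
    L <- as.integer(round(cfg@haploid_length / n_seq))
    seqids <- paste0("chr", seq_len(n_seq))

    consensus <- vapply(seq_len(max(cfg@n_repeat_families, 1L)),
                        function(i) .randomDNA(cfg@repeat_unit_len), "")

    hapA <- character(n_seq)
    all_var <- vector("list", n_seq)
    all_rep <- vector("list", n_seq)
    all_gene <- vector("list", n_seq)
    genes_per_seq <- diff(round(seq(0, cfg@n_genes, length.out = n_seq + 1L)))

    for (s in seq_len(n_seq)) {
        base <- sample(.BASES, L, replace = TRUE)

        rep_gr <- .placeRepeats(base, L, cfg, consensus, seqids[s])
        if (length(rep_gr)) {
            for (i in seq_along(rep_gr)) {
                st <- GenomicRanges::start(rep_gr)[i]
                fam <- S4Vectors::mcols(rep_gr)$family[i]
                copy <- .mutateSeq(consensus[fam], cfg@repeat_divergence)
                base[st:(st + cfg@repeat_unit_len - 1L)] <-
                    strsplit(copy, "", fixed = TRUE)[[1L]]
            }
        }

        exons <- .placeGenes(L, cfg, rep_gr, seqids[s], genes_per_seq[s], s)
        motifs <- .spliceMotifPositions(exons)
        if (nrow(motifs))
            base[motifs$pos] <- motifs$base
        seq_chr <- paste0(base, collapse = "")
        vars <- .plantVariants(seq_chr, L, cfg, exons, seqids[s],
                               motifs$pos)

        hapA[s] <- seq_chr
        all_var[[s]] <- vars
        all_rep[[s]] <- rep_gr
        all_gene[[s]] <- exons
    }

    variants <- do.call(rbind, all_var)
    rownames(variants) <- NULL
    hapB <- vapply(seq_len(n_seq), function(s)
        applyVariants(hapA[s], all_var[[s]]), "")

    A <- Biostrings::DNAStringSet(hapA); names(A) <- seqids
    B <- Biostrings::DNAStringSet(hapB); names(B) <- seqids
    new("DiploidGenome", hapA = A, hapB = B, variants = variants,
        repeats = .concatGRanges(all_rep), genes = .concatGRanges(all_gene))
}

.concatGRanges <- function(lst) {
    lst <- lst[vapply(lst, length, 1L) > 0L]
    if (!length(lst))
        return(GenomicRanges::GRanges())
    do.call(c, lst)
}

## Tile repeat copies with random gaps (stick-breaking), so the realized
## repeat fraction matches the target even at high densities.
.placeRepeats <- function(base, L, cfg, consensus, seqid) {
    unit <- as.integer(cfg@repeat_unit_len)
    n_copies <- as.integer(round(cfg@repeat_fraction * L / unit))
    if (n_copies == 0L)
        return(GenomicRanges::GRanges())
    total_gap <- L - n_copies * unit
    if (total_gap < 0L)
        stop("configuration error: repeat_fraction infeasible for this length")
    gap_frac <- diff(c(0, sort(runif(n_copies)), 1))
    gaps <- floor(gap_frac[seq_len(n_copies)] * total_gap)
    starts <- cumsum(gaps) + (seq_len(n_copies) - 1L) * unit + 1L
    fam <- sample(rep(seq_len(cfg@n_repeat_families), length.out = n_copies))
    GenomicRanges::GRanges(seqid,
        IRanges::IRanges(start = starts, width = unit),
        family = fam)
}

## Place gene models in repeat-free gaps; error if they cannot fit.
.placeGenes <- function(L, cfg, rep_gr, seqid, n_genes, seq_index) {
    if (n_genes == 0L)
        return(GenomicRanges::GRanges())
    margin <- 100L
    occupied <- IRanges::reduce(IRanges::IRanges(
        start = pmax(GenomicRanges::start(rep_gr) - margin, 1L),
        end = pmin(GenomicRanges::end(rep_gr) + margin, L)))
    free <- IRanges::setdiff(IRanges::IRanges(1L, L), occupied)
    out <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
        nex <- sample(seq(cfg@exons_per_gene_range[1],
                          cfg@exons_per_gene_range[2]), 1L)
        exlen <- sample(seq(cfg@exon_len_range[1], cfg@exon_len_range[2]),
                        nex, replace = TRUE)
        over <- sum(exlen) %% 3L
        exlen[nex] <- exlen[nex] - over
        inlen <- if (nex > 1L)
            sample(seq(cfg@intron_len_range[1], cfg@intron_len_range[2]),
                   nex - 1L, replace = TRUE)
        else integer()
        span <- sum(exlen) + sum(inlen)
        ok <- which(IRanges::width(free) >= span + 2L * margin)
        if (!length(ok))
            stop("configuration error: gene models cannot fit ",
                 "(reduce n_genes or repeat_fraction)")
        gap <- ok[sample.int(length(ok), 1L)]
        gstart <- IRanges::start(free)[gap] + margin +
            sample.int(IRanges::width(free)[gap] - span - 2L * margin + 1L, 1L) - 1L
        starts <- gstart + cumsum(c(0L, head(exlen, -1L) + inlen))
        strand <- sample(c("+", "-"), 1L)
        out[[g]] <- GenomicRanges::GRanges(seqid,
            IRanges::IRanges(start = starts, width = exlen),
            strand = strand,
            gene_id = sprintf("gene%02d_%02d", seq_index, g),
            exon_rank = seq_len(nex))
        free <- IRanges::setdiff(free, IRanges::IRanges(
            pmax(gstart - margin, 1L), pmin(gstart + span + margin, L)))
    }
    do.call(c, out)
}

## Canonical splice-site dinucleotides for every intron: GT..AG in
## transcription direction (AC..CT on the plus strand for minus-strand
## genes).  Returns the positions and bases to set.
.spliceMotifPositions <- function(exons) {
    out <- list()
    for (g in unique(S4Vectors::mcols(exons)$gene_id)) {
        e <- exons[S4Vectors::mcols(exons)$gene_id == g]
        e <- e[order(GenomicRanges::start(e))]
        if (length(e) < 2L) next
        istart <- GenomicRanges::end(e)[-length(e)] + 1L
        iend <- GenomicRanges::start(e)[-1L] - 1L
        strand <- as.character(GenomicRanges::strand(e))[1L]
        for (i in seq_along(istart)) {
            if (iend[i] - istart[i] + 1L < 4L) next
            if (strand == "+") {
                pos <- c(istart[i], istart[i] + 1L, iend[i] - 1L, iend[i])
                bs <- c("G", "T", "A", "G")
            } else {
                pos <- c(istart[i], istart[i] + 1L, iend[i] - 1L, iend[i])
                bs <- c("C", "T", "A", "C")
            }
            out[[length(out) + 1L]] <- data.frame(pos = pos, base = bs,
                                                  stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(pos = integer(), base = character(),
                   stringsAsFactors = FALSE)
}

## Left-normalize one indel (del: seq removed starting at pos; ins: alt
## inserted after pos).  Returns the possibly shifted pos (and alt).
.normalizeIndel <- function(seq_chars, pos, len, type, alt) {
    if (type == "del") {
        while (pos > 1L && seq_chars[pos - 1L] == seq_chars[pos + len - 1L])
            pos <- pos - 1L
        list(pos = pos, alt = alt)
    } else {
        a <- strsplit(alt, "", fixed = TRUE)[[1L]]
        while (pos > 1L && seq_chars[pos] == a[len]) {
            a <- c(a[len], a[-len])
            pos <- pos - 1L
        }
        list(pos = pos, alt = paste0(a, collapse = ""))
    }
}

## Plant SNPs and indels on one sequence.  Indels avoid exons and keep a
## guard window from each other; SNPs avoid indel footprints only.
.plantVariants <- function(seq_chr, L, cfg, exons, seqid,
                           protected_pos = integer()) {
    guard <- 25L
    seq_chars <- strsplit(seq_chr, "", fixed = TRUE)[[1L]]
    exon_rng <- IRanges::reduce(IRanges::IRanges(
        pmax(GenomicRanges::start(exons) - 12L, 1L),
        pmin(GenomicRanges::end(exons) + 12L, L)))

    n_small <- rbinom(1L, L, cfg@small_indel_rate)
    n_large <- rbinom(1L, L, cfg@large_indel_rate)
    lens <- c(sample.int(20L, n_small, replace = TRUE,
                         prob = cfg@small_indel_len_dist),
              cfg@large_indel_min_len +
                  stats::rgeom(n_large, 1 / (1 + cfg@large_indel_mean_extra)))
    n_ind <- n_small + n_large
    ind <- NULL
    if (n_ind > 0L) {
        pos <- sample.int(L - max(lens) - guard - 1L, n_ind) + 1L
        type <- sample(c("ins", "del"), n_ind, replace = TRUE)
        o <- order(pos)
        pos <- pos[o]; lens <- lens[o]; type <- type[o]
        keep <- logical(n_ind)
        last_end <- -1e9
        for (i in seq_len(n_ind)) {
            span_end <- pos[i] + ifelse(type[i] == "del", lens[i], 0L)
            hits_exon <- length(IRanges::findOverlaps(
                IRanges::IRanges(pos[i] - 1L, span_end + 1L), exon_rng)) > 0L
            if (!hits_exon && pos[i] > last_end + guard) {
                keep[i] <- TRUE
                last_end <- span_end
            }
        }
        pos <- pos[keep]; lens <- lens[keep]; type <- type[keep]
        if (length(pos)) {
            ref <- character(length(pos)); alt <- character(length(pos))
            for (i in seq_along(pos)) {
                if (type[i] == "del") {
                    nrm <- .normalizeIndel(seq_chars, pos[i], lens[i], "del", "")
                    pos[i] <- nrm$pos
                    ref[i] <- substring(seq_chr, pos[i], pos[i] + lens[i] - 1L)
                    alt[i] <- ""
                } else {
                    a <- .randomDNA(lens[i])
                    nrm <- .normalizeIndel(seq_chars, pos[i], lens[i], "ins", a)
                    pos[i] <- nrm$pos
                    ref[i] <- ""
                    alt[i] <- nrm$alt
                }
            }
            ind <- data.frame(seqid = seqid, pos = as.integer(pos),
                              type = type, ref = ref, alt = alt,
                              stringsAsFactors = FALSE)
            ## normalization may have reordered or collided events
            ind <- ind[order(ind$pos), , drop = FALSE]
            del_end <- ind$pos + ifelse(ind$type == "del", nchar(ind$ref), 0L)
            ok <- c(TRUE, ind$pos[-1L] > head(del_end, -1L))
            ind <- ind[ok, , drop = FALSE]
        }
    }

    ## heterozygosity mosaic: the genome-wide SNP count is a plain
    ## Binomial(L, snp_rate) draw (calibration), distributed over blocks
    ## with normalized lognormal rate multipliers (local variation)
    n_snp <- rbinom(1L, L, cfg@snp_rate)
    snp <- NULL
    if (n_snp > 0L) {
        bl <- as.integer(cfg@het_block_len)
        nb <- max(1L, ceiling(L / bl))
        bstart <- (seq_len(nb) - 1L) * bl + 1L
        bend <- pmin(bstart + bl - 1L, L)
        bw <- bend - bstart + 1L
        if (cfg@het_cv > 0 && nb > 1L) {
            sdlog <- sqrt(log(1 + cfg@het_cv^2))
            m <- stats::rlnorm(nb, -sdlog^2 / 2, sdlog)
        } else m <- rep(1, nb)
        w <- m * bw
        nb_snp <- as.vector(stats::rmultinom(1L, n_snp, w / sum(w)))
        nb_snp <- pmin(nb_snp, bw)
        pos <- sort(unlist(lapply(seq_len(nb), function(b) {
            if (nb_snp[b] == 0L) return(integer())
            bstart[b] - 1L + sample.int(bw[b], nb_snp[b])
        })))
        if (length(protected_pos))
            pos <- setdiff(pos, protected_pos)
        if (!is.null(ind) && nrow(ind)) {
            ## keep SNPs clear of indel footprints so each planted event
            ## corresponds to one unambiguous alignment column / gap run:
            ## +/- 5 bases around small indels; a read length around
            ## large ones, whose mapping shadow (reads cannot span the
            ## event) would otherwise leave nearby SNPs with one-sided
            ## read support
            ind_len <- pmax(nchar(ind$ref), nchar(ind$alt))
            pad <- ifelse(ind_len >= cfg@large_indel_min_len,
                          as.integer(cfg@read_len) + 10L, 5L)
            bad <- IRanges::IRanges(ind$pos - pad,
                ind$pos + ifelse(ind$type == "del", nchar(ind$ref) - 1L, 0L) +
                    pad)
            hit <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), bad)
            if (length(hit))
                pos <- pos[-unique(S4Vectors::queryHits(hit))]
        }
        if (length(pos)) {
            refb <- seq_chars[pos]
            altb <- vapply(refb, function(b) sample(setdiff(.BASES, b), 1L), "")
            snp <- data.frame(seqid = seqid, pos = as.integer(pos),
                              type = "snp", ref = refb, alt = altb,
                              stringsAsFactors = FALSE)
        }
    }

    out <- rbind(ind, snp)
    if (is.null(out))
        return(data.frame(seqid = character(), pos = integer(),
                          type = character(), ref = character(),
                          alt = character(), stringsAsFactors = FALSE))
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-gene planted truth
#'
#' Summarizes, for each simulated gene, the spliced length and the planted
#' exonic SNP heterozygosity (the truth that per-gene heterozygosity
#' estimates are scored against).
#'
#' @param genome a [DiploidGenome-class]
#' @return \code{data.frame}: gene_id, seqid, strand, n_exons, spliced_len,
#'   het_snps, het_pct_true
#' @export
geneTruth <- function(genome) {
    ex <- geneModels(genome)
    if (!length(ex))
        return(data.frame(gene_id = character(), seqid = character(),
                          strand = character(), n_exons = integer(),
                          spliced_len = integer(), het_snps = integer(),
                          het_pct_true = numeric()))
    v <- plantedVariants(genome)
    snp <- v[v$type == "snp", , drop = FALSE]
    ids <- unique(S4Vectors::mcols(ex)$gene_id)
    out <- lapply(ids, function(g) {
        e <- ex[S4Vectors::mcols(ex)$gene_id == g]
        sid <- as.character(GenomicRanges::seqnames(e))[1L]
        sp <- snp[snp$seqid == sid, , drop = FALSE]
        n_het <- sum(IRanges::countOverlaps(
            IRanges::IRanges(sp$pos, sp$pos), IRanges::ranges(e)) > 0L)
        slen <- sum(IRanges::width(e))
        data.frame(gene_id = g, seqid = sid,
                   strand = as.character(GenomicRanges::strand(e))[1L],
                   n_exons = length(e), spliced_len = slen,
                   het_snps = n_het,
                   het_pct_true = 100 * n_het / slen,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
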