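#' Simulate a tiling path of BAC-like long fragments
#'
#' Lays \code{n_fragments} fragments of \code{fragment_len} bases along one
#' sequence, consecutive fragments sharing \code{fragment_overlap} bases of
#' ancestral (haplotype A) coordinates.  Each fragment is drawn from a
#' single randomly chosen haplotype, as for BAC clones picked from a
#' population pool.  The declared-overlap truth records every planted SNP
#' and indel distinguishing the two haplotypes inside each overlap (zero
#' when both fragments come from the same haplotype).
#'
#' @param genome a [DiploidGenome-class]
#' @param cfg the [SimConfig-class] used to build it
#' @return a [FragmentSet-class]
#' @export
simulateFragments <- function(genome, cfg) {
    if (cfg@fragment_overlap >= cfg@fragment_len)
        stop("fragment_overlap must be smaller than fragment_len")
    set.seed(cfg@seed + 3L)
    flen <- as.integer(cfg@fragment_len)
    ov <- as.integer(cfg@fragment_overlap)
    n <- as.integer(cfg@n_fragments)
    span <- n * flen - (n - 1L) * ov
    lens <- Biostrings::width(genome@hapA)
    sel <- which(lens >= span)
    if (!length(sel))
        stop("no sequence long enough for the requested tiling path (need ",
             span, " bases)")
    sid <- names(genome@hapA)[sel[1L]]
    len <- lens[sel[1L]]
    v <- genome@variants[genome@variants$seqid == sid, , drop = FALSE]
    ind <- v[v$type != "snp", , drop = FALSE]
    ## fragment ends must not cut through a planted indel, otherwise the
    ## declared overlap content at the junction is ambiguous
    guard <- IRanges::IRanges(ind$pos - 25L,
                              ind$pos + nchar(ind$ref) + 25L)
    for (try in 1:100) {
        offset <- sample.int(len - span + 1L, 1L)
        starts <- offset + (seq_len(n) - 1L) * (flen - ov)
        ends <- starts + flen - 1L
        bnd <- IRanges::IRanges(c(starts, ends), c(starts, ends))
        if (length(guard) == 0L ||
            length(IRanges::findOverlaps(bnd, guard)) == 0L)
            break
        if (try == 100L)
            stop("could not place fragment boundaries clear of indels")
    }
    haps <- sample(c("A", "B"), n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i)
        .extractHomologous(genome, sid, starts[i], ends[i], haps[i]), "")
    ids <- sprintf("frag%02d", seq_len(n))
    fs <- Biostrings::DNAStringSet(seqs)
    names(fs) <- ids
    truth <- data.frame(id = ids, hap = haps, seqid = sid,
                        startA = starts, endA = ends,
                        stringsAsFactors = FALSE)
    ovl <- lapply(seq_len(n - 1L), function(i) {
        os <- starts[i + 1L]
        oe <- ends[i]
        same <- haps[i] == haps[i + 1L]
        if (same) {
            n_snp <- 0L; n_ind <- 0L; n_big <- 0L
        } else {
            w <- v[v$pos >= os & v$pos <= oe, , drop = FALSE]
            n_snp <- sum(w$type == "snp")
            ind <- w[w$type != "snp", , drop = FALSE]
            n_ind <- nrow(ind)
            n_big <- sum(pmax(nchar(ind$ref), nchar(ind$alt)) >= 100L)
        }
        data.frame(id1 = ids[i], id2 = ids[i + 1L], startA = os, endA = oe,
                   n_snp = n_snp, n_indel = n_ind, n_indel_large = n_big,
                   stringsAsFactors = FALSE)
    })
    new("FragmentSet", sequences = fs, truth = truth,
        overlaps = do.call(rbind, ovl))
}

#' Fragment both haplotypes into contig-sized pieces
#'
#' Emulates an assembly in which every region assembled into both
#' haplotypes: haplotype A is cut into pieces of uniformly distributed
#' length, and haplotype B is cut at the homologous positions jittered by
#' up to \code{jitter} bases (assemblers break the two haplotypes of a
#' region at similar but not identical points).  The truth table carries
#' each piece's ancestral (haplotype A) interval, from which truly
#' allelic piece pairs can be derived with [truthAllelicPairs()].
#'
#' @param genome a [DiploidGenome-class]
#' @param min_len,max_len piece length range (bases)
#' @param jitter maximum breakpoint shift between the haplotypes (bases)
#' @param seed integer seed
#' @return list: \code{contigs} (named \code{DNAStringSet}) and
#'   \code{truth} (\code{data.frame}: id, hap, seqid, start, end in own
#'   haplotype coordinates, startA, endA ancestral)
#' @export
fragmentBothHaplotypes <- function(genome, min_len = 5000, max_len = 20000,
                                   jitter = 100, seed = 1) {
    set.seed(seed)
    out_seq <- character(0)
    out_id <- character(0)
    truth <- list()
    for (sid in names(genome@hapA)) {
        sA <- as.character(genome@hapA[[sid]])
        sB <- as.character(genome@hapB[[sid]])
        lenA <- nchar(sA); lenB <- nchar(sB)
        v <- genome@variants[genome@variants$seqid == sid, , drop = FALSE]
        cuts <- integer(0)
        p <- 0L
        while (p < lenA) {
            p <- min(p + sample(seq(min_len, max_len), 1L), lenA)
            cuts <- c(cuts, p)
        }
        cutsB <- liftA2B(head(cuts, -1L), v) +
            sample(seq(-jitter, jitter), length(cuts) - 1L, replace = TRUE)
        cutsB <- sort(pmin(pmax(cutsB, 1L), lenB - 1L))
        for (hap in c("A", "B")) {
            cl <- if (hap == "A") cuts else c(cutsB, lenB)
            s <- if (hap == "A") sA else sB
            starts <- c(1L, head(cl, -1L) + 1L)
            ends <- cl
            keep <- (ends - starts + 1L) >= min_len
            starts <- starts[keep]; ends <- ends[keep]
            if (!length(starts)) next
            ids <- sprintf("%s_%s_%03d", hap, sid, seq_along(starts))
            out_seq <- c(out_seq, substring(s, starts, ends))
            out_id <- c(out_id, ids)
            if (hap == "A") {
                sa <- starts; ea <- ends
            } else {
                sa <- liftB2A(starts, v); ea <- liftB2A(ends, v)
            }
            truth[[paste0(hap, sid)]] <- data.frame(
                id = ids, hap = hap, seqid = sid, start = starts, end = ends,
                startA = sa, endA = ea, stringsAsFactors = FALSE)
        }
    }
    contigs <- Biostrings::DNAStringSet(out_seq)
    names(contigs) <- out_id
    list(contigs = contigs, truth = do.call(rbind, truth))
}

#' Truly allelic piece pairs from fragmentation truth
#'
#' A pair counts as allelic when the ancestral intervals of the two
#' pieces mutually overlap by at least \code{min_mutual}.  When the
#' planted variant table is supplied, the pair's true alignment identity
#' is computed from the planted SNP and indel content (gap columns count
#' as mismatches) and pairs below \code{min_true_identity} can be
#' excluded: a collapse rule thresholded at 95\% identity does not aim
#' at pieces from mosaic blocks diverged beyond its reach, so recovery
#' should be scored against pairs the rule targets.
#'
#' @param truth the truth table of [fragmentBothHaplotypes()]
#' @param min_mutual minimum fraction of ancestral overlap required of
#'   \emph{both} pieces for the pair to count as allelic
#' @param variants planted variant table (needed for
#'   \code{min_true_identity})
#' @param min_true_identity minimum planted identity (percent);
#'   \code{NULL} keeps all pairs
#' @return \code{data.frame}: idA, idB, mutual overlap fractions, and
#'   true_identity when computed
#' @export
truthAllelicPairs <- function(truth, min_mutual = 0.95, variants = NULL,
                              min_true_identity = NULL) {
    a <- truth[truth$hap == "A", , drop = FALSE]
    b <- truth[truth$hap == "B", , drop = FALSE]
    out <- list()
    for (sid in unique(truth$seqid)) {
        aa <- a[a$seqid == sid, , drop = FALSE]
        bb <- b[b$seqid == sid, , drop = FALSE]
        if (!nrow(aa) || !nrow(bb)) next
        ha <- IRanges::findOverlaps(IRanges::IRanges(aa$startA, aa$endA),
                                    IRanges::IRanges(bb$startA, bb$endA))
        qi <- S4Vectors::queryHits(ha); si <- S4Vectors::subjectHits(ha)
        ovw <- pmin(aa$endA[qi], bb$endA[si]) -
            pmax(aa$startA[qi], bb$startA[si]) + 1L
        fa <- ovw / (aa$endA[qi] - aa$startA[qi] + 1L)
        fb <- ovw / (bb$endA[si] - bb$startA[si] + 1L)
        keep <- fa >= min_mutual & fb >= min_mutual
        if (!any(keep)) next
        df <- data.frame(idA = aa$id[qi][keep], idB = bb$id[si][keep],
                         fracA = fa[keep], fracB = fb[keep],
                         stringsAsFactors = FALSE)
        if (!is.null(variants)) {
            v <- variants[variants$seqid == sid, , drop = FALSE]
            os <- pmax(aa$startA[qi], bb$startA[si])[keep]
            oe <- pmin(aa$endA[qi], bb$endA[si])[keep]
            df$true_identity <- vapply(seq_len(nrow(df)), function(r) {
                w <- v[v$pos >= os[r] & v$pos <= oe[r], , drop = FALSE]
                len <- oe[r] - os[r] + 1
                n_snp <- sum(w$type == "snp")
                ins_b <- sum(nchar(w$alt[w$type == "ins"]))
                del_b <- sum(nchar(w$ref[w$type == "del"]))
                100 * (len - n_snp - del_b) / (len + ins_b)
            }, 1)
            if (!is.null(min_true_identity))
                df <- df[df$true_identity > min_true_identity, ,
                         drop = FALSE]
        }
        out[[sid]] <- df
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(idA = character(), idB = character(),
                   fracA = numeric(), fracB = numeric(),
                   stringsAsFactors = FALSE)
}

#' Simulate a partially collapsed assembly with known merged/split regions
#'
#' Cuts haplotype A into pieces at shared ancestral breakpoints; every
#' piece contributes its haplotype-A contig, and a random subset
#' (\code{split_fraction}) additionally contributes the homologous
#' haplotype-B contig.  Genes falling in duplicated ("split") pieces
#' behave like independently assembled haplotypes (halved read depth per
#' contig), genes in single-copy ("merged") pieces collect reads from both
#' haplotypes -- the two coverage regimes of a heterozygous assembly.
#'
#' The default split rule mirrors why regions assemble separately in
#' practice: the most divergent pieces split.  With \code{rule = "het"},
#' the \code{split_fraction} quantile of pieces with the highest planted
#' variant density is duplicated; \code{rule = "random"} assigns the
#' split state independently of divergence.
#'
#' @param genome a [DiploidGenome-class]
#' @param min_len,max_len piece length range (bases)
#' @param split_fraction fraction of pieces represented by both
#'   haplotypes
#' @param rule \code{"het"} (most divergent pieces split) or
#'   \code{"random"}
#' @param seed integer seed
#' @return list: \code{contigs} (named \code{DNAStringSet}) and
#'   \code{truth} (\code{data.frame}: id, hap, seqid, startA, endA, split)
#' @export
simulateSplitAssembly <- function(genome, min_len = 5000, max_len = 20000,
                                  split_fraction = 0.5,
                                  rule = c("het", "random"), seed = 1) {
    rule <- match.arg(rule)
    set.seed(seed)
    out_seq <- character(0)
    out <- list()
    k <- 0L
    for (sid in names(genome@hapA)) {
        s <- as.character(genome@hapA[[sid]])
        len <- nchar(s)
        cuts <- integer(0)
        p <- 0L
        while (p < len) {
            p <- min(p + sample(seq(min_len, max_len), 1L), len)
            cuts <- c(cuts, p)
        }
        starts <- c(1L, head(cuts, -1L) + 1L)
        ends <- cuts
        if (rule == "random") {
            split <- runif(length(starts)) < split_fraction
        } else {
            v <- genome@variants
            vp <- v$pos[v$seqid == sid]
            dens <- vapply(seq_along(starts), function(i)
                sum(vp >= starts[i] & vp <= ends[i]) /
                    (ends[i] - starts[i] + 1L), 1)
            thr <- stats::quantile(dens, 1 - split_fraction,
                                   names = FALSE)
            split <- dens > thr
        }
        for (i in seq_along(starts)) {
            k <- k + 1L
            idA <- sprintf("ctgA_%03d", k)
            out_seq <- c(out_seq, substring(s, starts[i], ends[i]))
            out[[length(out) + 1L]] <- data.frame(
                id = idA, hap = "A", seqid = sid, startA = starts[i],
                endA = ends[i], split = split[i], stringsAsFactors = FALSE)
            names(out_seq)[length(out_seq)] <- idA
            if (split[i]) {
                idB <- sprintf("ctgB_%03d", k)
                out_seq <- c(out_seq,
                             .extractHomologous(genome, sid, starts[i],
                                                ends[i], "B"))
                names(out_seq)[length(out_seq)] <- idB
                out[[length(out) + 1L]] <- data.frame(
                    id = idB, hap = "B", seqid = sid, startA = starts[i],
                    endA = ends[i], split = TRUE, stringsAsFactors = FALSE)
            }
        }
    }
    contigs <- Biostrings::DNAStringSet(out_seq)
    list(contigs = contigs, truth = do.call(rbind, out))
}
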