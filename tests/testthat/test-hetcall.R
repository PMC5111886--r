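test_that("codon classification handles canonical examples", {
    ## silent alanine change
    expect_equal(unname(classifySubstitutions("GCT", "GCC")), c(1, 0, 0))
    ## Ala -> Asp
    expect_equal(unname(classifySubstitutions("GCT", "GAT")), c(0, 1, 0))
    ## unchanged sequence
    expect_equal(unname(classifySubstitutions("ATGGCT", "ATGGCT")),
                 c(0, 0, 0))
    expect_error(classifySubstitutions("GCTA", "GCTT"), "three")
})

test_that("codon classification matches the brute-force oracle on 1000
           random pairs", {
    set.seed(51)
    for (rep in 1:1000) {
        n <- sample(c(5, 20, 60), 1)
        a <- randomSeq(3 * n)
        ch <- strsplit(a, "")[[1]]
        nmut <- sample(0:min(10, n), 1)
        pos <- sample(3 * n, nmut)
        for (p in pos)
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        b <- paste0(ch, collapse = "")
        got <- classifySubstitutions(a, b)
        want <- oracleSubstitutions(a, b)
        expect_identical(got[c("syn", "nonsyn")], want)
    }
})

test_that("in-frame indels are decomposed into events; frameshifts error", {
    a <- paste0("ATGGCTGCT", "CCCTTT", "GCTGATTAA")
    b <- paste0("ATGGCTGCT", "GCTGATTAA")  # 6 bp in-frame deletion
    got <- classifySubstitutions(a, b)
    expect_equal(unname(got["indel_events"]), 1)
    ## frame-disrupting deletion
    b2 <- paste0("ATGGCTGCT", "CCTTT", "GCTGATTAA")
    expect_error(classifySubstitutions(a, b2), "frameshift|three")
})

test_that("coverage-group boundary follows the geometric-mean rule", {
    depths <- c(g1 = 70, g2 = 80, g3 = 145, g4 = 160,
                g5 = sqrt(75 * 150), g6 = 400)
    cov <- data.frame(gene_id = names(depths), depth = unname(depths),
                      length = 1000)
    grp <- classifyCoverageGroups(cov, modes = c(75, 150))
    expect_equal(attr(grp, "boundary"), sqrt(75 * 150))
    expect_lt(abs(attr(grp, "boundary") - 106), 0.1)
    expect_equal(attr(grp, "upper"), 250)
    expect_equal(grp$group[grp$gene_id %in% c("g1", "g2")],
                 rep("split", 2))
    expect_equal(grp$group[grp$gene_id %in% c("g3", "g4")],
                 rep("merged", 2))
    ## a region exactly at the boundary goes to the high (merged) group
    expect_equal(grp$group[grp$gene_id == "g5"], "merged")
    expect_equal(grp$group[grp$gene_id == "g6"], "unassigned")
    ## mode detection from a bimodal sample
    set.seed(52)
    d2 <- data.frame(gene_id = paste0("x", 1:60),
                     depth = c(rnorm(30, 75, 6), rnorm(30, 150, 10)),
                     length = 1000)
    g2 <- classifyCoverageGroups(d2)
    md <- attr(g2, "modes")
    expect_lt(abs(md[1] - 75), 12)
    expect_lt(abs(md[2] - 150), 18)
    truth <- rep(c("split", "merged"), each = 30)
    expect_gte(mean(g2$group == truth), 0.9)
    ## unimodal: single group with a warning
    d3 <- data.frame(gene_id = paste0("y", 1:20),
                     depth = rnorm(20, 100, 5), length = 1000)
    expect_warning(g3 <- classifyCoverageGroups(d3), "unimodal")
    expect_equal(length(unique(g3$group)), 1)
})

test_that("multi-mapping transcript filters follow the locus rules", {
    mkpaf <- function(qname, qstart, qend, tname, tstart, tend, nm) {
        data.frame(qname = qname, qlen = 500, qstart = qstart, qend = qend,
                   strand = "+", tname = tname, tlen = 1e5,
                   tstart = tstart, tend = tend,
                   nmatch = qend - qstart + 1 - nm,
                   aln_len = qend - qstart + 1, mapq = 60, nm = nm,
                   cigar = sprintf("%dM", qend - qstart + 1),
                   stringsAsFactors = FALSE)
    }
    ## two allelic loci: both retained, least-mismatch first
    paf <- rbind(mkpaf("t1", 1, 500, "ctgB", 100, 599, 3),
                 mkpaf("t1", 1, 500, "ctgA", 200, 699, 12))
    got <- mapTranscriptsAndFilter(NULL, NULL, paf = paf)
    expect_equal(nrow(got$hits), 2)
    expect_equal(got$hits$tname[got$hits$locus_rank == 1], "ctgB")
    ## six loci: dropped as repetitive
    paf6 <- do.call(rbind, lapply(1:6, function(i)
        mkpaf("t2", 1, 500, paste0("ctg", i), 1, 500, i)))
    got6 <- mapTranscriptsAndFilter(NULL, NULL, paf = paf6)
    expect_equal(got6$dropped$reason, "too_many_loci")
    expect_false("t2" %in% got6$hits$qname)
    ## sub-30-bp placements are discarded; t3 becomes unplaced
    paf3 <- mkpaf("t3", 1, 25, "ctgA", 1, 25, 0)
    got3 <- mapTranscriptsAndFilter(NULL, NULL, paf = paf3)
    expect_equal(got3$dropped$reason, "unplaced")
    ## a short continuation fragment never outranks the main placement
    paf4 <- rbind(mkpaf("t4", 1, 400, "ctgA", 1000, 1399, 9),
                  mkpaf("t4", 401, 500, "ctgC", 1, 100, 0),
                  mkpaf("t4", 1, 400, "ctgB", 2000, 2399, 14))
    got4 <- mapTranscriptsAndFilter(NULL, NULL, paf = paf4)
    expect_equal(got4$hits$tname[got4$hits$locus_rank == 1], "ctgA")
    expect_equal(got4$hits$tname[got4$hits$locus_rank == 2], "ctgB")
})

test_that("pileup heterozygous-site rule enforces all thresholds", {
    pile <- data.frame(
        seqnames = "c",
        pos = c(1, 1, 2, 2, 3, 3, 4, 4, 5),
        nucleotide = c("A", "T", "A", "T", "A", "T", "A", "T", "G"),
        count = c(20, 15,  5,  4, 30,  1, 50, 11, 40),
        stringsAsFactors = FALSE)
    het <- HapDip:::.hetSitesFromPileup(pile, min_depth = 10,
                                        min_reads = 2, min_maf = 0.2)
    ## pos 1: clean het; pos 2: depth 9 < 10; pos 3: second allele on one
    ## read; pos 4: minor fraction 11/61 < 0.2; pos 5: homozygous
    expect_equal(het$pos, 1)
    expect_equal(het$a1, "A")
    expect_equal(het$a2, "T")
})

test_that("per-gene heterozygosity and population variance recover the
           planted rates on a partially collapsed assembly", {
    cfg <- SimConfig(haploid_length = 1.5e5, n_genes = 10,
                     coverage_per_haplotype = 30, seq_error_rate = 0.002,
                     snp_rate = 0.025, seed = 61)
    g <- simulateDiploid(cfg)
    rs <- simulateReads(g, cfg)
    tx <- simulateTranscripts(g, cfg)
    asm <- simulateSplitAssembly(g, min_len = 20000, max_len = 40000,
                                 split_fraction = 0.5, seed = 61)
    bam <- mapReads(asm$contigs, rs, tempfile(fileext = ".bam"))
    tab <- geneHetTable(asm$contigs, tx$transcripts, bam)
    expect_gte(nrow(tab), 8)
    expect_true(all(tab$het_percent >= 0 & tab$het_percent <= 100,
                    na.rm = TRUE))
    gt <- geneTruth(g)
    gt$gene_id <- paste0("tx_", gt$gene_id)
    m <- merge(tab, gt[, c("gene_id", "het_pct_true")])
    expect_lt(abs(mean(m$het_percent, na.rm = TRUE) /
                  mean(m$het_pct_true) - 1), 0.2)
    ## split group shows elevated heterozygosity (divergent pieces split)
    sm <- mean(m$het_percent[m$group == "split"], na.rm = TRUE)
    mm <- mean(m$het_percent[m$group == "merged"], na.rm = TRUE)
    expect_gt(sm, mm)
    ## population variance near the planted 0.8% of transcribed bases
    pv <- tab$popvar_percent[!is.na(tab$popvar_percent)]
    tot <- sum(tab$assessed)
    expect_lt(abs(mean(pv) - 0.8),
              100 * 3 * sqrt(0.008 * 0.992 / tot) + 0.15)
    ## syn + nonsyn never exceeds the number of called variant sites
    ok <- !is.na(tab$syn)
    expect_true(all(tab$syn[ok] + tab$nonsyn[ok] <= tab$het_sites[ok]))
})

test_that("a gene with no variants and error-free reads calls zero
           heterozygosity", {
    cfg <- SimConfig(haploid_length = 6e4, n_genes = 4, snp_rate = 0,
                     small_indel_rate = 0, large_indel_rate = 0,
                     coverage_per_haplotype = 30, seq_error_rate = 0,
                     seed = 62)
    g <- simulateDiploid(cfg)
    rs <- simulateReads(g, cfg)
    tx <- simulateTranscripts(g, cfg, rate = 0)
    asm <- simulateSplitAssembly(g, min_len = 20000, max_len = 30000,
                                 split_fraction = 0, seed = 62)
    bam <- mapReads(asm$contigs, rs, tempfile(fileext = ".bam"))
    hits <- mapTranscriptsAndFilter(asm$contigs, tx$transcripts)$hits
    het <- callHeterozygosity(hits, asm$contigs, tx$transcripts, bam)
    expect_true(all(het$het_percent == 0))
    pv <- populationVariance(hits, asm$contigs, tx$transcripts, bam)
    expect_true(all(pv$popvar_percent == 0))
})
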