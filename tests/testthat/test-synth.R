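test_that("zero-rate configuration yields identical haplotypes", {
    cfg <- SimConfig(haploid_length = 2e4, snp_rate = 0,
                     small_indel_rate = 0, large_indel_rate = 0,
                     repeat_fraction = 0.05, n_genes = 2, seed = 1)
    g <- simulateDiploid(cfg)
    expect_identical(as.character(hapA(g)), as.character(hapB(g)))
    expect_equal(nrow(plantedVariants(g)), 0)
})

test_that("realized SNP count is binomially calibrated at 1 Mb", {
    cfg <- SimConfig(haploid_length = 1e6, snp_rate = 0.025, seed = 1,
                     n_genes = 10)
    g <- simulateDiploid(cfg)
    n_snp <- sum(plantedVariants(g)$type == "snp")
    expect_lt(abs(n_snp - 25000), 3 * sqrt(1e6 * 0.025 * 0.975))
    ## repeat fraction within +/- 10% of target
    rep_frac <- sum(IRanges::width(plantedRepeats(g))) / 1e6
    expect_lt(abs(rep_frac - 0.2) / 0.2, 0.1)
})

test_that("large indels at or above the minimum length are planted", {
    cfg <- SimConfig(haploid_length = 5e5, large_indel_rate = 2e-5,
                     n_genes = 0, seed = 3)
    ## expected count 10 >= 5, so at least one must appear
    g <- simulateDiploid(cfg)
    v <- plantedVariants(g)
    big <- pmax(nchar(v$ref), nchar(v$alt))
    expect_gte(sum(big >= 100), 1)
})

test_that("variant table reconstructs haplotype B and stays sorted", {
    for (seed in 1:3) {
        cfg <- SimConfig(haploid_length = 3e4, n_genes = 2,
                         small_indel_rate = 1e-3, large_indel_rate = 1e-4,
                         seed = seed)
        g <- simulateDiploid(cfg)
        v <- plantedVariants(g)
        expect_false(is.unsorted(v$pos[v$seqid == "chr1"], strictly = TRUE))
        b <- applyVariants(as.character(hapA(g)[[1]]),
                           v[v$seqid == "chr1", ])
        expect_identical(b, as.character(hapB(g)[[1]]))
        ## length bookkeeping: net indel delta explains the size change
        delta <- sum(nchar(v$alt[v$type == "ins"])) -
            sum(nchar(v$ref[v$type == "del"]))
        expect_equal(nchar(b), nchar(as.character(hapA(g)[[1]])) + delta)
    }
})

test_that("liftover matches a brute-force provenance oracle", {
    for (seed in 1:3) {
        cfg <- SimConfig(haploid_length = 3000, n_genes = 0,
                         repeat_fraction = 0, snp_rate = 0.02,
                         small_indel_rate = 0.004, large_indel_rate = 2e-4,
                         seed = seed)
        g <- simulateDiploid(cfg)
        v <- plantedVariants(g)
        A <- as.character(hapA(g)[[1]])
        B <- as.character(hapB(g)[[1]])
        ## per-base provenance of haplotype B (NA = inserted base)
        prov <- integer(0); cur <- 1L
        for (i in seq_len(nrow(v))) {
            if (v$type[i] == "snp") next
            if (v$type[i] == "del") {
                prov <- c(prov, seq(cur, v$pos[i] - 1L))
                cur <- v$pos[i] + nchar(v$ref[i])
            } else {
                prov <- c(prov, seq(cur, v$pos[i]),
                          rep(NA_integer_, nchar(v$alt[i])))
                cur <- v$pos[i] + 1L
            }
        }
        prov <- c(prov, seq(cur, nchar(A)))
        expect_equal(length(prov), nchar(B))
        pos <- sort(sample.int(nchar(A), 150))
        got <- liftA2B(pos, v)
        want <- vapply(pos, function(p) {
            w <- which(prov == p)
            if (length(w)) w[1]
            else max(which(prov < p & !is.na(prov)))
        }, 1L)
        expect_equal(got, want)
        posb <- sort(sample.int(nchar(B), 150))
        got <- liftB2A(posb, v)
        want <- vapply(posb, function(p) {
            if (!is.na(prov[p])) return(prov[p])
            while (is.na(prov[p])) p <- p - 1L
            prov[p]
        }, 1L)
        expect_equal(got, want)
    }
})

test_that("gene models are well-formed with canonical splice sites", {
    g <- smallGenome()$genome
    ex <- geneModels(g)
    A <- as.character(hapA(g)[[1]])
    for (id in unique(S4Vectors::mcols(ex)$gene_id)) {
        e <- ex[S4Vectors::mcols(ex)$gene_id == id]
        e <- e[order(GenomicRanges::start(e))]
        w <- IRanges::width(e)
        expect_equal(sum(w) %% 3, 0)
        expect_true(all(GenomicRanges::start(e) >= 1))
        expect_true(all(GenomicRanges::end(e) <= nchar(A)))
        if (length(e) > 1) {
            ## non-overlapping exons
            expect_true(all(GenomicRanges::start(e)[-1] >
                            GenomicRanges::end(e)[-length(e)]))
            strand <- as.character(GenomicRanges::strand(e))[1]
            is1 <- GenomicRanges::end(e)[1] + 1
            ie1 <- GenomicRanges::start(e)[2] - 1
            intron <- substring(A, is1, ie1)
            if (strand == "+") {
                expect_equal(substring(intron, 1, 2), "GT")
                expect_equal(substring(intron, nchar(intron) - 1), "AG")
            } else {
                expect_equal(substring(intron, 1, 2), "CT")
                expect_equal(substring(intron, nchar(intron) - 1), "AC")
            }
        }
    }
})

test_that("infeasible gene configuration raises a configuration error", {
    cfg <- SimConfig(haploid_length = 5000, n_genes = 30, seed = 1)
    expect_error(simulateDiploid(cfg), "configuration error")
})

test_that("error-free reads are exact substrings at calibrated depth", {
    sg <- smallGenome()
    rs <- simulateReads(sg$genome, sg$cfg)
    tr <- readTruth(rs)
    ## depth within 5% per haplotype
    for (h in c("A", "B")) {
        sel <- tr$hap == h
        bases <- 2 * sum(sel) * sg$cfg@read_len
        depth <- bases / nchar(as.character(hapA(sg$genome)[[1]]))
        expect_lt(abs(depth - 30) / 30, 0.05)
    }
    idx <- sample(nrow(tr), 25)
    for (i in idx) {
        src <- if (tr$hap[i] == "A") hapA(sg$genome) else hapB(sg$genome)
        frag <- substring(as.character(src[[tr$seqid[i]]]),
                          tr$frag_start[i], tr$frag_end[i])
        r1 <- as.character(rs@reads1[[i]])
        m1 <- if (tr$flipped[i])
            oracleRevcomp(substring(frag, nchar(frag) - 149, nchar(frag)))
        else substring(frag, 1, 150)
        expect_identical(r1, m1)
    }
})

test_that("read simulation is byte-deterministic and error-calibrated", {
    sg <- smallGenome()
    d1 <- tempfile(); d2 <- tempfile()
    rs1 <- simulateReads(sg$genome, sg$cfg)
    writeReadsFastq(rs1, d1)
    rs2 <- simulateReads(sg$genome, sg$cfg)
    writeReadsFastq(rs2, d2)
    expect_identical(readLines(paste0(d1, "_1.fastq")),
                     readLines(paste0(d2, "_1.fastq")))
    expect_identical(unname(tools::md5sum(paste0(d1, "_2.fastq"))),
                     unname(tools::md5sum(paste0(d2, "_2.fastq"))))
    ## substitution errors at the configured rate
    rs_err <- simulateReads(sg$genome, sg$cfg, error_rate = 0.01)
    diffs <- sum(as.character(rs_err@reads1) != as.character(rs1@reads1))
    expect_gt(diffs, 0)
    n1 <- sum(vapply(seq_len(200), function(i) {
        a <- strsplit(as.character(rs1@reads1[[i]]), "")[[1]]
        b <- strsplit(as.character(rs_err@reads1[[i]]), "")[[1]]
        sum(a != b)
    }, 1))
    rate <- n1 / (200 * 150)
    expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / (200 * 150)))
})

test_that("transcripts splice exons of one haplotype; extra variants are
           genuine third alleles", {
    sg <- smallGenome()
    ## no population variants: transcript equals the spliced product
    tx0 <- simulateTranscripts(sg$genome, sg$cfg, rate = 0)
    ex <- geneModels(sg$genome)
    for (i in seq_along(tx0$transcripts)) {
        o <- tx0$origin[i, ]
        e <- ex[S4Vectors::mcols(ex)$gene_id == o$gene_id]
        e <- e[order(GenomicRanges::start(e))]
        v <- plantedVariants(sg$genome)
        src <- if (o$hap == "A") as.character(hapA(sg$genome)[[1]])
               else as.character(hapB(sg$genome)[[1]])
        st <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
        if (o$hap == "B") {
            st <- liftA2B(st, v); en <- liftA2B(en, v)
        }
        spliced <- paste0(substring(src, st, en), collapse = "")
        if (o$strand == "-") spliced <- oracleRevcomp(spliced)
        expect_identical(as.character(tx0$transcripts[[i]]), spliced)
    }
    ## planted population variants: calibrated, never a haplotype allele
    tx <- simulateTranscripts(sg$genome, sg$cfg, rate = 0.008)
    tt <- tx$truth
    total <- sum(tx$origin$spliced_len)
    expect_lt(abs(nrow(tt) - 0.008 * total),
              3 * sqrt(total * 0.008 * 0.992) + 1)
    expect_true(all(tt$alt != tt$refA))
    expect_true(all(tt$alt != tt$refB))
    ## truth round-trips through TSV
    f <- tempfile(fileext = ".tsv")
    writeTruthTsv(tt, f)
    expect_equal(readTruthTsv(f), tt)
})

test_that("fragment tiling declares exactly the planted differences", {
    cfg <- SimConfig(haploid_length = 1e5, n_genes = 0,
                     n_fragments = 4, fragment_len = 2.5e4,
                     fragment_overlap = 6e3, seq_error_rate = 0, seed = 7)
    g <- simulateDiploid(cfg)
    fr <- simulateFragments(g, cfg)
    tr <- fragmentTruth(fr)
    ov <- declaredOverlaps(fr)
    v <- plantedVariants(g)
    expect_equal(nrow(tr), 4)
    expect_true(all(tr$hap %in% c("A", "B")))
    for (i in seq_len(nrow(ov))) {
        h1 <- tr$hap[tr$id == ov$id1[i]]
        h2 <- tr$hap[tr$id == ov$id2[i]]
        inside <- v$pos >= ov$startA[i] & v$pos <= ov$endA[i]
        if (h1 == h2) {
            expect_equal(ov$n_snp[i], 0)
            expect_equal(ov$n_indel[i], 0)
        } else {
            expect_equal(ov$n_snp[i], sum(inside & v$type == "snp"))
            expect_equal(ov$n_indel[i], sum(inside & v$type != "snp"))
        }
    }
    ## overlap must be shorter than the fragment
    expect_error(SimConfig(fragment_len = 1000, fragment_overlap = 1000),
                 "fragment_overlap")
})

test_that("invalid configurations are rejected", {
    expect_error(SimConfig(snp_rate = 1.5), "rates")
    expect_error(SimConfig(repeat_fraction = 1), "repeat_fraction")
})
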