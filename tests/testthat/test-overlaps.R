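## One small simulated fragment scenario shared by several blocks: four
## BAC-like fragments over a repeat-free diploid, error-free reads.
overlapScenario <- function() {
    fixture("overlap_scenario", function() {
        cfg <- SimConfig(haploid_length = 1e5, n_genes = 0,
                         repeat_fraction = 0, coverage_per_haplotype = 40,
                         seq_error_rate = 0, snp_rate = 0.02,
                         small_indel_rate = 3e-4, large_indel_rate = 1e-4,
                         n_fragments = 4, fragment_len = 2.2e4,
                         fragment_overlap = 6e3, seed = 71)
        g <- simulateDiploid(cfg)
        fr <- simulateFragments(g, cfg)
        rs <- simulateReads(g, cfg)
        bams <- stats::setNames(lapply(fragmentTruth(fr)$id, function(id)
            mapReads(fragmentSeqs(fr)[id], rs,
                     tempfile(fileext = ".bam"), max_clip = 0)),
            fragmentTruth(fr)$id)
        list(cfg = cfg, genome = g, frags = fr, reads = rs, bams = bams)
    })
}

test_that("exact terminal overlaps are detected from sequence alone", {
    set.seed(72)
    core <- randomSeq(5000)
    f1 <- paste0(randomSeq(8000), core)
    f2 <- paste0(core, randomSeq(8000))
    frs <- Biostrings::DNAStringSet(c(a = f1, b = f2, c = randomSeq(9000)))
    ov <- findFragmentOverlaps(frs, window = 7000)
    expect_equal(nrow(ov), 1)
    expect_equal(ov$id1, "a")
    expect_equal(ov$id2, "b")
    expect_equal(ov$length, 5000)
    expect_equal(ov$start2, 1)
    expect_equal(ov$end1, 13000)
})

test_that("detected overlaps of a simulated tiling path match the
           declared truth within 10 bases", {
    sc <- overlapScenario()
    declared <- declaredOverlapCoords(sc$frags, sc$genome)
    got <- findFragmentOverlaps(fragmentSeqs(sc$frags), window = 8000)
    for (i in seq_len(nrow(declared))) {
        row <- got[got$id1 == declared$id1[i] &
                   got$id2 == declared$id2[i], ]
        expect_equal(nrow(row), 1)
        expect_lt(abs(row$length - declared$length[i]), 11)
        expect_lt(abs(row$start2 - declared$start2[i]), 11)
    }
})

test_that("overlap SNP/indel accounting equals planted truth with
           error-free reads", {
    sc <- overlapScenario()
    ov <- declaredOverlaps(sc$frags)
    co <- declaredOverlapCoords(sc$frags, sc$genome)
    tr <- fragmentTruth(sc$frags)
    v <- plantedVariants(sc$genome)
    for (i in seq_len(nrow(co))) {
        i1 <- co$id1[i]; i2 <- co$id2[i]
        rep <- analyzeOverlap(fragmentSeqs(sc$frags)[[i1]],
                              fragmentSeqs(sc$frags)[[i2]],
                              co[i, ], sc$bams[[i1]], sc$bams[[i2]],
                              i1, i2)
        expect_equal(rep@snps_pairwise, ov$n_snp[i])
        expect_equal(nrow(rep@indels), ov$n_indel[i])
        expect_equal(rep@n_indels_large, ov$n_indel_large[i])
        expect_equal(rep@snps_both_supported, ov$n_snp[i])
        ## read pileups reveal every planted SNP in the overlap window,
        ## whichever haplotypes the two fragments carry
        truth_rs <- sum(v$type == "snp" & v$pos >= ov$startA[i] &
                        v$pos <= ov$endA[i])
        expect_equal(rep@snps_read_supported, truth_rs)
        expect_equal(rep@third_allele_sites, 0)
        ## identity consistent with SNP and gap columns
        expect_equal(rep@identity,
                     100 * (rep@overlap_length - rep@snps_pairwise -
                            sum(rep@indels$length)) / rep@overlap_length)
    }
})

test_that("overlap accounting is symmetric in fragment order", {
    sc <- overlapScenario()
    co <- declaredOverlapCoords(sc$frags, sc$genome)
    i <- which.max(declaredOverlaps(sc$frags)$n_snp)
    i1 <- co$id1[i]; i2 <- co$id2[i]
    fwd <- analyzeOverlap(fragmentSeqs(sc$frags)[[i1]],
                          fragmentSeqs(sc$frags)[[i2]], co[i, ],
                          sc$bams[[i1]], sc$bams[[i2]], i1, i2)
    rev_co <- data.frame(start1 = co$start2[i], end1 = co$end2[i],
                         start2 = co$start1[i], end2 = co$end1[i],
                         length = co$length[i])
    rev <- analyzeOverlap(fragmentSeqs(sc$frags)[[i2]],
                          fragmentSeqs(sc$frags)[[i1]], rev_co,
                          sc$bams[[i2]], sc$bams[[i1]], i2, i1)
    expect_equal(rev@snps_pairwise, fwd@snps_pairwise)
    expect_equal(rev@snps_both_supported, fwd@snps_both_supported)
    expect_equal(rev@third_allele_sites, fwd@third_allele_sites)
    expect_equal(nrow(rev@indels), nrow(fwd@indels))
    expect_equal(sort(rev@indels$length), sort(fwd@indels$length))
    ## insertion/deletion labels swap between orientations
    expect_equal(sum(rev@indels$type == "ins1"),
                 sum(fwd@indels$type == "ins2"))
})

test_that("short overlaps are refused as uninformative", {
    sc <- overlapScenario()
    co <- declaredOverlapCoords(sc$frags, sc$genome)[1, ]
    co$end1 <- co$start1 + 50; co$end2 <- co$start2 + 50; co$length <- 51
    expect_error(analyzeOverlap(fragmentSeqs(sc$frags)[[co$id1]],
                                fragmentSeqs(sc$frags)[[co$id2]], co),
                 "100")
})

test_that("per-fragment heterozygosity recovers the planted rate from
           diploid reads and vanishes for haploid reads", {
    sc <- overlapScenario()
    tr <- fragmentTruth(sc$frags)
    v <- plantedVariants(sc$genome)
    id <- tr$id[1]
    fh <- fragmentHet(fragmentSeqs(sc$frags)[[id]], sc$bams[[id]], id)
    n_true <- sum(v$type == "snp" & v$pos >= tr$startA[1] &
                  v$pos <= tr$endA[1])
    len <- nchar(as.character(fragmentSeqs(sc$frags)[[id]]))
    expect_lt(abs(fh$het_sites - n_true), 3 * sqrt(n_true) + 3)
    expect_equal(fh$popvar_sites, 0)
    expect_false(fh$low_conf)
    ## reads from a single haplotype: no heterozygosity
    rs_hapA <- simulateReads(sc$genome, sc$cfg, haplotypes = "A")
    bamA <- mapReads(fragmentSeqs(sc$frags)[id], rs_hapA,
                     tempfile(fileext = ".bam"), max_clip = 0)
    fhA <- fragmentHet(fragmentSeqs(sc$frags)[[id]], bamA, id)
    expect_lt(fhA$het_percent, 0.02)
})

test_that("population variants carried by reads surface as third alleles
           and extra fragment alleles", {
    sc <- overlapScenario()
    ov <- declaredOverlaps(sc$frags)
    co <- declaredOverlapCoords(sc$frags, sc$genome)
    tr <- fragmentTruth(sc$frags)
    v <- plantedVariants(sc$genome)
    ## plant 8 population alleles at heterozygous sites inside the first
    ## overlap window: a third allele requires more than two alleles at
    ## the site, so it must stack on an existing polymorphism
    snp_in <- v[v$type == "snp" & v$pos > ov$startA[1] + 200 &
                v$pos < ov$endA[1] - 200, ]
    stopifnot(nrow(snp_in) >= 8)
    sel <- snp_in[round(seq(1, nrow(snp_in), length.out = 8)), ]
    pv <- data.frame(seqid = "chr1", pos = sel$pos,
                     alt = vapply(seq_len(8), function(i)
                         setdiff(c("A", "C", "G", "T"),
                                 c(sel$ref[i], sel$alt[i]))[1], ""),
                     freq = 0.35, stringsAsFactors = FALSE)
    rs_pv <- simulateReads(sc$genome, sc$cfg, pop_variants = pv)
    i1 <- co$id1[1]; i2 <- co$id2[1]
    b1 <- mapReads(fragmentSeqs(sc$frags)[i1], rs_pv,
                   tempfile(fileext = ".bam"), max_clip = 0)
    b2 <- mapReads(fragmentSeqs(sc$frags)[i2], rs_pv,
                   tempfile(fileext = ".bam"), max_clip = 0)
    rep <- analyzeOverlap(fragmentSeqs(sc$frags)[[i1]],
                          fragmentSeqs(sc$frags)[[i2]], co[1, ],
                          b1, b2, i1, i2)
    expect_gte(rep@third_allele_sites, 1)
    fh <- fragmentHet(fragmentSeqs(sc$frags)[[i1]], b1, i1)
    expect_gte(fh$popvar_sites, 1)
})
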