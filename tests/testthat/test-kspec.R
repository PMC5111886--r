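test_that("k-mer counting matches a brute-force oracle", {
    set.seed(5)
    reads <- vapply(1:40, function(i) randomSeq(60), "")
    ## duplicate some reads so multiplicities above 1 occur
    reads <- c(reads, reads[1:10])
    sp <- buildSpectrum(reads, k = 15)
    oracle <- oracleKmerHistogram(reads, 15)
    got <- spectrumHistogram(sp)
    expect_equal(got$multiplicity, oracle$multiplicity)
    expect_equal(got$count, oracle$count)
    expect_equal(totalKmers(sp),
                 sum(oracle$multiplicity * oracle$count))
})

test_that("spectrum is strand-canonical", {
    set.seed(6)
    reads <- vapply(1:30, function(i) randomSeq(80), "")
    rc <- vapply(reads, oracleRevcomp, "")
    s1 <- buildSpectrum(reads, k = 21)
    s2 <- buildSpectrum(rc, k = 21)
    expect_equal(spectrumHistogram(s1), spectrumHistogram(s2))
})

test_that("k-mer size is validated", {
    expect_error(buildSpectrum("ACGTACGTACGTACGTACGT", k = 16), "odd")
    expect_error(buildSpectrum("ACGTACGTACGTACGTACGT", k = 13), "odd|15")
})

test_that("homozygous coverage peak sits at the expected k-mer depth", {
    ## error-free reads from a homozygous genome: histogram mode at
    ## about coverage * (read_len - k + 1) / read_len
    seqs <- Biostrings::DNAStringSet(randomSeq(5e4, seed = 11))
    names(seqs) <- "chr1"
    rs <- simulateReadsFrom(seqs, coverage = 50, read_len = 150, seed = 2)
    sp <- buildSpectrum(rs, k = 31)
    h <- spectrumHistogram(sp)
    h <- h[h$multiplicity > 2, ]
    mode <- h$multiplicity[which.max(h$count)]
    expect_lt(abs(mode - 50 * (150 - 31 + 1) / 150), 4)
})

test_that("diploid spectra are bimodal with a half-coverage het peak", {
    cfg <- SimConfig(haploid_length = 1e5, n_genes = 0, snp_rate = 0.025,
                     coverage_per_haplotype = 30, seq_error_rate = 0,
                     seed = 12)
    g <- simulateDiploid(cfg)
    rs <- simulateReads(g, cfg)
    sp <- buildSpectrum(rs, 31)
    pk <- detectPeaks(sp)
    expect_false(is.na(hetPeak(pk)))
    expect_gt(peakRatio(pk), 0.4)
    expect_lt(peakRatio(pk), 0.6)
    expect_true(errorCutoff(pk) < hetPeak(pk))
    ## genome size within 10%
    est <- estimateGenomeSize(sp, pk)
    expect_lt(abs(est - 1e5) / 1e5, 0.1)
    ## homozygous genome: no het peak
    cfg0 <- SimConfig(haploid_length = 1e5, n_genes = 0, snp_rate = 0,
                      small_indel_rate = 0, large_indel_rate = 0,
                      coverage_per_haplotype = 30, seq_error_rate = 0,
                      seed = 13)
    g0 <- simulateDiploid(cfg0)
    rs0 <- simulateReads(g0, cfg0)
    pk0 <- detectPeaks(buildSpectrum(rs0, 31))
    expect_true(is.na(hetPeak(pk0)))
    expect_true(is.na(peakRatio(pk0)))
})

test_that("pure-noise histograms never yield fabricated peaks", {
    h <- data.frame(multiplicity = 1:40,
                    count = round(1e6 * 0.5^(1:40)) + 1)
    sp <- new("KmerSpectrum", k = 31, histogram = h,
              total_kmers = sum(h$multiplicity * h$count))
    expect_error(detectPeaks(sp), "noise|minimum")
})

test_that("genome-size estimate is coverage-invariant", {
    seqs <- Biostrings::DNAStringSet(randomSeq(6e4, seed = 14))
    names(seqs) <- "chr1"
    est <- vapply(c(30, 60), function(cov) {
        rs <- simulateReadsFrom(seqs, coverage = cov, seed = 3)
        sp <- buildSpectrum(rs, 31)
        estimateGenomeSize(sp, detectPeaks(sp))
    }, 1)
    expect_lt(abs(est[2] - est[1]) / est[1], 0.05)
})

test_that("k-mer intersection behaves at its extremes and between
           libraries of one genome", {
    set.seed(15)
    reads <- vapply(1:200, function(i) randomSeq(100), "")
    same <- intersectKmers(reads, reads, k = 21, min_count = 1)
    expect_equal(same$jaccard, 1.0)
    other <- vapply(1:200, function(i) randomSeq(100), "")
    disj <- intersectKmers(reads, other, k = 21, min_count = 1)
    expect_lt(disj$jaccard, 0.01)
    ## two independent libraries from the same diploid genome
    cfg <- SimConfig(haploid_length = 8e4, n_genes = 0,
                     coverage_per_haplotype = 15, seq_error_rate = 0.002,
                     seed = 16)
    g <- simulateDiploid(cfg)
    libA <- simulateReads(g, cfg)
    cfgB <- cfg; cfgB@seed <- 99
    libB <- simulateReads(g, cfgB)
    j <- intersectKmers(libA, libB, k = 21)
    expect_gte(j$jaccard, 0.9)
    expect_error(intersectKmers(character(0), reads), "empty")
})

test_that("branch classification separates variant and repeat signal", {
    base <- function(snp, nfam, seed) {
        SimConfig(haploid_length = 8e4, n_genes = 0, snp_rate = snp,
                  small_indel_rate = 0, large_indel_rate = 0,
                  repeat_fraction = if (nfam > 0) 0.15 else 0,
                  n_repeat_families = max(nfam, 1),
                  coverage_per_haplotype = 25, seq_error_rate = 0,
                  seed = seed)
    }
    ## at very low heterozygosity the het peak is too small to detect;
    ## the coverage structure is known, so supply it (het = hom / 2)
    diploidPeaks <- function(pk) {
        if (!is.na(hetPeak(pk))) return(pk)
        new("SpectrumPeaks", error_cutoff = errorCutoff(pk),
            het_peak = homPeak(pk) / 2, hom_peak = homPeak(pk),
            peak_ratio = 0.5)
    }
    run <- function(cfg) {
        g <- simulateDiploid(cfg)
        rs <- simulateReads(g, cfg)
        sp <- buildSpectrum(rs, 31)
        pk <- diploidPeaks(detectPeaks(sp))
        classifyBranches(rs, 31, pk)
    }
    ## homozygous, repeat-free: essentially no branching
    cfg0 <- base(0, 0, 21)
    g0 <- simulateDiploid(cfg0)
    rs0 <- simulateReads(g0, cfg0)
    sp0 <- buildSpectrum(rs0, 31)
    pk0 <- suppressWarnings(detectPeaks(sp0))
    br0 <- suppressWarnings(classifyBranches(rs0, 31, pk0))
    expect_lt(br0@repeat_branch_rate, 1e-3)
    ## het branches grow with heterozygosity
    br_hi <- run(base(0.025, 0, 22))
    br_lo <- run(base(0.001, 0, 22))
    expect_gt(br_hi@variant_branch_rate, br_lo@variant_branch_rate)
    ## a high-copy repeat family inflates repeat branches
    cfg_rep <- base(0.001, 1, 23)
    br_rep <- run(cfg_rep)
    expect_gt(br_rep@repeat_branch_rate,
              5 * max(br_lo@repeat_branch_rate, 1e-6))
})

test_that("variant-branch rate is monotone in heterozygosity", {
    rates <- c(0.001, 0.005, 0.01, 0.025)
    got <- vapply(rates, function(r) {
        cfg <- SimConfig(haploid_length = 8e4, n_genes = 0, snp_rate = r,
                         small_indel_rate = 0, large_indel_rate = 0,
                         repeat_fraction = 0, coverage_per_haplotype = 25,
                         seq_error_rate = 0, seed = 31)
        g <- simulateDiploid(cfg)
        rs <- simulateReads(g, cfg)
        sp <- buildSpectrum(rs, 31)
        pk <- detectPeaks(sp)
        if (is.na(hetPeak(pk)))
            pk <- new("SpectrumPeaks", error_cutoff = errorCutoff(pk),
                      het_peak = homPeak(pk) / 2, hom_peak = homPeak(pk),
                      peak_ratio = 0.5)
        classifyBranches(rs, 31, pk)@variant_branch_rate
    }, 1)
    expect_true(all(diff(got) >= 0))
})
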