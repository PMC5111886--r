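test_that("identical and diverged contig pairs report expected identity", {
    set.seed(41)
    a <- randomSeq(3000)
    contigs <- Biostrings::DNAStringSet(c(c1 = a, c2 = a))
    cand <- pairwiseSimilarity(contigs, method = "dp")
    expect_equal(nrow(cand), 1)
    expect_equal(cand$identity, 100)
    expect_equal(cand$overlap_frac, 1.0)
    ## 5% random substitutions -> identity about 95
    ch <- strsplit(a, "")[[1]]
    pos <- sample(3000, 150)
    for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
    contigs2 <- Biostrings::DNAStringSet(c(c1 = a,
                                           c2 = paste0(ch, collapse = "")))
    cand2 <- pairwiseSimilarity(contigs2, method = "dp")
    expect_lt(abs(cand2$identity - 95), 0.5)
    ## the minimap2 engine agrees closely
    cand2m <- pairwiseSimilarity(contigs2, method = "minimap2")
    expect_lt(abs(cand2m$identity - cand2$identity), 0.5)
    ## unrelated contigs share no seeds: nothing reported
    contigs3 <- Biostrings::DNAStringSet(c(c1 = a, c2 = randomSeq(3000)))
    expect_equal(nrow(pairwiseSimilarity(contigs3, method = "dp")), 0)
    expect_error(pairwiseSimilarity(
        Biostrings::DNAStringSet(c(x = a, x = a))), "duplicate")
})

test_that("allelic-pair selection thresholds and cluster resolution", {
    lengths <- c(A = 12000, B = 10000, C = 9000, D = 5000, E = 5000)
    cand <- data.frame(
        idA = c("A", "B", "D", "A"),
        idB = c("B", "C", "E", "D"),
        identity = c(97, 96.5, 98, 94),
        aln_len = c(10000, 9000, 5000, 5000),
        overlap_frac = c(0.99, 0.97, 1.0, 0.99),
        stringsAsFactors = FALSE)
    sel <- selectAllelicPairs(cand, lengths)
    ## identity 94 pair excluded; chain A~B~C resolves to primary A
    expect_equal(sel$primary[sel$secondary == "B"], "A")
    expect_equal(sel$primary[sel$secondary == "C"], "A")
    ## equal-length tie broken lexicographically
    expect_equal(sel$primary[sel$secondary == "E"], "D")
    expect_false("D" %in% sel$secondary)
    expect_equal(sel, oracleResolve(
        cand[cand$identity > 95 & cand$overlap_frac > 0.95, ], lengths))
    ## inclusive mode admits a boundary pair
    cand95 <- data.frame(idA = "A", idB = "B", identity = 95,
                         aln_len = 100, overlap_frac = 0.99)
    expect_equal(nrow(selectAllelicPairs(cand95, lengths)), 0)
    expect_equal(nrow(selectAllelicPairs(cand95, lengths,
                                         inclusive = TRUE)), 1)
})

test_that("cluster resolution matches exhaustive search on random cases", {
    set.seed(42)
    for (rep in 1:20) {
        n <- sample(4:12, 1)
        ids <- LETTERS[seq_len(n)]
        lengths <- stats::setNames(sample(1000:9999, n), ids)
        npair <- sample(2:min(8, n * (n - 1) / 2), 1)
        pr <- t(replicate(npair, sort(sample(ids, 2))))
        cand <- data.frame(idA = pr[, 1], idB = pr[, 2],
                           identity = 97, aln_len = 1000,
                           overlap_frac = 0.99,
                           stringsAsFactors = FALSE)
        cand <- unique(cand)
        got <- selectAllelicPairs(cand, lengths)
        want <- oracleResolve(cand, lengths)
        expect_equal(got, want)
    }
})

test_that("collapse partitions and conserves sequence", {
    set.seed(43)
    contigs <- Biostrings::DNAStringSet(
        stats::setNames(vapply(1:6, function(i)
            randomSeq(sample(2000:4000, 1)), ""),
            paste0("ctg", 1:6)))
    ## empty pair set: everything primary
    res0 <- collapseContigs(contigs, data.frame(secondary = character(),
                                                primary = character()))
    expect_setequal(primaryContigs(res0), names(contigs))
    expect_equal(length(secondaryContigs(res0)), 0)
    pairs <- data.frame(secondary = c("ctg2", "ctg4"),
                        primary = c("ctg1", "ctg3"),
                        stringsAsFactors = FALSE)
    pairs$primary <- names(contigs)[order(-Biostrings::width(contigs))][1:2]
    pairs$secondary <- setdiff(names(contigs), pairs$primary)[1:2]
    res <- collapseContigs(contigs, pairs)
    expect_setequal(c(primaryContigs(res), secondaryContigs(res)),
                    names(contigs))
    lens <- res@lengths
    expect_equal(sum(lens[primaryContigs(res)]) +
                 sum(lens[secondaryContigs(res)]),
                 sum(Biostrings::width(contigs)))
    expect_error(collapseContigs(contigs,
        data.frame(secondary = "nope", primary = "ctg1")), "unknown")
})

test_that("lowering the identity threshold never removes secondaries", {
    sg <- smallGenome()
    fb <- fragmentBothHaplotypes(sg$genome, min_len = 5000,
                                 max_len = 15000, seed = 44)
    cand <- pairwiseSimilarity(fb$contigs)
    lens <- stats::setNames(as.numeric(Biostrings::width(fb$contigs)),
                            names(fb$contigs))
    n_sec <- vapply(c(98, 95, 90, 80), function(thr)
        nrow(selectAllelicPairs(cand, lens, min_identity = thr)), 1)
    expect_true(all(diff(n_sec) >= 0))
})

test_that("allelic pairs of a fragmented diploid are recovered", {
    cfg <- SimConfig(haploid_length = 2e5, n_genes = 0, seed = 45)
    g <- simulateDiploid(cfg)
    fb <- fragmentBothHaplotypes(g, seed = 45)
    res <- collapseAssembly(fb$contigs)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- allelicMap(res)
    rec <- key(m$secondary, m$primary)
    tp <- truthAllelicPairs(fb$truth, 0.95, plantedVariants(g), 95)
    tru <- key(tp$idA, tp$idB)
    expect_gte(mean(tru %in% rec), 0.9)
    relax <- truthAllelicPairs(fb$truth, 0.85)
    expect_gte(mean(rec %in% key(relax$idA, relax$idB)), 0.9)
})

test_that("N50 statistics match the brute-force definition", {
    expect_equal(assemblyStats(c(100, 200, 300, 400))$N50, 300)
    bruteN <- function(lens, frac) {
        l <- sort(lens, decreasing = TRUE)
        tot <- sum(l)
        for (i in seq_along(l))
            if (sum(l[1:i]) >= frac * tot) return(l[i])
    }
    set.seed(46)
    for (rep in 1:25) {
        lens <- sample(50:5000, sample(1:40, 1), replace = TRUE)
        st <- assemblyStats(lens)
        expect_equal(st$N50, bruteN(lens, 0.5))
        expect_equal(st$N90, bruteN(lens, 0.9))
        expect_equal(st$N10, bruteN(lens, 0.1))
    }
})

test_that("reintegration produces the three record classes with summary", {
    lengths <- stats::setNames(c(4000, 3500, 3000, 2500, 2000),
                               paste0("c", 1:5))
    res <- new("CollapseResult", primary = c("c1", "c2", "c3"),
               secondary = c("c4", "c5"),
               mapping = data.frame(secondary = c("c4", "c5"),
                                    primary = c("c1", "c2"),
                                    stringsAsFactors = FALSE),
               lengths = lengths, params = list(min_identity = 95,
                                                min_overlap = 0.95))
    ## identity scaffolding: each primary its own scaffold
    fin <- reintegrate(stats::setNames(as.list(c("c1", "c2", "c3")),
                                       c("s1", "s2", "s3")), res)
    counts <- table(fin$records$class)
    expect_equal(unname(counts["scaffold"]), 3)
    expect_false("unplaced_contig" %in% fin$records$class)
    expect_equal(unname(counts["hetero_contig"]), 2)
    expect_equal(names(fin$summary),
                 c("class", "n", "N90", "N50", "N10", "sum_length",
                   "max_length"))
    ## unplaced primaries are reported as such
    fin2 <- reintegrate(list(s1 = c("c1", "c2")), res)
    expect_equal(sum(fin2$records$class == "unplaced_contig"), 1)
    expect_error(reintegrate(list(s1 = "c9"), res), "primary")
    expect_error(reintegrate(list(s1 = "c1", s2 = "c1"), res),
                 "more than one")
})
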