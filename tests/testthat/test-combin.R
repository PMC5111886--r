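test_that("exon-array combination counts match known loci", {
    ## crustacean-type Dscam locus: Ig2 x Ig3 x Ig7 arrays
    expect_identical(countCombinations(c(13, 20, 13)), 3380)
    ## insect-type locus with a transmembrane array
    expect_identical(countCombinations(c(12, 48, 33, 2)), 38016)
    expect_identical(countCombinations(1), 1)
})

test_that("counting agrees with exhaustive enumeration", {
    expect_equal(nrow(enumerateIsoforms(c(2, 2))), 4)
    e <- enumerateIsoforms(c(13, 20, 13), cap = 1e4)
    expect_equal(nrow(e), 3380)
    ## duplicate-free, lexicographically ordered
    expect_equal(anyDuplicated(e), 0)
    expect_false(is.unsorted(e[, 1]))
    set.seed(7)
    for (rep in 1:10) {
        arrays <- sample(1:5, sample(1:4, 1), replace = TRUE)
        expect_equal(countCombinations(arrays),
                     nrow(enumerateIsoforms(arrays)))
    }
})

test_that("appending an array multiplies the count", {
    set.seed(8)
    for (rep in 1:10) {
        arrays <- sample(1:30, sample(1:4, 1), replace = TRUE)
        n <- sample(1:30, 1)
        expect_equal(countCombinations(c(arrays, n)),
                     countCombinations(arrays) * n)
    }
})

test_that("degenerate specifications are rejected", {
    expect_error(countCombinations(integer()), "empty")
    expect_error(countCombinations(c(3, 0)), "positive")
    expect_error(enumerateIsoforms(c(100, 100, 100), cap = 1e4),
                 "refusing")
})
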