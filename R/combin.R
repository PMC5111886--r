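## Hypervariable exon-array combinatorics: splice-isoform counting for
## Dscam-like loci whose immunoglobulin domains are encoded by tandem
## arrays of mutually exclusive alternative exons (splicing selects
## exactly one exon per array).

#' Count splice-isoform combinations of mutually exclusive exon arrays
#'
#' One exon is chosen from each array independently, so the number of
#' possible isoforms is the product of the per-array alternative counts.
#' A crustacean Dscam-like locus with arrays of 13, 20 and 13 alternative
#' exons yields 3380 combinations; an insect-like locus with 12, 48, 33
#' and 2 yields 38,016.
#'
#' @param arrays integer vector: number of mutually exclusive alternative
#'   exons per array, ordered 5' to 3'
#' @return the number of combinations (numeric, exact for products below
#'   2^53)
#' @examples
#' countCombinations(c(13, 20, 13))   # 3380
#' countCombinations(c(12, 48, 33, 2))  # 38016
#' @export
countCombinations <- function(arrays) {
    if (!length(arrays))
        stop("empty exon-array specification")
    if (any(arrays < 1) || any(arrays != round(arrays)))
        stop("array sizes must be positive integers")
    prod(as.numeric(arrays))
}

#' Enumerate all exon-choice tuples of an exon-array locus
#'
#' Complete lexicographic enumeration (first array varies slowest); used
#' as the brute-force cross-check of [countCombinations()].
#'
#' @param arrays integer vector of per-array alternative counts
#' @param cap refuse enumeration above this many combinations
#' @return integer matrix, one row per isoform, one column per array
#' @export
enumerateIsoforms <- function(arrays, cap = 1e6) {
    n <- countCombinations(arrays)
    if (n > cap)
        stop("refusing to enumerate ", n, " combinations (cap ", cap, ")")
    grid <- expand.grid(rev(lapply(arrays, seq_len)),
                        KEEP.OUT.ATTRS = FALSE)
    m <- as.matrix(grid[, rev(seq_along(arrays)), drop = FALSE])
    dimnames(m) <- list(NULL, paste0("array", seq_along(arrays)))
    m[do.call(order, as.data.frame(m)), , drop = FALSE]
}
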