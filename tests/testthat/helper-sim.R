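## Shared fixtures: everything is generated in code, cached per test run
## so expensive objects are built once even when several files use them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixture_env))
        assign(name, builder(), envir = .fixture_env)
    get(name, envir = .fixture_env)
}

## A small diploid genome with genes, used across modules.
smallGenome <- function() {
    fixture("small_genome", function() {
        cfg <- SimConfig(haploid_length = 1e5, n_genes = 6,
                         coverage_per_haplotype = 30,
                         seq_error_rate = 0, seed = 101)
        list(cfg = cfg, genome = simulateDiploid(cfg))
    })
}

## Random DNA as a character string (independent of package internals).
randomSeq <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Reverse complement for oracle code, independent of the package.
oracleRevcomp <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

## Brute-force codon oracle, independent of the package implementation
## (seqinr translation tables).
oracleSubstitutions <- function(a, b) {
    ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    syn <- 0L; nonsyn <- 0L
    for (i in seq_along(ca)) {
        if (ca[i] == cb[i]) next
        aa1 <- seqinr::translate(strsplit(ca[i], "")[[1]])
        aa2 <- seqinr::translate(strsplit(cb[i], "")[[1]])
        if (identical(aa1, aa2)) syn <- syn + 1L else nonsyn <- nonsyn + 1L
    }
    c(syn = syn, nonsyn = nonsyn)
}

## Brute-force canonical k-mer histogram (oracle for the C++ counter).
oracleKmerHistogram <- function(seqs, k) {
    tab <- new.env(parent = emptyenv())
    for (s in seqs) {
        n <- nchar(s)
        if (n < k) next
        for (i in seq_len(n - k + 1)) {
            km <- substring(s, i, i + k - 1)
            if (grepl("[^ACGT]", km)) next
            rc <- oracleRevcomp(km)
            canon <- if (km <= rc) km else rc
            cur <- tab[[canon]]
            tab[[canon]] <- if (is.null(cur)) 1L else cur + 1L
        }
    }
    counts <- unlist(as.list(tab))
    if (is.null(counts))
        return(data.frame(multiplicity = integer(), count = numeric()))
    h <- table(counts)
    data.frame(multiplicity = as.integer(names(h)),
               count = as.numeric(h))
}
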