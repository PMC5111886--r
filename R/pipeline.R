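## End-to-end pipeline orchestration from a single configuration (R list
## or YAML file): simulation, k-mer diagnostics, allelic collapse,
## per-gene heterozygosity/population variance, fragment-overlap
## accounting and exon-array combinatorics, with a JSON manifest.

#' Run the full simulation-and-analysis pipeline
#'
#' Stages (each optional, controlled by the config): \code{synth} builds
#' the diploid genome, reads, transcripts and BAC-like fragments and
#' writes them with their truth; \code{kspec} builds the k-mer spectrum,
#' detects peaks, estimates genome size and classifies branches;
#' \code{collapse} fragments both haplotypes, detects allelic pairs and
#' collapses the assembly; \code{hetcall} maps reads and transcripts to a
#' partially collapsed assembly and produces the per-gene table;
#' \code{overlaps} analyzes declared fragment overlaps; \code{combin}
#' counts exon-array combinations.  A manifest (stages, parameters, file
#' checksums) is written as JSON; deterministic stages are byte-identical
#' under the same seed.
#'
#' @param config list or path to a YAML file.  Recognized blocks:
#'   \code{sim} (arguments of [SimConfig()]), \code{outdir},
#'   \code{stages} (character subset of stages above), \code{kspec}
#'   (\code{k}), \code{collapse} (\code{min_identity},
#'   \code{min_overlap}), \code{combin} (\code{arrays}).
#' @return invisibly, a list: per-stage results plus \code{manifest}
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    outdir <- config$outdir %||% tempfile("pipeline")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stages <- config$stages %||%
        c("synth", "kspec", "collapse", "hetcall", "overlaps", "combin")
    cfg <- do.call(SimConfig, config$sim %||% list())
    manifest <- list(parameters = config, stages = list())
    results <- list(config = cfg)
    log <- function(...) message("[pipeline] ", ...)

    stage_files <- function(stage, paths) {
        manifest$stages[[stage]] <<- list(
            stage = stage,
            files = as.list(vapply(paths, identity, "")),
            md5 = as.list(tools::md5sum(unlist(paths))))
    }

    genome <- NULL; reads <- NULL; tx <- NULL; frags <- NULL
    if ("synth" %in% stages) {
        log("synth: simulating genome, reads, transcripts, fragments")
        genome <- simulateDiploid(cfg)
        reads <- simulateReads(genome, cfg)
        tx <- simulateTranscripts(genome, cfg)
        frags <- simulateFragments(genome, cfg)
        gdir <- file.path(outdir, "synth")
        paths <- writeGenomeTruth(genome, gdir)
        rp <- writeReadsFastq(reads, file.path(gdir, "reads"))
        Biostrings::writeXStringSet(tx$transcripts,
                                    file.path(gdir, "transcripts.fasta"))
        writeTruthTsv(tx$truth, file.path(gdir, "transcript_truth.tsv"))
        fp <- writeFragments(frags, gdir)
        stage_files("synth", c(paths, rp,
                               file.path(gdir, "transcripts.fasta"),
                               file.path(gdir, "transcript_truth.tsv"), fp))
        results$genome <- genome
        results$reads <- reads
        results$transcripts <- tx
        results$fragments <- frags
    }

    if ("kspec" %in% stages) {
        k <- config$kspec$k %||% 31
        log("kspec: spectrum and peaks at k=", k)
        sp <- buildSpectrum(reads, k)
        pk <- detectPeaks(sp)
        gs <- estimateGenomeSize(sp, pk)
        br <- classifyBranches(reads, k, pk)
        kdir <- file.path(outdir, "kspec")
        dir.create(kdir, showWarnings = FALSE)
        writeSpectrumTsv(sp, file.path(kdir, "spectrum.tsv"))
        writePeaksJson(pk, file.path(kdir, "peaks.json"))
        jsonlite::write_json(list(
            sampled_kmers = br@sampled_kmers,
            variant_branch_rate = br@variant_branch_rate,
            repeat_branch_rate = br@repeat_branch_rate,
            genome_size_estimate = gs), file.path(kdir, "branches.json"),
            auto_unbox = TRUE, na = "null")
        stage_files("kspec", file.path(kdir, c("spectrum.tsv", "peaks.json",
                                               "branches.json")))
        results$spectrum <- sp
        results$peaks <- pk
        results$genome_size <- gs
        results$branches <- br
    }

    if ("collapse" %in% stages) {
        log("collapse: fragmenting haplotypes and collapsing")
        fb <- fragmentBothHaplotypes(genome, seed = cfg@seed + 4L)
        res <- collapseAssembly(fb$contigs,
            min_identity = config$collapse$min_identity %||% 95,
            min_overlap = config$collapse$min_overlap %||% 0.95)
        cdir <- file.path(outdir, "collapse")
        paths <- writeCollapse(fb$contigs, res, cdir)
        stage_files("collapse", paths)
        results$fragmented <- fb
        results$collapse <- res
    }

    if ("hetcall" %in% stages) {
        log("hetcall: per-gene heterozygosity and population variance")
        asm <- simulateSplitAssembly(genome, min_len = 20000,
                                     max_len = 40000,
                                     seed = cfg@seed + 5L)
        bam <- mapReads(asm$contigs, reads,
                        file.path(outdir, "hetcall.bam"))
        tab <- geneHetTable(asm$contigs, tx$transcripts, bam)
        hdir <- file.path(outdir, "hetcall")
        dir.create(hdir, showWarnings = FALSE)
        writeTruthTsv(tab, file.path(hdir, "gene_het.tsv"))
        stage_files("hetcall", file.path(hdir, "gene_het.tsv"))
        results$assembly <- asm
        results$gene_het <- tab
    }

    if ("overlaps" %in% stages) {
        log("overlaps: fragment-overlap polymorphism accounting")
        co <- declaredOverlapCoords(frags, genome)
        reports <- list()
        for (i in seq_len(nrow(co))) {
            i1 <- co$id1[i]; i2 <- co$id2[i]
            b1 <- mapReads(frags@sequences[i1], reads,
                           file.path(outdir, paste0("ov_", i1, ".bam")),
                           max_clip = 0)
            b2 <- mapReads(frags@sequences[i2], reads,
                           file.path(outdir, paste0("ov_", i2, ".bam")),
                           max_clip = 0)
            reports[[i]] <- analyzeOverlap(frags@sequences[[i1]],
                frags@sequences[[i2]], co[i, , drop = FALSE],
                b1, b2, i1, i2)
        }
        odir <- file.path(outdir, "overlaps")
        dir.create(odir, showWarnings = FALSE)
        writeTruthTsv(overlapTable(reports),
                      file.path(odir, "overlap_table.tsv"))
        stage_files("overlaps", file.path(odir, "overlap_table.tsv"))
        results$overlap_reports <- reports
    }

    if ("combin" %in% stages) {
        arrays <- config$combin$arrays %||% c(13, 20, 13)
        results$combinations <- countCombinations(arrays)
        jdir <- file.path(outdir, "combin")
        dir.create(jdir, showWarnings = FALSE)
        jsonlite::write_json(list(arrays = arrays,
                                  combinations = results$combinations),
                             file.path(jdir, "combinations.json"),
                             auto_unbox = TRUE)
        stage_files("combin", file.path(jdir, "combinations.json"))
    }

    manifest_path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         na = "null")
    results$manifest <- manifest
    results$outdir <- outdir
    invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a pipeline run
#'
#' Collates the headline numbers of each completed stage (peak ratio and
#' genome-size estimate, collapse partition counts and N50s, coverage
#' group mean heterozygosity and population variance, overlap totals,
#' isoform combinations) into one JSON-serializable list and a text
#' rendering.  Group means over an empty gene table are reported as
#' absent, not zero.
#'
#' @param results the list returned by [runPipeline()]
#' @param json_path optional path to write the JSON summary
#' @param text_path optional path to write the text summary
#' @return the summary list (invisibly if written to file)
#' @export
summarizePipeline <- function(results, json_path = NULL, text_path = NULL) {
    s <- list(seed = results$config@seed)
    warn <- character()
    if (!is.null(results$peaks)) {
        s$kspec <- list(error_cutoff = results$peaks@error_cutoff,
                        het_peak = results$peaks@het_peak,
                        hom_peak = results$peaks@hom_peak,
                        peak_ratio = results$peaks@peak_ratio,
                        genome_size_estimate = results$genome_size)
    } else warn <- c(warn, "kspec stage missing")
    if (!is.null(results$collapse)) {
        r <- results$collapse
        s$collapse <- list(n_primary = length(r@primary),
                           n_secondary = length(r@secondary),
                           primary_stats =
                               assemblyStats(r@lengths[r@primary]),
                           secondary_stats =
                               assemblyStats(r@lengths[r@secondary]))
    } else warn <- c(warn, "collapse stage missing")
    if (!is.null(results$gene_het)) {
        tab <- results$gene_het
        gm <- function(g, col) {
            x <- tab[[col]][tab$group == g]
            x <- x[!is.na(x)]
            if (length(x)) mean(x) else NULL
        }
        s$hetcall <- list(
            n_genes = nrow(tab),
            mean_het_split = gm("split", "het_percent"),
            mean_het_merged = gm("merged", "het_percent"),
            mean_popvar_split = gm("split", "popvar_percent"),
            mean_popvar_merged = gm("merged", "popvar_percent"))
        s$hetcall$split_exceeds_merged <-
            !is.null(s$hetcall$mean_het_split) &&
            !is.null(s$hetcall$mean_het_merged) &&
            s$hetcall$mean_het_split > s$hetcall$mean_het_merged
    } else warn <- c(warn, "hetcall stage missing")
    if (!is.null(results$overlap_reports)) {
        ot <- overlapTable(results$overlap_reports)
        s$overlaps <- list(n_pairs = nrow(ot),
                           total_snps = sum(ot$snps_pairwise),
                           total_indels = sum(ot$n_indels),
                           total_indels_large = sum(ot$n_indels_large))
    } else warn <- c(warn, "overlaps stage missing")
    if (!is.null(results$combinations))
        s$combin <- list(combinations = results$combinations)
    if (length(warn)) s$warnings <- warn
    if (!is.null(json_path))
        jsonlite::write_json(s, json_path, auto_unbox = TRUE, na = "null",
                             digits = NA)
    if (!is.null(text_path)) {
        con <- file(text_path, "w")
        on.exit(close(con))
        writeLines(.summaryText(s), con)
    }
    if (is.null(json_path) && is.null(text_path)) s else invisible(s)
}

.summaryText <- function(s) {
    fmt <- function(x) if (is.null(x)) "absent" else
        format(signif(x, 4), big.mark = ",")
    out <- c(sprintf("Pipeline summary (seed %s)", s$seed))
    if (!is.null(s$kspec))
        out <- c(out, sprintf(
            "  k-mer peaks: het %s / hom %s (ratio %s); genome size %s bp",
            fmt(s$kspec$het_peak), fmt(s$kspec$hom_peak),
            fmt(s$kspec$peak_ratio), fmt(s$kspec$genome_size_estimate)))
    if (!is.null(s$collapse))
        out <- c(out, sprintf(
            "  collapse: %d primary / %d secondary (primary N50 %s)",
            s$collapse$n_primary, s$collapse$n_secondary,
            fmt(s$collapse$primary_stats$N50)))
    if (!is.null(s$hetcall))
        out <- c(out, sprintf(
            "  genes: %d; het%% split %s vs merged %s; popvar%% %s / %s",
            s$hetcall$n_genes, fmt(s$hetcall$mean_het_split),
            fmt(s$hetcall$mean_het_merged),
            fmt(s$hetcall$mean_popvar_split),
            fmt(s$hetcall$mean_popvar_merged)))
    if (!is.null(s$overlaps))
        out <- c(out, sprintf(
            "  overlaps: %d pairs, %d SNPs, %d indels (%d >= 100 bp)",
            s$overlaps$n_pairs, s$overlaps$total_snps,
            s$overlaps$total_indels, s$overlaps$total_indels_large))
    if (!is.null(s$combin))
        out <- c(out, sprintf("  exon-array combinations: %s",
                              fmt(s$combin$combinations)))
    if (!is.null(s$warnings))
        out <- c(out, paste("  warning:", s$warnings))
    out
}
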