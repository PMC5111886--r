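#' Build a simulation configuration
#'
#' Constructor with defaults describing the high-heterozygosity diploid
#' regime the package targets: 2.5\% per-base SNP heterozygosity, rare
#' small (1-20 bp) and large (>= 100 bp) haplotype indels, interspersed
#' repeat families, gene models with exons and introns, 150 nt paired-end
#' reads at 75-fold coverage per haplotype, and transcripts carrying extra
#' population-level variants at 0.8\% of bases.
#'
#' @param haploid_length total haploid genome length (bases)
#' @param n_sequences number of sequences composing the haploid genome
#' @param snp_rate genome-wide mean per-base SNP heterozygosity between
#'   haplotypes
#' @param het_block_len block length of the heterozygosity mosaic (bases)
#' @param het_cv coefficient of variation of per-block SNP-rate
#'   multipliers (0 = spatially uniform heterozygosity)
#' @param small_indel_rate per-base rate of 1-20 bp indels between
#'   haplotypes
#' @param small_indel_len_dist 20 probability weights for lengths 1..20
#'   (default: geometric decay)
#' @param large_indel_rate per-base rate of large indels
#' @param large_indel_min_len minimum large-indel length (bases)
#' @param large_indel_mean_extra mean geometric excess length beyond the
#'   minimum
#' @param repeat_fraction fraction of the haploid genome covered by
#'   interspersed repeats
#' @param repeat_unit_len repeat unit length (bases)
#' @param n_repeat_families number of repeat families
#' @param repeat_divergence substitution divergence of planted copies from
#'   the family consensus
#' @param n_genes number of gene models
#' @param exons_per_gene_range min/max exons per gene
#' @param exon_len_range min/max exon length (bases)
#' @param intron_len_range min/max intron length (bases)
#' @param read_len read length (bases)
#' @param fragment_mean,fragment_sd insert-size mean and SD (bases)
#' @param coverage_per_haplotype fold coverage generated from each
#'   haplotype
#' @param seq_error_rate per-base substitution sequencing error rate
#' @param population_variant_rate per-base rate of extra population
#'   variants on transcripts
#' @param n_fragments number of BAC-like fragments in the tiling path
#' @param fragment_len BAC-like fragment length (bases)
#' @param fragment_overlap ancestral overlap between consecutive fragments
#'   (bases)
#' @param seed integer random seed
#' @return a [SimConfig-class] object
#' @examples
#' cfg <- SimConfig(haploid_length = 1e5, n_genes = 5, seed = 1)
#' cfg
#' @export
SimConfig <- function(haploid_length = 1e6,
                      n_sequences = 1,
                      snp_rate = 0.025,
                      het_block_len = 3e4,
                      het_cv = 0.6,
                      small_indel_rate = 2e-4,
                      small_indel_len_dist = 0.65^(0:19),
                      large_indel_rate = 1e-5,
                      large_indel_min_len = 100,
                      large_indel_mean_extra = 50,
                      repeat_fraction = 0.2,
                      repeat_unit_len = 500,
                      n_repeat_families = 10,
                      repeat_divergence = 0.03,
                      n_genes = 20,
                      exons_per_gene_range = c(3, 8),
                      exon_len_range = c(120, 300),
                      intron_len_range = c(100, 500),
                      read_len = 150,
                      fragment_mean = 400,
                      fragment_sd = 40,
                      coverage_per_haplotype = 75,
                      seq_error_rate = 0.005,
                      population_variant_rate = 0.008,
                      n_fragments = 5,
                      fragment_len = 4e4,
                      fragment_overlap = 5e3,
                      seed = 1) {
    new("SimConfig",
        haploid_length = haploid_length,
        n_sequences = n_sequences,
        snp_rate = snp_rate,
        het_block_len = het_block_len,
        het_cv = het_cv,
        small_indel_rate = small_indel_rate,
        small_indel_len_dist = small_indel_len_dist / sum(small_indel_len_dist),
        large_indel_rate = large_indel_rate,
        large_indel_min_len = large_indel_min_len,
        large_indel_mean_extra = large_indel_mean_extra,
        repeat_fraction = repeat_fraction,
        repeat_unit_len = repeat_unit_len,
        n_repeat_families = n_repeat_families,
        repeat_divergence = repeat_divergence,
        n_genes = n_genes,
        exons_per_gene_range = exons_per_gene_range,
        exon_len_range = exon_len_range,
        intron_len_range = intron_len_range,
        read_len = read_len,
        fragment_mean = fragment_mean,
        fragment_sd = fragment_sd,
        coverage_per_haplotype = coverage_per_haplotype,
        seq_error_rate = seq_error_rate,
        population_variant_rate = population_variant_rate,
        n_fragments = n_fragments,
        fragment_len = fragment_len,
        fragment_overlap = fragment_overlap,
        seed = seed)
}
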