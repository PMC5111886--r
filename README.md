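# HapDip

Heterozygosity and haplotype diagnostics for highly heterozygous diploid
genomes.

## The problem

In outbred invertebrate lines, the two haplotypes of a single diploid
individual can differ at 1–3% of bases, with frequent small indels and
occasional polynucleotide indels of ≥ 100 bp. At that divergence an
assembler no longer merges the haplotypes of many regions: the assembly
becomes a mosaic of *merged* regions (one contig, reads from both
haplotypes, ~2c coverage) and *split* regions (two allelic contigs at
~1c each). HapDip implements, as tested R functions, the diagnostics and
accounting this regime requires:

* **Simulation with ground truth** (`SimConfig`, `simulateDiploid`,
  `simulateReads`, `simulateTranscripts`, `simulateFragments`): a diploid
  genome with a planted variant table (`applyVariants(hapA) == hapB`
  exactly), a heterozygosity mosaic, repeat families, gene models with
  GT..AG introns, paired-end reads, transcripts carrying extra
  population-level alleles, and BAC-like overlapping fragments — every
  downstream estimate can be scored against truth.
* **K-mer spectrum diagnostics** (`buildSpectrum`, `detectPeaks`,
  `estimateGenomeSize`, `intersectKmers`, `classifyBranches`): canonical
  k-mer spectra (k = 15–63), error/heterozygous/homozygous peak
  detection (het peak at half the homozygous depth), haploid genome size
  as above-cutoff k-mer mass divided by the homozygous peak, and de
  Bruijn branch classification into variant branches (two balanced
  extensions ≤ 1.5× het peak) versus repeat branches (≥ 3 extensions or
  any extension > 1.75× hom peak).
* **Allelic-contig collapse** (`pairwiseSimilarity`,
  `selectAllelicPairs`, `collapseContigs`, `reintegrate`): all-vs-all
  similarity (identity = matches/columns, overlap fraction on the
  shorter contig), the >95% identity / >0.95 overlap collapse rule with
  longest-primary cluster resolution, and reintegration into the three
  record classes (scaffolds, unplaced contigs, heterozygous contigs)
  with N50/N90 summaries.
* **Per-gene heterozygosity and population variance** (`geneHetTable`
  and friends): transcript-guided two-locus analysis — spliced transcript
  mapping with the <30 bp / >5-loci / top-two filters, coverage-group
  classification (boundary at the geometric mean of the two depth
  modes, ≈106 for modes 75/150), pileup-based calling for merged genes,
  two-locus alignment calling for split genes, population variance as
  transcript alleles matching neither haplotype, and
  synonymous/non-synonymous classification of coding differences.
* **Fragment-overlap accounting** (`findFragmentOverlaps`,
  `analyzeOverlap`, `fragmentHet`): pairwise SNP/indel accounting over
  BAC-like overlaps with read support, third-allele (>2 alleles)
  detection and the ≥100 bp indel tally.
* **Exon-array combinatorics** (`countCombinations`,
  `enumerateIsoforms`): isoform counts for Dscam-like mutually exclusive
  exon arrays (13 × 20 × 13 = 3380; 12 × 48 × 33 × 2 = 38,016).

Read mapping and spliced transcript alignment use minimap2/samtools
(required on `PATH`); alignment, pileups and I/O use
Biostrings/Rsamtools/rtracklayer/VariantAnnotation.

## Worked example

A 1 Mb diploid at 2.5% heterozygosity, sequenced at 50× per haplotype
with 0.5% error, analysed at k = 31:

```r
library(HapDip)
cfg <- SimConfig(haploid_length = 1e6, n_genes = 0, snp_rate = 0.025,
                 coverage_per_haplotype = 50, seq_error_rate = 0.005,
                 seed = 1)
g  <- simulateDiploid(cfg)
rs <- simulateReads(g, cfg)
sp <- buildSpectrum(rs, 31)
pk <- detectPeaks(sp)
pk
#> SpectrumPeaks: error cutoff 10 | het 34 | hom 68 | ratio 0.5
estimateGenomeSize(sp, pk)
#> [1] 1009907
```

The spectrum is bimodal: k-mers on one haplotype peak at multiplicity
34, shared k-mers at 68, the ratio 0.5 expected of a diploid; the
mass-based size estimate recovers the 1 Mb haploid length within 1%.

Gene-level analysis on a partially collapsed assembly (300 kb, 20
genes, 30× per haplotype; the most divergent half of the pieces
assemble into separate haplotypes):

```r
cfg <- SimConfig(haploid_length = 3e5, n_genes = 20,
                 coverage_per_haplotype = 30, seq_error_rate = 0.002,
                 snp_rate = 0.025, seed = 3)
g   <- simulateDiploid(cfg)
rs  <- simulateReads(g, cfg)
tx  <- simulateTranscripts(g, cfg)
asm <- simulateSplitAssembly(g, min_len = 2e4, max_len = 4e4,
                             split_fraction = 0.5, seed = 3)
bam <- mapReads(asm$contigs, rs, "het.bam")
tab <- geneHetTable(asm$contigs, tx$transcripts, bam)
mean(tab$het_percent[tab$group == "split"])   # 2.95
mean(tab$het_percent[tab$group == "merged"])  # 2.15
mean(tab$popvar_percent, na.rm = TRUE)        # 0.74
```

Genes in the low-coverage (split-haplotype) group show higher
heterozygosity (2.95% of bases) than merged-haplotype genes (2.15%) —
the split pieces are split *because* they are divergent — while the
transcript-only population variance is recovered near its planted 0.8%
in both groups.

`runPipeline()` chains all stages from one (YAML or list) configuration
and writes stage outputs, truth tables and a checksummed manifest;
`summarizePipeline()` collates the headline numbers.

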