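---
title: "Heterozygosity and haplotype diagnostics for highly heterozygous diploid genomes"
author: "HapDip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HapDip methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Some animals maintain enormous genetic diversity: in a single diploid
individual of an outbred invertebrate line, the two haplotypes can differ
at 1--3% of bases, with frequent small indels and occasional
polynucleotide indels of 100 bp or more. At that divergence a shotgun
assembler no longer merges the haplotypes of many regions; instead both
haplotypes assemble independently, so the assembly is a mosaic of
single-copy ("merged") regions at full read depth and duplicated
("split") regions at half depth. Every downstream quantity -- genome
size, contig statistics, per-gene heterozygosity, polymorphism of cloned
fragments -- has to be interpreted through that mosaic.

HapDip packages the diagnostic and accounting procedures for this regime
as reusable, testable functions, together with a simulator that generates
diploid genomes with complete ground truth, so that each procedure can be
scored against known answers.

# The simulator

`SimConfig()` / `simulateDiploid()` build haplotype A (random sequence,
interspersed repeat families, gene models) and derive haplotype B by
applying a planted variant table; `applyVariants()` over haplotype A
reconstructs haplotype B exactly, which is the invariant every truth
table hangs off.

Key modelling choices, with defaults:

* **SNP heterozygosity** (`snp_rate`, default 0.025): the genome-wide
  per-base rate. The genome-wide planted count is a single
  Binomial(L, rate) draw, so the realized rate is binomially calibrated.
* **Heterozygosity mosaic** (`het_block_len` 30 kb, `het_cv` 0.6): real
  heterozygosity is not spatially uniform, and regions assemble
  separately *because* they are locally divergent. SNPs are distributed
  over blocks with lognormal rate multipliers (normalized to mean one).
  Without this mosaic, split and merged regions would have identical
  expected heterozygosity and the characteristic contrast between the
  coverage groups could not arise.
* **Indels**: small indels (1--20 bp, geometric length weights) and rare
  large indels (>= 100 bp, geometric excess) between the haplotypes.
  Indels are left-normalized and keep a 25 bp guard from each other;
  SNPs keep a 5 bp guard from small indels and a full read length from
  large ones (short reads cannot span a >= 100 bp event, so its mapping
  shadow would leave nearby SNPs with one-sided read support). Without
  the guards, alignment-ambiguous adjacent events would make exact
  truth accounting impossible. Indels avoid exons (purifying selection
  against frameshifts), which also keeps every spliced product in frame
  on both haplotypes. BAC-like fragment ends are likewise placed clear
  of indel spans, so the declared content of every overlap is
  unambiguous.
* **Repeats** (`repeat_fraction` 0.2, unit 500 bp, 10 families, 3%
  divergence from consensus): planted on haplotype A (hence at
  homologous positions on both haplotypes). They create the repeat
  branch signal in the de Bruijn graph without confounding
  heterozygosity estimates.
* **Genes**: placed in repeat-free gaps; exons 120--300 bp, introns
  100--500 bp with canonical GT..AG splice dinucleotides (spliced
  aligners use the motif to anchor junctions; motif positions are
  protected from variants), spliced length divisible by three.
* **Reads**: paired-end 150 nt, insert 400 +/- 40, 75-fold per haplotype
  by default, substitution errors only. Substitution-only errors keep
  pileup truth exact; an indel error model would entangle sequencing
  error with haplotype indels.
* **Transcripts**: one per gene, spliced from a random haplotype, with
  extra population variants at 0.8% of bases; a planted population
  allele never equals either haplotype allele, so it is a genuine third
  allele.
* **Fragments**: a BAC-like tiling path; each fragment from exactly one
  haplotype, consecutive fragments sharing a declared ancestral overlap
  whose planted SNP/indel content is recorded.

Coordinates are 1-based closed throughout (the IRanges/GRanges
convention); VCF/GFF3/BED writers use the standard conventions of those
formats.

What the simulator does *not* model: base-quality error profiles,
GC/coverage bias, sequencing indel errors, mate-pair libraries, gene
families/paralogy beyond interspersed repeats, and selection. Tests that
pass on these simulations therefore demonstrate the correctness of the
accounting procedures under clean mapping conditions, not robustness to
every artifact of real libraries.

# K-mer spectrum diagnostics

`buildSpectrum()` counts canonical k-mers (lexicographic minimum of the
two strands) exactly, streaming reads into a single count table (k odd,
15--63, packed 2-bit in a 128-bit word). For a diploid read set the
error-free spectrum is bimodal: k-mers on one haplotype (heterozygous
regions) at the per-haplotype depth c, shared k-mers at 2c.

`detectPeaks()` smooths the histogram (moving average, window 3), takes
the first local minimum as the error cutoff, and reports the two highest
local maxima above it (at least 1.5-fold apart in multiplicity) as the
heterozygous and homozygous peaks. A unimodal spectrum yields a missing
het peak rather than a fabricated one; a monotone (pure noise) histogram
is an error.

`estimateGenomeSize()` divides the above-cutoff k-mer mass by the
homozygous peak. The mass above the cutoff is 2cG regardless of
heterozygosity or repeat content (every genomic position contributes its
coverage), and the homozygous peak sits at 2c, so the ratio recovers the
haploid length G directly; no reweighting of heterozygous k-mers is
needed for a mass-based estimator, and the estimate is invariant under
coverage changes.

`classifyBranches()` probes both outgoing sides of every above-error
k-mer. A side with exactly two extensions, both at or below 1.5x the het
peak, is a variant branch (balanced haplotype difference at one-haplotype
coverage); a side with three or more extensions, or any extension above
1.75x the homozygous peak, is a repeat branch (excess copy number). The
two multipliers are exposed as arguments; they are this package's
concrete rendering of the variant/repeat branch distinction, chosen so
that a clean diploid classifies het branches as variants at any
heterozygosity while repeat copies (which stack coverage) trip the
repeat rule.

`intersectKmers()` reports |A .intersect. B| / |A .union. B| over distinct
above-error k-mers of two libraries -- a consistency check that two
libraries sequenced the same genome (close to 1 for same-genome
libraries, near 0 for unrelated genomes).

# Allelic-contig collapse

`pairwiseSimilarity()` finds contig pairs with detectable homology and
reports identity (matches / alignment columns, gaps counting as
mismatches) and overlap fraction (aligned span of the shorter contig
over its length -- the natural denominator when the shorter contig is
the candidate haplotig). The default engine is an all-vs-all minimap2
alignment (`asm20`), the standard approach at assembly scale, whose
nmatch/alignment-length is exactly the matches/columns identity; an
exact dynamic-programming engine (shared canonical 21-mer seeding, >= 10
distinct seeds, then optimal local alignment) is provided for small
inputs and used to cross-validate the default engine in the tests.

`selectAllelicPairs()` applies the collapse thresholds -- identity > 95
and overlap fraction > 0.95 by default, strict inequalities with an
`inclusive` switch since the choice is not canonical -- and resolves
connected clusters of passing pairs so each secondary contig maps to
exactly one primary: the longest contig of its cluster, ties broken
lexicographically. On small inputs this resolution provably matches
exhaustive enumeration of assignments maximizing total primary length.

`collapseContigs()` partitions the assembly (primary + secondary = input,
total length conserved); `reintegrate()` restores the secondary contigs
after external scaffolding and reports the three record classes
(scaffolds, unplaced contigs, heterozygous contigs) with n, N90, N50,
N10, total and maximum length.

# Per-gene heterozygosity and population variance

The gene-level procedure (`geneHetTable()`) is transcript-guided:

1. **Transcript mapping** (`mapTranscriptsAndFilter()`): spliced
   alignment of each transcript; genomic placements under 30 bp are
   discarded; transcripts with more than five loci are dropped as
   repetitive or highly conserved; remaining placements are sorted by
   ascending edit distance and the top two retained. Two refinements
   make the two-locus logic explicit: placements spanning less than half
   of the transcript's best placement are treated as continuations of a
   record-split gene rather than independent loci, and a secondary locus
   must cover at least half of the top locus's transcript span to be
   treated as allelic.
2. **Coverage groups** (`regionCoverage()`,
   `classifyCoverageGroups()`): mean read depth over the top-locus
   blocks of each gene; the depth distribution of a heterozygous
   assembly is bimodal (split loci at c, merged loci at 2c), the
   boundary is the geometric mean of the two modes (about 106 for modes
   75/150) and the upper bound 5/3 of the high mode (250 for 150).
   Regions exactly at the boundary go to the high group.
3. **Heterozygous sites** (`callHeterozygosity()`): merged genes are
   called from the read pileup (site rule: depth >= 10, both alleles on
   >= 2 reads, minor fraction >= 0.2 -- thresholds chosen to suppress
   false positives at a 1% sequencing error rate and exposed as
   arguments); split genes from the global alignment of the two genomic
   segments, each difference column requiring read support on its own
   contig. The assessed denominator is block bases at adequate depth
   (merged) or aligned columns (split); indel events in the split-locus
   alignment count one site each.
4. **Population variance** (`populationVariance()`): for every aligned
   transcript position, the transcript base is compared with the union
   of genomic alleles over the retained loci (contig base plus
   adequately supported read alleles). A base matching neither haplotype
   allele is a population-variant site; a third allele at an already
   heterozygous site counts once.
5. **Substitution classes** (`classifySubstitutions()`): codon-by-codon
   comparison of the transcript against the transcript with the called
   alternate alleles substituted; amino-acid changes are non-synonymous.
   Gap runs in unequal-length comparisons count as indel events;
   a decomposition that leaves a segment length not divisible by three
   (a frameshift) is an error.

# Fragment-overlap accounting

For BAC-like fragments (`simulateFragments()`, or any FASTA),
`findFragmentOverlaps()` detects terminal overlaps by end-free alignment
of terminal windows; `analyzeOverlap()` globally aligns the two overlap
sequences (match 2, mismatch -3, gap open 10, extend 1 -- conventional
affine scoring, exposed in code) and counts mismatch columns (SNPs) and
gap runs (indels; runs separated by up to two match columns are kept
separate so each event retains its own length; >= 100 bp events counted
separately, threshold inclusive). Read support uses the same pileup rule
as the gene module on each fragment individually: a pairwise SNP is
both-supported when its two alleles are the called heterozygous alleles
on either fragment; a third allele is a site where pooling the two
fragment bases with the supported read alleles yields more than two
distinct alleles -- the second haplotype revealed by reads over a
same-haplotype overlap is a second allele, not a third.
`fragmentHet()` gives the per-fragment heterozygosity and
more-than-two-allele (population variance) rates from the pileup alone.

# Exon-array combinatorics

`countCombinations()` multiplies the per-array counts of mutually
exclusive alternative exons (exactly one exon chosen per array;
exon skipping is out of scope), and `enumerateIsoforms()` is the
brute-force enumeration used to cross-check it. A crustacean Dscam-like
locus with arrays of 13, 20 and 13 alternatives yields 3380 isoform
combinations; an insect-like locus with 12, 48, 33 and 2 yields 38,016.

# Numerical choices and edge cases

* Peak detection: moving-average window 3; minimum peak separation
  1.5-fold; plateaus resolve to the left-most bin.
* Ties at the coverage-group boundary go to the merged group;
  equal-length collapse ties go to the lexicographically smaller id;
  mismatch-count ties in transcript loci break by longer alignment,
  then target name.
* Degenerate inputs error loudly: monotone spectra, overlaps under
  100 bp, infeasible gene configurations, frame-disrupting indel
  decompositions, pairs referencing unknown contigs.
* All randomness flows from the configuration seed; stage seeds are
  derived as small fixed offsets, so every output is bit-reproducible.

# Problem sizes used in the checks

The automated checks run on desk-scale simulations chosen to keep the
full suite fast while leaving the statistics well-powered: 1 Mb genomes
at 50-fold coverage per haplotype for the spectrum checks (5 seeds);
300 kb genomes with 20 genes at 30-fold per haplotype for the gene-level
checks (10 seeds per heterozygosity setting); 100-150 kb genomes with
four 22-30 kb fragments for the overlap checks (10 seeds). Overlap
exactness is verified on repeat-free simulations: repeat copies attract
cross-mapping reads into single-fragment pileups, a mapping artifact
that is real in BAC data but orthogonal to the overlap accounting being
checked. The collapse checks fragment both haplotypes into 5-20 kb
pieces with breakpoints jittered by up to 100 bp between haplotypes,
emulating assemblers breaking the two haplotypes of a region at similar
but not identical points.

# Known limitations

* Read mapping and spliced transcript alignment delegate to minimap2;
  its heuristics (not exhaustive alignment) bound the recall of allelic
  loci. Read mapping re-seeds with shorter, denser minimizers and a
  milder mismatch penalty than the stock short-read preset, because
  reads drawn from the other haplotype of a locally >= 5% divergent
  stretch fail to seed at k = 21 and would vanish from pileups exactly
  where heterozygosity peaks. All chains are retained during transcript
  alignment because secondary-chain selection otherwise suppresses
  near-identical allelic placements. Single-fragment pileups exclude
  clipped alignments: reads spanning a large-indel junction align with
  frayed clipped ends that otherwise contaminate the columns at the
  junction.
* The pileup caller is rule-based, not a genotype-likelihood model; it
  is designed for parameter recovery on simulations and transparent
  accounting, not for clinical-grade variant calling.
* Repeat families are interspersed mutated copies of a consensus;
  segmental duplications, tandem arrays and nested repeats are not
  modelled.
* The exon-array module treats arrays as strictly mutually exclusive;
  exon skipping and cryptic splice variants are out of scope.
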