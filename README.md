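# migseqr — in-silico MIG-seq, from primer design to genetic analysis

MIG-seq (multiplexed ISSR genotyping by sequencing) is a PCR-based
reduced-representation sequencing method: instead of restriction
digestion, multiplexed PCR with tailed inter-simple-sequence-repeat
(ISSR) primers amplifies thousands of anonymous regions lying between
microsatellite tracts, and SNPs in the 80-nucleotide fragment ends are
discovered and genotyped de novo. The approach works from small
amounts of degraded DNA across very different taxa, which makes it
attractive for conservation genetics, clone identification and
population studies at the few-hundred-marker scale.

`migseqr` is an R package for people who want to work with this design
computationally: evaluate or redesign primer sets, predict which loci a
genome would yield, simulate realistic MIG-seq libraries with known
truth, and run the full genotyping-and-filtering chain on simulated (or
real, preprocessed) reads.

## What is implemented

**Primer design.** Annealing designs are `(core SSR)×k + anchor`
14-mers — e.g. `(ACT)₄TG` — with the published candidate enumeration
(2-base cores ×6, 3-base cores ×4; anchors AC, AG, CC, GG, TC, TG) and
rejection rules: (i) pure repeat extensions, (ii) one base from a pure
SSR, (iii) G/C on all three 3'-terminal bases, (iv) fewer than three
distinct bases, (v) a reverse complement of the 3'-terminal 4-mer
inside the design. Tailed primers are
`tail(14) + 2nd-PCR anchor(3) + SSR(12) + anchor(2)` = 31 nt; multiplex
sets are screened for 3'-end reverse-complement conflicts. The
recommended published set (set-1) ships as `migPrimerSet1()`.

**In-silico PCR.** `findAnnealingSites()` (exact 3' hexamer, bounded 5'
mismatches) → `predictAmplicons()` (convergent pairs, 300–800 bp
library-size gate, `sequenceable_fraction = 0.5`) →
`extractLocusReads()` (the two 80-nt end reads) → BED/FASTA export.

**Library simulation.** Seeded genomes with planted amplifiable loci;
cohorts (two differentiated populations, a heterozygous mother with 16
haploid megagametophytes segregating 1:1, clonal genets/ramets,
replicate pairs); reads with the exact 80/94/6 geometry, Poisson depth,
sequencing errors and Beta-fraction PCR pseudo-alleles, all under a
mandatory seed.

**Genotyping.** A simplified stack-based genotyper with the published
thresholds: stack depth `m = 20`, merge distance `M = 2`, catalog
mismatches `n = 4`, heterozygote depth-ratio rule `1/20`, marker
selection `r = 0.5`, `p ∈ {1, 2}`, single-SNP mode. Results live in a
`MigGenotypes` container (a `SummarizedExperiment`) with TSV, minimal
VCF 4.2 and FASTA export.

**Locus QC.** The five artifact controls: genotyper thresholds against
sequencing errors; singleton-variant and replicate-discordance filters
(with the depth chi-square PCR signature) against PCR errors; >60 %
shifted-homology group elimination against shifted-priming pseudo-loci
(identity over the full 80-base length, shifts |s| < 16, so
(80−16−16)/80 = 0.6 is the design point); duplicated-locus typing from
haploid heterozygote flags; paired-end locus detection by perfect
linkage.

**Analyses.** 1:1 segregation chi-square in haploid panels, pairwise
SNP-difference clone assignment with automatic bimodal thresholding,
and allele-frequency differentiation summaries (Hudson-style
estimator, allele-sharing distances).

A thin command-line wrapper (`inst/scripts/migseq`) exposes `design`,
`scan`, `genotype`, `qc`, `segtest`, `clones` and `popdiff`
subcommands over the same functions.

## Worked example

Simulate a megagametophyte panel (a heterozygous mother sequenced
twice plus 16 haploid seeds), genotype it, filter artifacts, and test
segregation:

```r
library(migseqr)

ps <- migPrimerSet1()
ps
#> MigPrimerSet 'set-1': 8 designs, 16 tailed primers
#>   multiplex-compatible: TRUE

cfg   <- simConfig(seed = 7, nLoci = 60, depthMean = 100)
sim   <- simulateGenome(cfg)
truth <- simulateCohort(sim, cohortSpec("megagametophyte_panel",
                                        nSamples = 16, nHetLoci = 30))
reads <- simulateReads(sim, truth)          # 108,024 read pairs
pools <- preprocessRun(reads)$pools         # demux + trim + q30/p40
mg    <- genotypeSamples(pools, truth$samples[, c("sample_id",
                                                  "population", "ploidy")])
mg
#> MigGenotypes: 122 locus rows x 18 samples
#>   polymorphic rows: 39; missing cells: 0/2196

qc <- qcPipeline(mg, replicatePairs = rbind(c("mother_rep1", "mother_rep2")))
table(qc$report$status)
#>               kept removed_paired_end  removed_singleton
#>                113                  6                  3

seg <- segregationTest(qc$mg, c("mother_rep1", "mother_rep2"),
                       sprintf("hap%02d", 1:16))
head(seg[, c("locus_id", "count_a", "count_b", "chi_square", "p_value")], 4)
#>  locus_id count_a count_b chi_square   p_value
#>  cat00002       7       9       0.25 0.6170751
#>  cat00007       5      11       2.25 0.1336144
#>  cat00013       7       9       0.25 0.6170751
#>  cat00017       8       8       0.00 1.0000000
```

The 60 planted loci appear as ~120 catalog loci because each fragment
contributes two independent 80-nt ends; the paired-end filter finds
and collapses the ends that share a fragment, the singleton filter
removes expressed PCR pseudo-variants, and the surviving heterozygous
loci segregate 1:1 in the haploids (here 1 of 30 deviates at
α = 0.05, as expected by chance).

See `vignettes/migseq-methods.Rmd` for the models, parameter
semantics, numerical choices and limitations.

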