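---
title: "MIG-seq in silico: models, parameters and design choices"
author: "migseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MIG-seq in silico: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migseqr)
```

## The method in brief

MIG-seq (multiplexed ISSR genotyping by sequencing) replaces the
restriction-digestion step of reduced-representation sequencing with
multiplexed PCR between microsatellite (SSR) tracts. Primers anneal to
the 3' ends of SSR runs — a 12-base repeated core plus a 2-base anchor
that pins the primer at the repeat boundary — and amplify the anonymous
inter-SSR regions between convergent sites. A second, tailed PCR adds
platform adapters and a 6-base sample index; 300–800 bp fragments are
size-selected and sequenced as an 80-base read 1, a 94-base read 2
(whose first 14 bases are the SSR + anchor region and are trimmed), and
the index read. Identical 80-base reads are bundled into per-sample
stacks, stacks merge into loci, loci cluster across samples into a
catalog, and SNPs are called by a depth-ratio rule. A set of locus-level
filters then screens the artifacts this design is prone to.

`migseqr` implements that entire computational chain at desk scale,
together with a seeded synthetic-data generator that plants amplifiable
loci in a random genome and simulates cohorts and reads, so every
procedure can be validated against known truth.

## Primer design

Candidate 14-base annealing designs are the cross of admissible core
motifs (2-base cores repeated six times, 3-base cores repeated four
times) with the six admissible anchors (AC, AG, CC, GG, TC, TG — the
3'-terminal base must be C or G and the self-complementary CG/GC pair
is excluded). Low-complexity repeat classes (polypurine AG/GA,
polypyrimidine TC/CT, GC/CG, AT/TA) are excluded up front. Half of the
three-distinct-base trimers seed a main candidate set; their reverse
complements form the alternative set.

Five string rules reject unsuitable designs: (i) pure repeat
extensions; (ii) one base away from any pure 14-mer SSR; (iii) all
three 3'-terminal bases G/C; (iv) fewer than three distinct bases;
(v) the reverse complement of the 3'-terminal 4-mer occurring inside
the design. A design can violate several rules at once, and the
published per-rule examples are only mutually consistent when the most
specific structural rule wins: the implementation therefore evaluates
i, v, iii, iv, ii and reports that precedence's first hit. Two further
interpretation choices were open: "GC rich on three bases of the 3'
end" is implemented as *all three* bases G/C (the printed example
(AC)~6~CC has CCC); and rule v scans the 14-base annealing sequence
only, since the rule is applied before tails are attached. The rule-v
window includes the terminal position itself, which covers the
palindromic example (ACC)~4~GG.

Tailed primers are `14-base tail + 3-base 2nd-PCR anchor + 14-base
annealing sequence` = 31 bases; forward and reverse variants differ
only in the constant 17-base prefix. The per-design dimer screen
rejects a primer whose 3'-terminal 4–6-mer has a reverse-complement
match in its own or its counterpart's sequence (a longer match implies
the shorter, so windows above 6 add nothing). Multiplex assembly is a
deterministic greedy pass over lexicographically ordered designs under
the cross-primer rule (no member's 3'-terminal 3-mer reverse
complement inside any other member); optional seeded restarts explore
permutations because several conflict-free choices exist. The
published set-1 is bundled as `migPrimerSet1()` and validates
conflict-free under the same rule.

```{r}
ps <- migPrimerSet1()
ps
isCompatible(validateMultiplexSet(ps))
```

## In-silico PCR

`findAnnealingSites()` reports every footprint where a primer's
3'-terminal `exact3 = 6` bases (anchor plus one repeat unit) match
exactly and the remaining 5' bases match with at most `maxMismatch5`
mismatches. Strict mode (`maxMismatch5 = 0`) reproduces perfect-site
prediction; the relaxed mode brackets the unknown tolerance of
low-stringency annealing, for which no single value is asserted.
Convergent (+, −) pairs on one contig become amplicons when the
*library* length — genomic span plus 34 non-genomic tail bases (17 per
end) — falls in the 300–800 selection window; the gate sits on the
final library because size selection happens after the second PCR. The
additional ~120 bases of outer 2nd-PCR adapter are configurable via
`tailBases` and excluded by default. Every convergent pair is
reported, including nested and shifted ones; deduplication is
deliberately left to the downstream homology filter, mirroring the
pipeline order. Half of all product molecules carry same-tail ends and
cannot be sequenced, so `sequenceable_fraction` is 0.5 throughout.

Internally coordinates are 1-based closed `GRanges`/`IRanges` — the
native convention of the container library — and are converted to
0-based half-open only in BED export. Amplicons whose insert is
shorter than 160 bases (impossible inside the 300–800 window) are
flagged `overlap_risk` rather than dropped.

## The synthetic-data generator

`simulateGenome()` plants `nLoci` convergent footprint pairs, with
library sizes uniform over the selection window, separated by ≥ 900
bases of background so no cross-locus pair falls inside the window;
accidental background matches to any primer are scrubbed. Strict-mode
scanning therefore recovers exactly the planted loci — a property the
tests rely on.

Cohort designs reproduce the three validation studies: a
megagametophyte panel (a mother tree heterozygous at `nHetLoci` loci,
sequenced as a replicate pair, plus 16 haploid megagametophytes each
inheriting one maternal haplotype per fragment with probability 1/2 —
the 1:1 gametic expectation), a two-population pair (Balding–Nichols
frequencies around an ancestral frequency drawn from `mafRange`, with
differentiation `fstLike = 0.2` by default), clonal ramets (genets
copied into ramets with `somaticDiffCount = 2` single-marker somatic
changes; changes are restricted to single-SNP loci so one event is one
marker difference), and exact replicate pairs. SNPs sit on the first
end read of a polymorphic fragment and, with probability
`bothEndSnpRate = 0.15`, also on the second end, phase-linked because
both ends ride one physical fragment — which is precisely what makes
paired-end loci detectable by linkage.

`simulateReads()` draws Poisson(`depthMean = 100`) read pairs per
sample-locus, splits heterozygotes binomially, randomises the
amplification orientation per fragment (a locus amplifies in both the
forward–reverse and reverse–forward direction, so its ends swap
between the read-1 and read-2 pools), and emits the exact read
geometry: 80-base read 1, 94-base read 2 beginning with the 14-base
annealing region, 6-base index read. Two error processes are modelled:
per-base substitutions at `seqErrorRate = 0.001`, and per-sample-locus
PCR pseudo-alleles at `pcrErrorRate = 0.01` whose depth share is
Beta(2, 2) — chosen so that biased depth ratios (the chi-square
signature of an early-cycle PCR error) occur among the planted
positives. The paper quantifies neither rate; these defaults make the
observed few-percent replicate discordance plausible without being
calibrated to it. Base qualities are constant Q37, with an optional
low-quality-tail injection (`lowQualityRate`, 56-base Q2 tails) to
exercise the q = 30 / p = 40 filter. Not modelled: indels, chimeras,
GC-coverage bias, index hopping, PhiX spike-in — so passing tests
demonstrate correctness of the downstream logic under this error
model, not robustness to everything real libraries do.

## Preprocessing and genotyping

Demultiplexing is exact 6-base index matching (non-matches go to an
`undetermined` pool). Read 2 loses its first 14 bases; both mates are
kept iff at least `p = 40` percent of bases reach `q = 30` (Phred+33),
and reads containing the mate-appropriate sequencing-primer query (the
published 37- and 32-base sequences) are removed as short-insert
read-through — exact substring by default, with a mismatch-tolerant
mode. Reads 1 and 2 stay unpaired downstream: joining them would split
each locus into forward–reverse and reverse–forward variants.

The genotyper is a deliberate simplification of the stack-based
de-novo chain, not a bit-exact reproduction. Identical reads form
stacks; stacks of depth ≥ `m = 20` seed loci greedily (deepest first,
ties lexicographic) and absorb seeds within `M = 2` substitutions;
sample loci assembled from more than 3 stacks are discarded — the
documented stand-in for the deleveraging/removal algorithms, whose
internals the source pipeline does not specify. Sub-threshold stacks
attach to the nearest locus within `M` as secondary depth. Catalog
clustering is the same greedy pattern at `n = 4` across samples, the
catalog consensus being each cluster's first (deepest) member.
Genotypes use the stated depth-ratio rule rather than a likelihood
model: a minor allele below 1/20 of the major is rejected; haploid
samples always receive the major allele plus a heterozygote flag
whenever the diploid rule would have called one — the input to the
duplicated-locus classifier. Marker selection applies the
`r = 0.5` / `p = 1` presence thresholds and optionally keeps only each
locus's leftmost SNP. A locus undetected in a sample is missing data,
never homozygous reference.

## Artifact filters

Five artifact classes are handled. Sequencing errors die in the
genotyper thresholds (singleton error reads cannot pass the 1/20 rule
at depth ≥ 20). PCR pseudo-variants are removed by the singleton rule
(minor allele in exactly one sample) and, for replicated individuals,
by discordance between replicates, with a (d₁−d₂)²/(d₁+d₂) chi-square
on the heterozygote's allele depths reported as the PCR-error
signature. Shifted-priming pseudo-loci are removed as whole homology
groups: ungapped identity, denominator fixed at the 80-base read
length (two identical reads shifted 16 bases at each end retain
(80−16−16)/80 = 0.6), scanned at offsets strictly inside ±16;
components above 0.6 are eliminated wholesale even though they
inevitably contain true loci (`keepOne` keeps one representative if
wanted). Comparison is same-strand by default — shifted priming makes
same-strand copies — with a `bothStrands` flag. Duplicated loci are
typed from haploid heterozygote flags: all flagged → two copies fixed
for different alleles; flagged:unflagged compatible with 1:1 (exact
binomial, α = 0.05) with one allele among the unflagged → homo +
hetero; with both alleles among the unflagged → hetero + hetero
(1:2:1); a 1–3-sample minority class → linked copies, the small-count
rule taking precedence. Paired-end loci — the two ends of one
fragment — are perfectly concordant, so pairs whose genotype mapping
is a bijection over ≥ 8 co-genotyped informative samples are reported
and the higher-ID member removed. The pipeline order (singleton /
replicate → homology → paired-end) is fixed and idempotent.

## Genetic analyses

The segregation test computes (a−b)²/(a+b) against the 1:1 gametic
expectation for loci where the mother (or both her replicates,
concordantly) is heterozygous, at least `minInformative = 10` haploids
are genotyped, and no haploid carries the heterozygote flag. The
default is the uncorrected chi-square — the convention behind the
published worked values such as counts (10, 6) → χ² = 1.0,
p ≈ 0.317 — with Yates correction available by flag. One calibration
caveat is worth stating precisely: at a full panel of n = 16 the
uncorrected test's exact null rejection set is |a − 8| ≥ 4, rate
0.0768, slightly above the nominal 0.05; the corrected test is
conservative at 0.0213. The test suite asserts calibration against
that exact discrete rate.

Clone identification counts, per sample pair, the co-genotyped markers
with any allelic difference (missing loci are excluded pairwise; a
pair with no shared loci is a missing cell). With clonal structure the
distribution of pairwise differences is bimodal — somatic noise near
zero against tens of differences between genets — so the automatic
threshold is the midpoint of the largest gap between consecutive
sorted difference values, and clones are single-linkage components at
or below it; a degenerate unimodal distribution triggers a warning.

Population differentiation reports per-population allele frequencies,
the Hudson-style frequency-variance estimator with within-population
sampling correction (fixed-identical pairs → 0, fixed-opposite → 1),
and an allele-sharing distance matrix (one minus the multiset
shared-allele fraction) for external ordination. Bayesian clustering
and ordination themselves are out of scope; the summaries feed those
tools.

## Validation strategy and problem sizes

Every operation is tested against independent oracles: a
position-by-position naive scanner for annealing sites, exhaustive
pair enumeration for amplicons, a double-loop identity computation for
the homology model, hand-computed chi-square and binomial values, and
the simulator's truth tables for end-to-end recovery. The routine
suite uses 20 seeded genomes of 8–17 kb for oracle equivalence, a
200-locus × 18-sample megagametophyte panel at depth 100 for parameter
recovery (error-free recovery must be exact; with default error
rates the singleton + replicate filters are scored only against
pseudo-variants that actually reach the genotype matrix — an event
whose pseudo-allele stays below the 1/20 rule corrupts nothing a
locus filter could see), 1,000 loci for segregation calibration, and
a 3-genet × 18-ramet design (intra ≤ 6, inter ≥ 27 differences) for
clone recovery. These sizes were chosen as the smallest at which the
binomial tolerances are meaningful.

## Known limitations

* The genotyper is a functional stand-in: no gapped alignment inside
  stacks, no likelihood-based calling, simplified secondary-read and
  deleveraging behaviour.
* PCR efficiency competition between amplicons and annealing
  thermodynamics are not modelled; site prediction is purely string
  based.
* The homology filter's full-length denominator makes it blind to
  shifts ≥ 16 bases by construction, exactly as designed.
* Simulated data cannot establish how the thresholds behave under
  error processes the generator does not model (see above).
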