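## Synthetic-data generator: seeded genomes with plantable ISSR loci, cohort
## designs (two populations, haploid megagametophyte panels, clonal ramets,
## replicate pairs), and read simulation reproducing the MIG-seq read
## geometry (80-base read 1, 94-base read 2, 6-base index read) with PCR-
## and sequencing-error models.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. All randomness in
#' the simulator flows from `seed`; there is no unseeded randomness
#' anywhere.
#'
#' @param seed Mandatory integer seed.
#' @param nLoci Number of amplifiable loci planted in the genome.
#' @param libraryLenRange Planted library sizes in bases (default the
#'   300-800 size-selection window).
#' @param depthMean Mean reads per locus per sample (Poisson; default 100).
#' @param seqErrorRate Per-base substitution rate of the sequencer
#'   (default 0.001).
#' @param pcrErrorRate Per-locus-per-sample probability that an early-cycle
#'   PCR error propagates as a pseudo-allele (default 0.01).
#' @param pcrErrorDepthShape Two Beta shape parameters for the fraction of
#'   a sample-locus's reads carrying the pseudo-allele (default
#'   `c(2, 2)`, so biased depth ratios are possible).
#' @param mafRange Ancestral allele-frequency interval for planted SNPs in
#'   population designs (default `c(0.1, 0.5)`).
#' @param duplicationRate Fraction of loci planted as a two-copy family
#'   whose copies co-assemble (default 0).
#' @param bothEndSnpRate Probability that a polymorphic locus carries a
#'   (phase-linked) SNP at its second end as well (default 0.15), which
#'   creates detectable paired-end locus pairs.
#' @param lowQualityRate Fraction of reads given a low-quality tail, to
#'   exercise the q/p quality filter (default 0).
#' @param lowQualityTailLen Length of that Q2 tail (default 56 bases, i.e.
#'   70 percent of an 80-base read).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed, nLoci = 200L, libraryLenRange = c(300L, 800L),
                      depthMean = 100, seqErrorRate = 0.001,
                      pcrErrorRate = 0.01, pcrErrorDepthShape = c(2, 2),
                      mafRange = c(0.1, 0.5), duplicationRate = 0,
                      bothEndSnpRate = 0.15, lowQualityRate = 0,
                      lowQualityTailLen = 56L) {
    if (missing(seed)) stop("seed is mandatory")
    rates <- c(seqErrorRate, pcrErrorRate, duplicationRate, bothEndSnpRate,
               lowQualityRate)
    stopifnot(all(rates >= 0 & rates <= 1), depthMean > 0, nLoci >= 0,
              libraryLenRange[1] >= 200L, diff(libraryLenRange) >= 0)
    structure(list(seed = as.integer(seed), nLoci = as.integer(nLoci),
                   libraryLenRange = as.integer(libraryLenRange),
                   depthMean = depthMean, seqErrorRate = seqErrorRate,
                   pcrErrorRate = pcrErrorRate,
                   pcrErrorDepthShape = pcrErrorDepthShape,
                   mafRange = mafRange, duplicationRate = duplicationRate,
                   bothEndSnpRate = bothEndSnpRate,
                   lowQualityRate = lowQualityRate,
                   lowQualityTailLen = as.integer(lowQualityTailLen)),
              class = "SimConfig")
}

#' Cohort design specification
#'
#' @param design One of `"population_pair"` (two populations with
#'   allele-frequency differentiation), `"megagametophyte_panel"` (a
#'   heterozygous mother sampled as a replicate pair plus haploid
#'   megagametophytes segregating 1:1), `"clonal_ramets"` (genets sampled
#'   as multiple ramets with somatic differences), or `"replicate_pair"`
#'   (one genotype sequenced twice).
#' @param nSamples Samples per group: per population, haploids in the
#'   panel, or total ramets.
#' @param fstLike Differentiation parameter of the population pair
#'   (Balding-Nichols F, default 0.2).
#' @param nHetLoci Loci at which the panel mother is heterozygous
#'   (default 100).
#' @param nGenets,rametsPerGenet Clonal design: number of genets and
#'   ramets per genet (recycled).
#' @param somaticDiffCount Somatic single-locus changes per non-founder
#'   ramet (default 2).
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(design = c("population_pair", "megagametophyte_panel",
                                  "clonal_ramets", "replicate_pair"),
                       nSamples = NULL, fstLike = 0.2, nHetLoci = 100L,
                       nGenets = 3L, rametsPerGenet = 6L,
                       somaticDiffCount = 2L) {
    design <- match.arg(design)
    if (is.null(nSamples)) {
        nSamples <- switch(design, population_pair = 4L,
                           megagametophyte_panel = 16L,
                           clonal_ramets = 18L, replicate_pair = 1L)
    }
    structure(list(design = design, nSamples = as.integer(nSamples),
                   fstLike = fstLike, nHetLoci = as.integer(nHetLoci),
                   nGenets = as.integer(nGenets),
                   rametsPerGenet = as.integer(rametsPerGenet),
                   somaticDiffCount = as.integer(somaticDiffCount)),
              class = "CohortSpec")
}

## Distinct 6-base sample barcodes, deterministic under the RNG stream.
makeBarcodes <- function(n) {
    pool <- character(0)
    while (length(pool) < n) {
        pool <- unique(c(pool, randomSeq(n * 2L, INDEX_LEN)))
    }
    pool[seq_len(n)]
}

#' Simulate a genome with planted ISSR loci
#'
#' Builds one random contig carrying `nLoci` non-overlapping convergent
#' primer-site pairs (footprints drawn from the supplied primer set) at
#' seeded positions with seeded library sizes; loci are separated by
#' enough background that no cross-locus convergent pair falls inside the
#' size-selection window, and accidental background annealing matches are
#' scrubbed, so strict-mode scanning recovers exactly the planted loci.
#' A `duplicationRate` fraction of loci is planted twice, the second copy
#' diverged at one fixed site of its first end.
#'
#' @param config A [simConfig()].
#' @param primers A [MigPrimerSet-class] (default [migPrimerSet1()]).
#' @return A list of class `MigSimGenome`: `genome`
#'   ([Biostrings::DNAStringSet]), `loci` ([GenomicRanges::GRanges] of
#'   planted amplicons with end-read windows in `mcols`), `config`,
#'   `primers`.
#' @export
simulateGenome <- function(config, primers = migPrimerSet1()) {
    set.seed(config$seed)
    designs <- annealingDesigns(primers)
    n <- config$nLoci
    ndup <- if (n > 0L) rbinom(1L, n, config$duplicationRate) else 0L
    dup_of <- if (ndup > 0L) sort(sample(n, ndup)) else integer(0)
    n_total <- n + ndup
    fwd_idx <- if (n > 0L) sample(nrow(designs), n, replace = TRUE) else integer(0)
    rev_idx <- if (n > 0L) sample(nrow(designs), n, replace = TRUE) else integer(0)
    lib_len <- if (n > 0L)
        sample(seq(config$libraryLenRange[1], config$libraryLenRange[2]),
               n, replace = TRUE) else integer(0)
    insert_len <- lib_len - 2L * TAIL_BASES_PER_END - 2L * ANNEAL_LEN
    inserts <- if (n > 0L) randomSeq(n, 1L) else character(0) # placeholder
    for (i in seq_len(n)) inserts[i] <- randomSeq(1L, insert_len[i])
    ## Order: each original locus followed by its duplicate copy (if any).
    ord_orig <- integer(0); copy_of <- integer(0)
    for (i in seq_len(n)) {
        ord_orig <- c(ord_orig, i); copy_of <- c(copy_of, NA_integer_)
        if (i %in% dup_of) {
            ord_orig <- c(ord_orig, i); copy_of <- c(copy_of, i)
        }
    }
    pieces <- character(0)
    rows <- vector("list", n_total)
    pos <- 0L
    gapMin <- 900L
    for (k in seq_along(ord_orig)) {
        i <- ord_orig[k]
        is_copy <- !is.na(copy_of[k])
        gap <- gapMin + sample(0:200L, 1L)
        ins <- inserts[i]
        if (is_copy) # paralogous divergence at a fixed site of end 1
            ins <- substituteBase(ins, 40L, otherBase(substr(ins, 40L, 40L)))
        frag <- paste0(designs$annealing_seq[fwd_idx[i]], ins,
                       revComp(designs$annealing_seq[rev_idx[i]]))
        pieces <- c(pieces, randomSeq(1L, gap), frag)
        fwd_start <- pos + gap + 1L
        pos <- pos + gap + nchar(frag)
        ins_s <- fwd_start + ANNEAL_LEN
        ins_e <- pos - ANNEAL_LEN
        rows[[k]] <- data.frame(
            amplicon_id = sprintf("SIM%04d%s", i, if (is_copy) "d" else ""),
            locus = i, is_copy = is_copy,
            fwd_primer = designs$name[fwd_idx[i]],
            rev_primer = designs$name[rev_idx[i]],
            fwd_anneal = designs$annealing_seq[fwd_idx[i]],
            rev_anneal = designs$annealing_seq[rev_idx[i]],
            start = fwd_start, end = pos,
            insert_start = ins_s, insert_end = ins_e,
            library_len = nchar(frag) + 2L * TAIL_BASES_PER_END,
            end1_seq = substr(ins, 1L, READ_LEN),
            end2_seq = revComp(substr(ins, nchar(ins) - READ_LEN + 1L,
                                      nchar(ins))),
            stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, randomSeq(1L, gapMin))
    genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                                "sim1"))
    loci <- do.call(rbind, rows) %||% data.frame()
    if (n_total > 0L)
        genome <- scrubAccidentalSites(genome, designs, loci)
    gr <- if (n_total > 0L)
        GenomicRanges::GRanges("sim1", IRanges::IRanges(loci$start, loci$end),
                               strand = "+")
    else GenomicRanges::GRanges()
    if (n_total > 0L)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            loci[, setdiff(names(loci), c("start", "end"))])
    structure(list(genome = genome, loci = gr, config = config,
                   primers = primers), class = "MigSimGenome")
}

## Destroy accidental annealing matches outside the planted footprints so
## that strict scanning yields exactly the planted amplicons.
scrubAccidentalSites <- function(genome, designs, loci) {
    planted <- IRanges::IRanges(
        c(loci$start, loci$end - ANNEAL_LEN + 1L),
        c(loci$start + ANNEAL_LEN - 1L, loci$end))
    for (pass in 1:10) {
        hit_ranges <- list()
        for (k in seq_len(nrow(designs))) {
            for (pat in c(designs$annealing_seq[k],
                          revComp(designs$annealing_seq[k]))) {
                m <- Biostrings::matchPattern(pat, genome[[1L]])
                if (length(m))
                    hit_ranges[[length(hit_ranges) + 1L]] <-
                        IRanges::IRanges(BiocGenerics::start(m),
                                         BiocGenerics::end(m))
            }
        }
        if (length(hit_ranges) == 0L) break
        hits <- do.call(c, hit_ranges)
        accidental <- hits[!IRanges::overlapsAny(hits, planted, type = "equal")]
        if (length(accidental) == 0L) break
        g <- as.character(genome[[1L]])
        for (j in seq_along(accidental)) {
            ## Mutate a position of the accidental match that lies outside
            ## every planted footprint, so planted sites stay intact.
            cand <- IRanges::setdiff(accidental[j], planted)
            if (length(cand) == 0L) next
            p <- BiocGenerics::start(cand)[1L]
            g <- substituteBase(g, p, otherBase(substr(g, p, p)))
        }
        genome <- Biostrings::DNAStringSet(setNames(g, names(genome)))
    }
    genome
}
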