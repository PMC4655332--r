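## Cohort genotype simulation on a planted genome, and read simulation with
## the MIG-seq read geometry and error models.

#' Simulate true cohort genotypes on a planted genome
#'
#' Draws per-sample true genotypes for every planted amplicon according to
#' the cohort design. SNPs are placed on the first end read of a
#' polymorphic amplicon and, with probability `bothEndSnpRate`, also on
#' its second end; the two ends of one amplicon are phase-linked because
#' they sit on one physical fragment.
#'
#' Designs:
#' * `megagametophyte_panel` — a mother tree heterozygous at `nHetLoci`
#'   amplicons, sampled as a replicate pair, plus `nSamples` haploid
#'   megagametophytes each inheriting one maternal haplotype per amplicon
#'   independently with probability 1/2 (the expected 1:1 segregation).
#' * `population_pair` — two populations of `nSamples` diploids;
#'   population allele frequencies drawn around an ancestral frequency by
#'   a Balding-Nichols model with differentiation `fstLike`; genotypes by
#'   Hardy-Weinberg draws.
#' * `clonal_ramets` — `nGenets` genets, each sampled as `rametsPerGenet`
#'   ramets; every ramet after a genet's founder carries
#'   `somaticDiffCount` random single-amplicon genotype changes.
#' * `replicate_pair` — one diploid genotype duplicated exactly.
#'
#' @param sim A `MigSimGenome` from [simulateGenome()].
#' @param spec A [cohortSpec()].
#' @return A list of class `MigTruth`: `samples`, `loci` (one row per
#'   amplicon end), `doses` (amplicons x samples alt-haplotype counts),
#'   `genotypes` (ends x samples alt-allele counts), plus the amplicon
#'   table, spec and config.
#' @export
simulateCohort <- function(sim, spec) {
    config <- sim$config
    set.seed(config$seed + 101L)
    amp <- as.data.frame(S4Vectors::mcols(sim$loci))
    amp$start <- GenomicRanges::start(sim$loci)
    amp$end <- GenomicRanges::end(sim$loci)
    primary <- which(!amp$is_copy)

    samples <- switch(spec$design,
        megagametophyte_panel = data.frame(
            sample_id = c("mother_rep1", "mother_rep2",
                          sprintf("hap%02d", seq_len(spec$nSamples))),
            population = c("mother", "mother",
                           rep("megagametophytes", spec$nSamples)),
            ploidy = c(2L, 2L, rep(1L, spec$nSamples)),
            replicate_of = c(NA, "mother_rep1", rep(NA, spec$nSamples)),
            genet = NA_character_, stringsAsFactors = FALSE),
        population_pair = data.frame(
            sample_id = c(sprintf("p1_s%02d", seq_len(spec$nSamples)),
                          sprintf("p2_s%02d", seq_len(spec$nSamples))),
            population = rep(c("pop1", "pop2"), each = spec$nSamples),
            ploidy = 2L, replicate_of = NA_character_,
            genet = NA_character_, stringsAsFactors = FALSE),
        clonal_ramets = {
            genet <- rep(sprintf("genet%d", seq_len(spec$nGenets)),
                         length.out = spec$nGenets)
            genet <- rep(genet, each = spec$rametsPerGenet)
            data.frame(
                sample_id = sprintf("ramet%02d", seq_along(genet)),
                population = "clonal", ploidy = 2L,
                replicate_of = NA_character_, genet = genet,
                stringsAsFactors = FALSE)
        },
        replicate_pair = data.frame(
            sample_id = c("rep1", "rep2"), population = "replicates",
            ploidy = 2L, replicate_of = c(NA, "rep1"),
            genet = NA_character_, stringsAsFactors = FALSE))
    samples$barcode <- makeBarcodes(nrow(samples))
    nS <- nrow(samples)
    nA <- nrow(amp)

    ## Choose polymorphic amplicons and place SNPs on their end reads.
    poly <- switch(spec$design,
        megagametophyte_panel = sort(sample(primary,
            min(spec$nHetLoci, length(primary)))),
        primary)
    snp1_pos <- rep(NA_integer_, nA); snp2_pos <- rep(NA_integer_, nA)
    snp1_pos[poly] <- sample(READ_LEN, length(poly), replace = TRUE)
    both <- poly[runif(length(poly)) < config$bothEndSnpRate]
    snp2_pos[both] <- sample(READ_LEN, length(both), replace = TRUE)

    ## Alt-haplotype dose per amplicon per sample (phase-linked ends).
    doses <- matrix(0L, nA, nS,
                    dimnames = list(amp$amplicon_id, samples$sample_id))
    if (spec$design == "megagametophyte_panel") {
        doses[poly, c("mother_rep1", "mother_rep2")] <- 1L
        hap_cols <- which(samples$ploidy == 1L)
        doses[poly, hap_cols] <- matrix(
            rbinom(length(poly) * length(hap_cols), 1L, 0.5),
            length(poly), length(hap_cols))
    } else if (spec$design == "population_pair") {
        p_anc <- runif(length(poly), config$mafRange[1], config$mafRange[2])
        F <- max(spec$fstLike, 1e-6)
        for (pop in c("pop1", "pop2")) {
            pf <- rbeta(length(poly), p_anc * (1 - F) / F,
                        (1 - p_anc) * (1 - F) / F)
            cols <- which(samples$population == pop)
            doses[poly, cols] <- matrix(
                rbinom(length(poly) * length(cols), 2L, rep(pf, length(cols))),
                length(poly), length(cols))
        }
    } else if (spec$design == "clonal_ramets") {
        p <- runif(length(poly), config$mafRange[1], config$mafRange[2])
        ## somatic changes are single-SNP events: restrict them to
        ## amplicons carrying one SNP so one change = one marker difference
        single_snp <- which(is.na(snp2_pos[poly]))
        for (g in unique(samples$genet)) {
            founder <- rbinom(length(poly), 2L, p)
            cols <- which(samples$genet == g)
            for (ci in seq_along(cols)) {
                dose <- founder
                if (ci > 1L && spec$somaticDiffCount > 0L) {
                    at <- sample(single_snp, spec$somaticDiffCount)
                    dose[at] <- vapply(dose[at], function(d)
                        sample(setdiff(0:2, d), 1L), integer(1))
                }
                doses[poly, cols[ci]] <- dose
            }
        }
    } else { # replicate_pair
        p <- runif(length(poly), config$mafRange[1], config$mafRange[2])
        g <- rbinom(length(poly), 2L, p)
        doses[poly, 1L] <- g; doses[poly, 2L] <- g
    }

    ## Per-end locus table with ref/alt sequences.
    loci <- do.call(rbind, lapply(seq_len(nA), function(i) {
        ends <- data.frame(
            end_id = paste0(amp$amplicon_id[i], ":e", 1:2),
            amplicon_id = amp$amplicon_id[i], end = 1:2,
            snp_pos = c(snp1_pos[i], snp2_pos[i]),
            seq_ref = c(amp$end1_seq[i], amp$end2_seq[i]),
            anneal = c(amp$fwd_anneal[i], amp$rev_anneal[i]),
            stringsAsFactors = FALSE)
        ends$ref <- ifelse(is.na(ends$snp_pos), NA,
                           substr(ends$seq_ref, ends$snp_pos, ends$snp_pos))
        ends
    }))
    loci$alt <- NA_character_
    has_snp <- !is.na(loci$snp_pos)
    loci$alt[has_snp] <- otherBase(loci$ref[has_snp])
    loci$seq_alt <- NA_character_
    loci$seq_alt[has_snp] <- mapply(substituteBase, loci$seq_ref[has_snp],
                                    loci$snp_pos[has_snp], loci$alt[has_snp])

    genotypes <- doses[loci$amplicon_id, , drop = FALSE]
    genotypes[is.na(loci$snp_pos), ] <- 0L
    rownames(genotypes) <- loci$end_id

    structure(list(samples = samples, loci = loci, doses = doses,
                   genotypes = genotypes, amplicons = amp, spec = spec,
                   config = config), class = "MigTruth")
}

#' Simulate indexed paired reads for a cohort
#'
#' Per sample and planted amplicon, the read count is Poisson with mean
#' `depthMean`, split between haplotypes binomially. Each fragment yields
#' an 80-base read 1 from one end and a 94-base read 2 (14-base primer
#' annealing region + 80 genomic bases) from the other, with the
#' orientation randomised per fragment because a locus amplifies in both
#' the forward-reverse and reverse-forward direction; the 6-base index
#' read carries the sample barcode. Per-base substitution errors occur at
#' `seqErrorRate`; with probability `pcrErrorRate` per sample-amplicon a
#' pseudo-allele (one random substitution on one end) replaces a
#' Beta-distributed fraction of that cell's reads.
#'
#' @param sim A `MigSimGenome`.
#' @param truth A `MigTruth` from [simulateCohort()].
#' @return A list of class `MigReadSim`: `read1`, `read2`, `index`
#'   (data.frames with `id`, `seq`, `qual`), `provenance` (per fragment:
#'   sample, amplicon, allele, orientation, PCR-error flag), `pcrEvents`,
#'   `seqErrors`, plus `truth` and `config`.
#' @export
simulateReads <- function(sim, truth) {
    config <- sim$config
    set.seed(config$seed + 202L)
    loci <- truth$loci
    samples <- truth$samples
    amp_ids <- rownames(truth$doses)
    nA <- length(amp_ids); nS <- nrow(samples)

    ## End sequences per amplicon x end x allele, and annealing regions.
    e1 <- loci[loci$end == 1L, ]; e2 <- loci[loci$end == 2L, ]
    stopifnot(identical(e1$amplicon_id, amp_ids),
              identical(e2$amplicon_id, amp_ids))
    end_ref <- cbind(e1$seq_ref, e2$seq_ref)
    end_alt <- cbind(ifelse(is.na(e1$seq_alt), e1$seq_ref, e1$seq_alt),
                     ifelse(is.na(e2$seq_alt), e2$seq_ref, e2$seq_alt))
    anneal <- cbind(e1$anneal, e2$anneal)

    out_s <- character(0)
    r1 <- list(); r2 <- list(); prov <- list(); events <- list()
    cell <- 0L
    for (si in seq_len(nS)) {
        ploidy <- samples$ploidy[si]
        for (ai in seq_len(nA)) {
            cell <- cell + 1L
            d <- rpois(1L, config$depthMean)
            if (d == 0L) next
            dose <- truth$doses[ai, si]
            k_alt <- rbinom(1L, d, dose / ploidy)
            allele <- c(rep(1L, k_alt), rep(0L, d - k_alt))
            orient <- rbinom(d, 1L, 0.5) # 1: end2 sequenced as read 1
            pcr_hit <- rep(FALSE, d)
            s1 <- matrix(c(end_ref[ai, 1L], end_alt[ai, 1L]),
                         2L)[allele + 1L]
            s2 <- matrix(c(end_ref[ai, 2L], end_alt[ai, 2L]),
                         2L)[allele + 1L]
            if (runif(1) < config$pcrErrorRate) {
                e <- sample(2L, 1L)
                pos <- sample(READ_LEN, 1L)
                frac <- rbeta(1L, config$pcrErrorDepthShape[1],
                              config$pcrErrorDepthShape[2])
                n_aff <- rbinom(1L, d, frac)
                if (n_aff > 0L) {
                    aff <- sample(d, n_aff)
                    pcr_hit[aff] <- TRUE
                    tgt <- if (e == 1L) s1 else s2
                    newb <- otherBase(substr(tgt[aff[1L]], pos, pos))
                    tgt[aff] <- substituteBase(tgt[aff], pos, newb)
                    if (e == 1L) s1 <- tgt else s2 <- tgt
                    events[[length(events) + 1L]] <- data.frame(
                        sample_id = samples$sample_id[si],
                        amplicon_id = amp_ids[ai], end = e, pos = pos,
                        base = newb, frac = frac, n_reads = n_aff,
                        stringsAsFactors = FALSE)
                }
            }
            first <- ifelse(orient == 1L, s2, s1)
            second <- ifelse(orient == 1L, s1, s2)
            sec_anneal <- anneal[ai, ifelse(orient == 1L, 1L, 2L)]
            ids <- sprintf("%s:%s:%04d", samples$sample_id[si],
                           amp_ids[ai], seq_len(d))
            r1[[cell]] <- data.frame(id = ids, seq = first,
                                     stringsAsFactors = FALSE)
            r2[[cell]] <- data.frame(id = ids,
                                     seq = paste0(sec_anneal, second),
                                     stringsAsFactors = FALSE)
            prov[[cell]] <- data.frame(
                id = ids, sample_id = samples$sample_id[si],
                amplicon_id = amp_ids[ai], allele = allele,
                orientation = orient, pcr_error = pcr_hit,
                stringsAsFactors = FALSE)
        }
    }
    read1 <- do.call(rbind, r1); read2 <- do.call(rbind, r2)
    provenance <- do.call(rbind, prov)
    n <- nrow(read1)

    ## Sequencing errors: substitutions at seqErrorRate per base.
    seqErrors <- data.frame(mate = integer(0), idx = integer(0),
                            pos = integer(0))
    injectErrors <- function(seqs, len, mate) {
        n_err <- rbinom(1L, length(seqs) * len, config$seqErrorRate)
        if (n_err == 0L) return(seqs)
        idx <- sample(length(seqs), n_err, replace = TRUE)
        pos <- sample(len, n_err, replace = TRUE)
        for (k in seq_len(n_err)) {
            s <- seqs[idx[k]]
            seqs[idx[k]] <- substituteBase(s, pos[k],
                                           otherBase(substr(s, pos[k], pos[k])))
        }
        seqErrors <<- rbind(seqErrors,
                            data.frame(mate = mate, idx = idx, pos = pos))
        seqs
    }
    read1$seq <- injectErrors(read1$seq, READ_LEN, 1L)
    read2$seq <- injectErrors(read2$seq, READ2_RAW_LEN, 2L)

    ## Quality strings: Q37 throughout, optional low-quality tails.
    qual_of <- function(len) {
        good <- strrep("F", len)
        bad <- paste0(strrep("F", len - config$lowQualityTailLen),
                      strrep("#", config$lowQualityTailLen))
        q <- rep(good, n)
        if (config$lowQualityRate > 0) {
            hit <- runif(n) < config$lowQualityRate
            q[hit] <- bad
        }
        q
    }
    read1$qual <- qual_of(READ_LEN)
    read2$qual <- qual_of(READ2_RAW_LEN)
    barcode <- setNames(samples$barcode, samples$sample_id)
    index <- data.frame(id = read1$id,
                        seq = unname(barcode[provenance$sample_id]),
                        qual = strrep("F", INDEX_LEN),
                        stringsAsFactors = FALSE)
    pcrEvents <- if (length(events)) do.call(rbind, events) else
        data.frame(sample_id = character(0), amplicon_id = character(0),
                   end = integer(0), pos = integer(0), base = character(0),
                   frac = numeric(0), n_reads = integer(0))
    structure(list(read1 = read1, read2 = read2, index = index,
                   provenance = provenance, pcrEvents = pcrEvents,
                   seqErrors = seqErrors, truth = truth, config = config),
              class = "MigReadSim")
}

#' Build a MigGenotypes object directly from simulated truth
#'
#' Shortcut for analysis-level studies (segregation calibration, clone
#' identification, population differentiation) that do not need the read
#' level: converts a `MigTruth` genotype table into a
#' [MigGenotypes-class] with nominal depths and no missing data.
#'
#' @param truth A `MigTruth`.
#' @param polymorphicOnly Keep only ends carrying a planted SNP (default
#'   `TRUE`).
#' @return A [MigGenotypes-class].
#' @export
genotypesFromTruth <- function(truth, polymorphicOnly = TRUE) {
    loci <- truth$loci
    keep <- if (polymorphicOnly) !is.na(loci$snp_pos) else
        rep(TRUE, nrow(loci))
    loci <- loci[keep, , drop = FALSE]
    G <- truth$genotypes[keep, , drop = FALSE]
    samples <- truth$samples
    depth <- round(truth$config$depthMean)
    geno <- matrix(NA_character_, nrow(loci), nrow(samples))
    depthMajor <- matrix(depth, nrow(loci), nrow(samples))
    depthMinor <- matrix(0L, nrow(loci), nrow(samples))
    for (j in seq_len(nrow(samples))) {
        ploidy <- samples$ploidy[j]
        for (i in seq_len(nrow(loci))) {
            a <- c(loci$ref[i], loci$alt[i])
            if (is.na(loci$snp_pos[i])) {
                geno[i, j] <- if (ploidy == 1L) substr(loci$seq_ref[i], 1L, 1L)
                    else strrep(substr(loci$seq_ref[i], 1L, 1L), 2L)
                next
            }
            d <- G[i, j]
            if (ploidy == 1L) {
                geno[i, j] <- a[d + 1L]
            } else {
                al <- sort(c(a[(d >= 1L) + 1L], a[(d == 2L) + 1L]))
                geno[i, j] <- paste(al, collapse = "/")
                if (d == 1L) {
                    depthMajor[i, j] <- ceiling(depth / 2)
                    depthMinor[i, j] <- floor(depth / 2)
                }
            }
        }
    }
    locusInfo <- data.frame(locus_id = loci$end_id, snp_pos = loci$snp_pos,
                            alleles = ifelse(is.na(loci$snp_pos), NA,
                                paste(loci$ref, loci$alt, sep = "/")),
                            consensus = loci$seq_ref,
                            stringsAsFactors = FALSE)
    sampleInfo <- samples[, c("sample_id", "population", "ploidy")]
    MigGenotypes(geno, depthMajor, depthMinor, NULL, locusInfo, sampleInfo)
}
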