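## Scoring utilities for simulated runs: map catalog loci back to planted
## truth, measure genotype concordance, and score the PCR-error filters
## against planted events.

#' Match catalog loci to planted truth loci
#'
#' Pairs each catalog locus with the planted amplicon end whose reference
#' 80-mer is nearest (Hamming) within `maxMismatch`; ties go to the first
#' truth end.
#'
#' @param mg A [MigGenotypes-class] from [genotypeSamples()].
#' @param truth A `MigTruth`.
#' @param maxMismatch Maximum distance for a match (default the catalog
#'   mismatch budget, 4).
#' @return `data.frame` with `locus_id`, `end_id` (`NA` when unmatched)
#'   and `dist`.
#' @export
matchLociToTruth <- function(mg, truth, maxMismatch = 4L) {
    rd <- locusInfo(mg)
    loci <- rd[!duplicated(rd$locus_id), c("locus_id", "consensus")]
    hp <- hammingPairs(loci$consensus, truth$loci$seq_ref, maxMismatch)
    hp <- hp[order(hp$i, hp$dist, hp$j), ]
    hp <- hp[!duplicated(hp$i), ]
    out <- data.frame(locus_id = loci$locus_id, end_id = NA_character_,
                      dist = NA_integer_, stringsAsFactors = FALSE)
    out$end_id[hp$i] <- truth$loci$end_id[hp$j]
    out$dist[hp$i] <- hp$dist
    out
}

## True genotype string for one truth end / sample, matching the
## genotype-call encoding ("A" haploid, "A/T" diploid sorted).
truthGenotype <- function(truth, end_id, sample_id) {
    i <- match(end_id, truth$loci$end_id)
    j <- match(sample_id, truth$samples$sample_id)
    ploidy <- truth$samples$ploidy[j]
    if (is.na(truth$loci$snp_pos[i])) {
        b <- substr(truth$loci$seq_ref[i], 1L, 1L)
        return(if (ploidy == 1L) b else paste(b, b, sep = "/"))
    }
    d <- truth$genotypes[end_id, sample_id]
    a <- c(truth$loci$ref[i], truth$loci$alt[i])
    if (ploidy == 1L) return(a[d + 1L])
    paste(sort(c(a[(d >= 1L) + 1L], a[(d == 2L) + 1L])), collapse = "/")
}

#' Genotype concordance between calls and planted truth
#'
#' Compares every called genotype at rows whose catalog locus matches a
#' planted end and whose SNP position coincides with the planted SNP.
#'
#' @inheritParams matchLociToTruth
#' @return List with `byCell` (fraction of genotyped cells equal to
#'   truth), `byLocus` (fraction of rows with every genotyped cell
#'   correct), `nRows`, `nCells`.
#' @export
genotypeConcordance <- function(mg, truth) {
    mm <- matchLociToTruth(mg, truth)
    rd <- locusInfo(mg)
    g <- genoMatrix(mg)
    end_of <- setNames(mm$end_id, mm$locus_id)
    rows <- which(!is.na(rd$snp_pos) & !is.na(end_of[rd$locus_id]) &
                  rd$snp_pos == truth$loci$snp_pos[
                      match(end_of[rd$locus_id], truth$loci$end_id)])
    ok_cells <- 0L; n_cells <- 0L; ok_rows <- 0L
    for (i in rows) {
        eid <- end_of[[rd$locus_id[i]]]
        truthv <- vapply(colnames(g), function(s)
            truthGenotype(truth, eid, s), character(1))
        typed <- !is.na(g[i, ])
        hits <- g[i, typed] == truthv[typed]
        ok_cells <- ok_cells + sum(hits)
        n_cells <- n_cells + sum(typed)
        ok_rows <- ok_rows + all(hits)
    }
    list(byCell = if (n_cells) ok_cells / n_cells else NA_real_,
         byLocus = if (length(rows)) ok_rows / length(rows) else NA_real_,
         nRows = length(rows), nCells = n_cells)
}

#' Score the singleton and replicate filters against planted PCR errors
#'
#' On a simulated run, identifies the matrix rows carrying a
#' pseudo-variant — a called allele absent from the planted allele set at
#' that position (a PCR-error event whose pseudo-allele never reaches the
#' calling thresholds leaves no trace in the matrix and corrupts
#' nothing, so it is not in the denominator) — runs
#' [removeSingletonVariantLoci()] and [replicateConcordanceFilter()], and
#' reports their sensitivity on pseudo-variant rows and their removal
#' rate on clean rows (rows without pseudo-variants whose locus had no
#' recorded PCR event).
#'
#' @param mg A [MigGenotypes-class] from [genotypeSamples()].
#' @param readSim A `MigReadSim` from [simulateReads()] (carries the
#'   truth table and the planted PCR-error events).
#' @param replicatePairs Two-column matrix of replicate sample ids.
#' @return List with `sensitivity`, `cleanRemoved`, `nErrorRows`,
#'   `nCleanRows`, and the filtered `mg`.
#' @export
scoreErrorFilters <- function(mg, readSim, replicatePairs) {
    truth <- readSim$truth
    mm <- matchLociToTruth(mg, truth)
    rd <- locusInfo(mg)
    g <- genoMatrix(mg)
    end_of <- setNames(mm$end_id, mm$locus_id)
    ev <- readSim$pcrEvents
    event_ends <- if (nrow(ev)) unique(paste0(ev$amplicon_id, ":e", ev$end))
                  else character(0)
    is_pseudo <- logical(nrow(g)); has_event <- logical(nrow(g))
    for (i in which(!is.na(rd$snp_pos))) {
        eid <- end_of[[rd$locus_id[i]]]
        if (is.na(eid)) next
        ti <- match(eid, truth$loci$end_id)
        p <- rd$snp_pos[i]
        truth_alleles <- unique(c(substr(truth$loci$seq_ref[ti], p, p),
            if (!is.na(truth$loci$seq_alt[ti]))
                substr(truth$loci$seq_alt[ti], p, p)))
        called <- unique(unlist(strsplit(g[i, !is.na(g[i, ])], "/",
                                         fixed = TRUE)))
        is_pseudo[i] <- any(!called %in% truth_alleles)
        has_event[i] <- eid %in% event_ends
    }
    poly <- !is.na(rd$snp_pos)
    error_rows <- rownames(g)[poly & is_pseudo]
    clean_rows <- rownames(g)[poly & !is_pseudo & !has_event]
    s1 <- removeSingletonVariantLoci(mg)
    s2 <- replicateConcordanceFilter(s1$mg, replicatePairs)
    kept <- rownames(genoMatrix(s2$mg))
    removed <- setdiff(rownames(g), kept)
    list(sensitivity = if (length(error_rows))
             mean(error_rows %in% removed) else NA_real_,
         cleanRemoved = if (length(clean_rows))
             mean(clean_rows %in% removed) else NA_real_,
         nErrorRows = length(error_rows),
         nCleanRows = length(clean_rows),
         mg = s2$mg)
}
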