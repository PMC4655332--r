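## Preprocessing: demultiplex by exact 6-base index match, trim the 14-base
## SSR+anchor region off read 2, quality-filter (keep a read when at least
## p percent of bases reach Q>=q), and remove adapter read-through. Reads 1
## and 2 stay unpaired downstream by design: forward-reverse and
## reverse-forward amplicons of one locus would otherwise assemble as
## different paired stacks.

#' Preprocessing configuration
#'
#' @param qThreshold Minimum per-base quality (default 30).
#' @param pPercent Minimum percentage of bases at or above `qThreshold`
#'   for a read to survive (default 40).
#' @param trimRead2Bases Bases trimmed off the start of read 2 (the
#'   12-base SSR region plus 2-base anchor; default 14).
#' @param adapterRead1,adapterRead2 Sequencing-primer queries: the read-2
#'   primer region searched in read 1 and the read-1 primer region
#'   searched in the trimmed read 2 (defaults are the published
#'   sequences).
#' @param adapterMaxMismatch Mismatches tolerated in the adapter search
#'   (default 0, exact substring).
#' @param qualityOffset FASTQ quality encoding offset (default 33,
#'   Phred+33).
#' @return A list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(qThreshold = 30L, pPercent = 40,
                             trimRead2Bases = 14L,
                             adapterRead1 = ADAPTER_QUERY_READ1,
                             adapterRead2 = ADAPTER_QUERY_READ2,
                             adapterMaxMismatch = 0L, qualityOffset = 33L) {
    stopifnot(pPercent > 0, pPercent <= 100)
    structure(list(qThreshold = as.integer(qThreshold), pPercent = pPercent,
                   trimRead2Bases = as.integer(trimRead2Bases),
                   adapterRead1 = adapterRead1, adapterRead2 = adapterRead2,
                   adapterMaxMismatch = as.integer(adapterMaxMismatch),
                   qualityOffset = as.integer(qualityOffset)),
              class = "PreprocessConfig")
}

#' Demultiplex synchronized read streams by index read
#'
#' Exact-match assignment of each read triplet to the sample whose 6-base
#' barcode equals the index read; non-matching triplets go to an
#' `undetermined` group.
#'
#' @param read1,read2,index Synchronized `data.frame`s with columns `id`,
#'   `seq`, `qual` (as produced by [simulateReads()] or [readFastq()]).
#' @param barcodes Named character vector, sample id to 6-base barcode;
#'   barcodes must be mutually distinct.
#' @return List with `samples` (per sample: list of `read1`, `read2`),
#'   `undetermined` (count) and `counts` (`data.frame` of per-sample read
#'   counts).
#' @export
demultiplexReads <- function(read1, read2, index, barcodes) {
    if (anyDuplicated(barcodes))
        stop("barcode collision: barcodes must be mutually distinct")
    stopifnot(nrow(read1) == nrow(index), nrow(read2) == nrow(index))
    assign <- names(barcodes)[match(index$seq, barcodes)]
    samples <- lapply(setNames(nm = names(barcodes)), function(s) {
        sel <- which(!is.na(assign) & assign == s)
        list(read1 = read1[sel, , drop = FALSE],
             read2 = read2[sel, , drop = FALSE])
    })
    counts <- data.frame(sample_id = names(barcodes),
                         n = vapply(samples, function(x) nrow(x$read1),
                                    integer(1)), stringsAsFactors = FALSE)
    list(samples = samples, undetermined = sum(is.na(assign)),
         counts = counts)
}

#' Trim the primer region off read 2
#'
#' Removes the first `trimRead2Bases` bases (sequence and quality in
#' lockstep); a 94-base raw read 2 becomes the 80-base unit used for SNP
#' discovery. Reads shorter than the trim length are dropped.
#'
#' @param reads `data.frame` with `id`, `seq`, `qual`.
#' @param config A [preprocessConfig()].
#' @param mate Guarded precondition: must be 2 (read 1 carries no primer
#'   region to trim).
#' @return The trimmed `data.frame`; dropped reads are recorded in the
#'   `"dropped"` attribute.
#' @export
trimRead2 <- function(reads, config = preprocessConfig(), mate = 2L) {
    if (mate != 2L) stop("trimRead2 applies to read 2 only")
    n <- config$trimRead2Bases
    short <- nchar(reads$seq) < n + 1L
    out <- reads[!short, , drop = FALSE]
    out$seq <- substring(out$seq, n + 1L)
    out$qual <- substring(out$qual, n + 1L)
    attr(out, "dropped") <- sum(short)
    out
}

## Per-read percentage of bases with quality >= q (Phred+offset); computed
## on unique quality strings since simulated runs reuse few patterns.
percentAboveQ <- function(qual, q, offset) {
    uq <- unique(qual)
    pct <- vapply(uq, function(x) {
        qv <- as.integer(charToRaw(x)) - offset
        100 * mean(qv >= q)
    }, numeric(1))
    unname(pct[match(qual, uq)])
}

#' Quality filter (q/p rule)
#'
#' Keeps a read iff at least `pPercent` percent of its bases have quality
#' at or above `qThreshold` — the q = 30 / p = 40 setting of the standard
#' pipeline.
#'
#' @inheritParams trimRead2
#' @return Logical keep vector, one element per read.
#' @export
qualityFilter <- function(reads, config = preprocessConfig()) {
    if (nrow(reads) == 0L) return(logical(0))
    percentAboveQ(reads$qual, config$qThreshold, config$qualityOffset) >=
        config$pPercent
}

#' Remove adapter read-through
#'
#' Drops reads containing the mate-appropriate sequencing-primer query as
#' a substring (the signature of an extremely short library insert): the
#' read-2 primer region is searched in read 1 and the read-1 primer
#' region in the trimmed read 2.
#'
#' @inheritParams trimRead2
#' @param mate 1 or 2.
#' @return Logical keep vector.
#' @export
removeAdapterReads <- function(reads, mate, config = preprocessConfig()) {
    if (nrow(reads) == 0L) return(logical(0))
    query <- if (mate == 1L) config$adapterRead1 else config$adapterRead2
    if (config$adapterMaxMismatch == 0L) {
        !grepl(query, reads$seq, fixed = TRUE)
    } else {
        Biostrings::vcountPattern(query,
            Biostrings::DNAStringSet(reads$seq),
            max.mismatch = config$adapterMaxMismatch) == 0L
    }
}

#' Run the full preprocessing chain for one sample
#'
#' Trims read 2, quality-filters both mates, screens adapters, and pools
#' the surviving 80-base units (reads 1 and 2 treated as independent
#' reads).
#'
#' @param read1,read2 `data.frame`s with `id`, `seq`, `qual` for one
#'   sample.
#' @param config A [preprocessConfig()].
#' @return List with `reads` (character vector of 80-base sequences),
#'   `report` (`data.frame` of drop reasons and survivor counts; reasons
#'   plus survivors sum to the input count).
#' @export
preprocessSample <- function(read1, read2, config = preprocessConfig()) {
    n_in <- nrow(read1) + nrow(read2)
    r2 <- trimRead2(read2, config)
    n_short <- attr(r2, "dropped")
    k1q <- qualityFilter(read1, config)
    k2q <- qualityFilter(r2, config)
    r1 <- read1[k1q, , drop = FALSE]; r2 <- r2[k2q, , drop = FALSE]
    k1a <- removeAdapterReads(r1, 1L, config)
    k2a <- removeAdapterReads(r2, 2L, config)
    r1 <- r1[k1a, , drop = FALSE]; r2 <- r2[k2a, , drop = FALSE]
    report <- data.frame(
        reason = c("too_short", "low_quality", "adapter", "survived"),
        n = c(n_short, sum(!k1q) + sum(!k2q), sum(!k1a) + sum(!k2a),
              nrow(r1) + nrow(r2)))
    stopifnot(sum(report$n) == n_in)
    list(reads = c(r1$seq, r2$seq), report = report)
}

#' Demultiplex and preprocess a simulated run into per-sample read pools
#'
#' @param readSim A `MigReadSim` from [simulateReads()].
#' @param config A [preprocessConfig()].
#' @return List with `pools` (named list, sample id to character vector of
#'   80-base reads), `reports`, `undetermined`.
#' @export
preprocessRun <- function(readSim, config = preprocessConfig()) {
    barcodes <- setNames(readSim$truth$samples$barcode,
                         readSim$truth$samples$sample_id)
    dm <- demultiplexReads(readSim$read1, readSim$read2, readSim$index,
                           barcodes)
    res <- lapply(dm$samples, function(s)
        preprocessSample(s$read1, s$read2, config))
    list(pools = lapply(res, `[[`, "reads"),
         reports = lapply(res, `[[`, "report"),
         undetermined = dm$undetermined)
}
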