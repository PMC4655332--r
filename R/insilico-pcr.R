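## In-silico multiplexed ISSR-PCR: locate primer annealing footprints on a
## genome, pair convergent footprints into size-selected amplicons, and pull
## the 80-base end reads that the sequencer would deliver.

## Unique annealing designs of a primer set: one row per 14-base annealing
## sequence with the design name (direction suffix stripped).
annealingDesigns <- function(primers) {
    if (is(primers, "MigPrimerSet")) primers <- primerTable(primers)
    fwd <- primers[primers$direction == "forward", , drop = FALSE]
    data.frame(name = sub("-f$", "", fwd$name),
               annealing_seq = fwd$annealing_seq, stringsAsFactors = FALSE)
}

#' Find primer annealing sites on a genome
#'
#' Reports every 14-base footprint, on either strand, where a primer's
#' 3'-terminal `exact3` bases match exactly and the remaining 5' bases
#' match with at most `maxMismatch5` mismatches. The defaults (six exact
#' 3' bases — the 2-base anchor plus one repeat unit — and zero 5'
#' mismatches) give strict perfect-site prediction; raising `maxMismatch5`
#' models the permissive annealing of low-stringency PCR.
#'
#' @param genome A [Biostrings::DNAStringSet], a single string, or a path
#'   to a FASTA file.
#' @param primers A [MigPrimerSet-class] (or tailed-primer `data.frame`).
#' @param maxMismatch5 Maximum mismatches tolerated in the 5' part of the
#'   14-base annealing sequence (default 0).
#' @param exact3 Number of 3'-terminal bases required to match exactly
#'   (default 6, at most 14).
#' @return A sorted [GenomicRanges::GRanges] of 14-base footprints with
#'   metadata columns `primer_name` and `mismatches`. A `-` strand
#'   footprint means the primer anneals to the reverse-complement strand.
#' @export
findAnnealingSites <- function(genome, primers, maxMismatch5 = 0L,
                               exact3 = 6L) {
    stopifnot(exact3 >= 1L, exact3 <= 14L)
    genome <- asGenome(genome)
    af <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
    nonACGT <- sum(af[setdiff(names(af), c("A", "C", "G", "T"))])
    if (nonACGT > 0L)
        warning(nonACGT, " non-ACGT genome positions cannot anneal and are skipped")
    designs <- annealingDesigns(primers)
    hits <- list()
    for (contig in names(genome)) {
        subj <- genome[[contig]]
        for (k in seq_len(nrow(designs))) {
            a <- designs$annealing_seq[k]
            for (str in c("+", "-")) {
                pat <- if (str == "+") a else revComp(a)
                m <- Biostrings::matchPattern(pat, subj,
                                              max.mismatch = maxMismatch5)
                if (length(m) == 0L) next
                ## Observed footprint in primer orientation, to count 5'
                ## mismatches and enforce the exact 3' block.
                obs <- as.character(m)
                if (str == "-") obs <- revComp(obs)
                ok <- substr(obs, 14L - exact3 + 1L, 14L) ==
                      substr(a, 14L - exact3 + 1L, 14L)
                mm5 <- hammingDist(substr(a, 1L, 14L - exact3),
                                   substr(obs, 1L, 14L - exact3))
                keep <- ok & mm5 <= maxMismatch5 & !grepl("[^ACGT]", obs)
                if (!any(keep)) next
                gr <- GenomicRanges::GRanges(contig,
                        IRanges::IRanges(BiocGenerics::start(m)[keep],
                                         BiocGenerics::end(m)[keep]),
                        strand = str)
                S4Vectors::mcols(gr)$primer_name <- designs$name[k]
                S4Vectors::mcols(gr)$mismatches <- mm5[keep]
                hits[[length(hits) + 1L]] <- gr
            }
        }
    }
    if (length(hits) == 0L) {
        out <- GenomicRanges::GRanges()
        S4Vectors::mcols(out)$primer_name <- character(0)
        S4Vectors::mcols(out)$mismatches <- integer(0)
        return(out)
    }
    out <- sort(do.call(c, hits), ignore.strand = TRUE)
    names(out) <- NULL
    out
}

## Coerce genome inputs (path, string, DNAStringSet) to a named DNAStringSet.
asGenome <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        g <- genome
    } else if (is.character(genome) && length(genome) == 1L &&
               file.exists(genome)) {
        g <- Biostrings::readDNAStringSet(genome)
    } else {
        g <- Biostrings::DNAStringSet(genome)
    }
    if (is.null(names(g))) names(g) <- paste0("contig", seq_along(g))
    names(g) <- sub("\\s.*$", "", names(g))
    g
}

#' Pair convergent annealing sites into size-selected amplicons
#'
#' Every (+, -) convergent footprint pair on one contig becomes a
#' candidate amplicon; any primer may pair with any primer. The size gate
#' applies to the library length: the genomic span from the start of the
#' forward footprint to the end of the reverse footprint plus `tailBases`
#' non-genomic tail bases (17 per end: 14-base tail + 3-base 2nd-PCR
#' anchor). Nested and overlapping amplicons are all reported; half of the
#' PCR product mass is forward-forward / reverse-reverse and unsequenceable,
#' so `sequenceable_fraction` is 0.5 throughout.
#'
#' @param sites [GenomicRanges::GRanges] from [findAnnealingSites()].
#' @param minLen,maxLen Library-size selection window in bases (default
#'   300-800).
#' @param tailBases Non-genomic bases added to the genomic span (default
#'   34).
#' @return A [GenomicRanges::GRanges] spanning each amplicon's genomic
#'   footprint, with metadata `amplicon_id`, `fwd_primer`, `rev_primer`,
#'   `insert_start`, `insert_end`, `genomic_len`, `library_len`,
#'   `sequenceable_fraction`.
#' @export
predictAmplicons <- function(sites, minLen = 300L, maxLen = 800L,
                             tailBases = 34L) {
    stopifnot(minLen > 0L, minLen < maxLen)
    empty <- GenomicRanges::GRanges()
    if (length(sites) == 0L) return(empty)
    res <- list()
    for (contig in unique(as.character(GenomicRanges::seqnames(sites)))) {
        s <- sites[GenomicRanges::seqnames(sites) == contig]
        fwd <- s[GenomicRanges::strand(s) == "+"]
        rev <- s[GenomicRanges::strand(s) == "-"]
        if (length(fwd) == 0L || length(rev) == 0L) next
        grid <- expand.grid(f = seq_along(fwd), r = seq_along(rev))
        fs <- GenomicRanges::start(fwd)[grid$f]
        fe <- GenomicRanges::end(fwd)[grid$f]
        rs <- GenomicRanges::start(rev)[grid$r]
        re <- GenomicRanges::end(rev)[grid$r]
        glen <- re - fs + 1L
        keep <- rs > fe & (glen + tailBases) >= minLen &
                (glen + tailBases) <= maxLen
        if (!any(keep)) next
        gr <- GenomicRanges::GRanges(contig,
                IRanges::IRanges(fs[keep], re[keep]), strand = "+")
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            fwd_primer = S4Vectors::mcols(fwd)$primer_name[grid$f[keep]],
            rev_primer = S4Vectors::mcols(rev)$primer_name[grid$r[keep]],
            insert_start = fe[keep] + 1L, insert_end = rs[keep] - 1L,
            genomic_len = glen[keep],
            library_len = glen[keep] + tailBases,
            sequenceable_fraction = 0.5)
        res[[length(res) + 1L]] <- gr
    }
    if (length(res) == 0L) return(empty)
    out <- sort(do.call(c, res), ignore.strand = TRUE)
    S4Vectors::mcols(out)$amplicon_id <-
        sprintf("AMP%05d", seq_along(out))
    out
}

#' Extract the two 80-base end reads of predicted amplicons
#'
#' Read 1 is the 80 genomic bases immediately interior to the forward
#' footprint (top strand); read 2 is the 80 bases immediately interior to
#' the reverse footprint, reported on the bottom strand as sequenced.
#' Within the 300-800 library window the two reads cannot overlap; inserts
#' shorter than 160 bases are flagged `overlap_risk` and the reads are
#' still emitted.
#'
#' @param amplicons [GenomicRanges::GRanges] from [predictAmplicons()].
#' @param genome Genome as accepted by [findAnnealingSites()].
#' @return `data.frame` with one row per amplicon: `locus_id`, `contig`,
#'   `insert_start`, `insert_end`, `fwd_primer`, `rev_primer`,
#'   `read1_seq`, `read2_seq`, `overlap_risk`.
#' @export
extractLocusReads <- function(amplicons, genome) {
    genome <- asGenome(genome)
    mc <- S4Vectors::mcols(amplicons)
    contig <- as.character(GenomicRanges::seqnames(amplicons))
    ins_s <- mc$insert_start
    ins_e <- mc$insert_end
    insert_len <- ins_e - ins_s + 1L
    read1 <- character(length(amplicons))
    read2 <- character(length(amplicons))
    for (i in seq_along(amplicons)) {
        subj <- genome[[contig[i]]]
        r1_end <- min(ins_s[i] + READ_LEN - 1L, length(subj))
        read1[i] <- as.character(Biostrings::subseq(subj, ins_s[i], r1_end))
        r2_start <- max(ins_e[i] - READ_LEN + 1L, 1L)
        read2[i] <- revComp(as.character(
            Biostrings::subseq(subj, r2_start, ins_e[i])))
    }
    data.frame(
        locus_id = mc$amplicon_id %||% sprintf("AMP%05d", seq_along(amplicons)),
        contig = contig, insert_start = ins_s, insert_end = ins_e,
        fwd_primer = mc$fwd_primer, rev_primer = mc$rev_primer,
        read1_seq = read1, read2_seq = read2,
        overlap_risk = insert_len < 2L * READ_LEN,
        stringsAsFactors = FALSE)
}

#' Export predicted loci as BED and FASTA
#'
#' Writes a BED6 of insert coordinates (0-based half-open, as BED
#' requires; internal coordinates are 1-based) and a FASTA holding both
#' end-read templates per locus, named `<locus_id>|read1` /
#' `<locus_id>|read2`.
#'
#' @param templates `data.frame` from [extractLocusReads()].
#' @param bedPath,fastaPath Output paths (either may be `NULL` to skip).
#' @return Invisibly, the BED `data.frame`.
#' @export
exportLoci <- function(templates, bedPath = NULL, fastaPath = NULL) {
    stopifnot(nrow(templates) > 0L)
    bed <- data.frame(
        chrom = templates$contig,
        chromStart = templates$insert_start - 1L,
        chromEnd = templates$insert_end,
        name = paste0(templates$locus_id, ":", templates$fwd_primer, "x",
                      templates$rev_primer),
        score = 0L, strand = "+", stringsAsFactors = FALSE)
    if (!is.null(bedPath)) {
        write.table(bed, bedPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(fastaPath)) {
        seqs <- Biostrings::DNAStringSet(
            setNames(c(templates$read1_seq, templates$read2_seq),
                     c(paste0(templates$locus_id, "|read1"),
                       paste0(templates$locus_id, "|read2"))))
        Biostrings::writeXStringSet(seqs, fastaPath)
    }
    invisible(bed)
}
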