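## Independent naive oracles and small fixture builders. These stay pure-R
## and position-by-position so they cannot share code paths with the
## implementation they check.

## Naive annealing-site scan: position-by-position mismatch counting with
## an exact 3'-block requirement.
naiveSites <- function(genome_str, designs, mm5 = 0L, exact3 = 6L) {
    L <- nchar(genome_str)
    gch <- strsplit(genome_str, "")[[1L]]
    out <- list()
    for (k in seq_len(nrow(designs))) {
        a <- designs$annealing_seq[k]
        for (str in c("+", "-")) {
            pat <- if (str == "+") a else
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(a)))
            pch <- strsplit(pat, "")[[1L]]
            if (L < 14L) next
            mism <- rep(0L, L - 13L)
            for (p in 1:14)
                mism <- mism + (gch[p:(L - 14L + p)] != pch[p])
            ## per-window mismatch split into 5' part and 3' block, in
            ## primer orientation
            prim3 <- if (str == "+") (15L - exact3):14L else 1L:exact3
            m3 <- rep(0L, L - 13L)
            for (p in prim3)
                m3 <- m3 + (gch[p:(L - 14L + p)] != pch[p])
            hit <- which(m3 == 0L & (mism - m3) <= mm5)
            if (length(hit))
                out[[length(out) + 1L]] <- data.frame(
                    start = hit, end = hit + 13L, strand = str,
                    primer_name = designs$name[k],
                    mismatches = (mism - m3)[hit])
        }
    }
    if (length(out) == 0L)
        return(data.frame(start = integer(0), end = integer(0),
                          strand = character(0), primer_name = character(0),
                          mismatches = integer(0)))
    res <- do.call(rbind, out)
    res[order(res$start, res$strand, res$primer_name), ]
}

## Naive all-pairs amplicon enumeration on a naive site table.
naiveAmplicons <- function(sites, minLen = 300L, maxLen = 800L,
                           tailBases = 34L) {
    fwd <- sites[sites$strand == "+", , drop = FALSE]
    rev <- sites[sites$strand == "-", , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(fwd))) {
        for (j in seq_len(nrow(rev))) {
            if (rev$start[j] <= fwd$end[i]) next
            glen <- rev$end[j] - fwd$start[i] + 1L
            lib <- glen + tailBases
            if (lib < minLen || lib > maxLen) next
            out[[length(out) + 1L]] <- data.frame(
                start = fwd$start[i], end = rev$end[j],
                fwd_primer = fwd$primer_name[i],
                rev_primer = rev$primer_name[j], library_len = lib)
        }
    }
    if (length(out) == 0L)
        return(data.frame(start = integer(0), end = integer(0),
                          fwd_primer = character(0),
                          rev_primer = character(0),
                          library_len = integer(0)))
    res <- do.call(rbind, out)
    res[order(res$start, res$end, res$fwd_primer, res$rev_primer), ]
}

## Naive shifted identity: double loop over offsets and positions.
naiveMaxShiftedIdentity <- function(a, b, maxShift = 16L) {
    ach <- strsplit(a, "")[[1L]]; bch <- strsplit(b, "")[[1L]]
    len <- length(ach)
    best <- 0
    for (s in (-(maxShift - 1L)):(maxShift - 1L)) {
        m <- 0L
        for (i in seq_len(len)) {
            j <- i + s
            if (j >= 1L && j <= len && ach[j] == bch[i]) m <- m + 1L
        }
        best <- max(best, m / len)
    }
    best
}

## Compact MigGenotypes fixture builder for QC/analysis tests. `geno` is a
## loci x samples character matrix; consensus sequences default to fixed
## random 80-mers (seeded) so homology filters see unrelated loci.
makeGeno <- function(geno, ploidy = NULL, population = NULL,
                     consensus = NULL, snp_pos = NULL, hetFlag = NULL,
                     depthMajor = NULL, depthMinor = NULL, seed = 424L) {
    geno <- as.matrix(geno)
    nL <- nrow(geno); nS <- ncol(geno)
    if (is.null(colnames(geno)))
        colnames(geno) <- sprintf("s%02d", seq_len(nS))
    if (is.null(rownames(geno)))
        rownames(geno) <- sprintf("L%03d", seq_len(nL))
    if (is.null(ploidy))
        ploidy <- ifelse(apply(geno, 2L, function(x)
            any(grepl("/", x[!is.na(x)]))), 2L, 1L)
    if (is.null(population)) population <- rep("pop1", nS)
    if (is.null(consensus)) {
        set.seed(seed)
        consensus <- vapply(seq_len(nL), function(i)
            paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
            character(1))
    }
    alleles <- vapply(seq_len(nL), function(i) {
        al <- sort(unique(unlist(strsplit(geno[i, !is.na(geno[i, ])], "/"))))
        if (length(al) < 2L) NA_character_ else
            paste(al[1:2], collapse = "/")
    }, character(1))
    if (is.null(snp_pos)) snp_pos <- ifelse(is.na(alleles), NA_integer_, 1L)
    locusInfo <- data.frame(locus_id = rownames(geno), snp_pos = snp_pos,
                            alleles = alleles, consensus = consensus,
                            stringsAsFactors = FALSE)
    sampleInfo <- data.frame(sample_id = colnames(geno),
                             population = population,
                             ploidy = as.integer(ploidy),
                             stringsAsFactors = FALSE)
    MigGenotypes(geno, depthMajor = depthMajor, depthMinor = depthMinor,
                 hetFlag = hetFlag, locusInfo = locusInfo,
                 sampleInfo = sampleInfo)
}

randSeq80 <- function(n = 1L) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
        character(1))
}
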