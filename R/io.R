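## File I/O: FASTQ via Biostrings, genotype matrices as TSV, a minimal
## VCF 4.2 export, locus FASTA, and primer-set TSV.

#' Write and read FASTQ
#'
#' `writeFastq()` writes a `data.frame` of `id`, `seq`, `qual` (Phred+33)
#' to a FASTQ file (gzip when the path ends in `.gz`); `readFastq()`
#' reads one back into the same shape.
#'
#' @param reads `data.frame` with `id`, `seq`, `qual`.
#' @param path Output/input path.
#' @return `writeFastq()` the path, invisibly; `readFastq()` the
#'   `data.frame`.
#' @export
writeFastq <- function(reads, path) {
    seqs <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
    qual <- Biostrings::BStringSet(reads$qual)
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = qual,
                                compress = grepl("\\.gz$", path))
    invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    data.frame(id = names(x), seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE)
}

#' Export a genotype matrix as TSV
#'
#' Samples x SNPs table with alleles as `A/T` pairs (single bases for
#' haploids) and `.` for missing data, preceded by locus metadata
#' columns.
#'
#' @param mg A [MigGenotypes-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenotypeTSV <- function(mg, path) {
    g <- genoMatrix(mg)
    g[is.na(g)] <- "."
    out <- cbind(locusInfo(mg)[, c("locus_id", "snp_pos", "alleles")],
                 as.data.frame(g, stringsAsFactors = FALSE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a genotype TSV back into a MigGenotypes
#'
#' @param path TSV from [writeGenotypeTSV()].
#' @param samples Optional `data.frame` with `sample_id`, `population`,
#'   `ploidy`; inferred as one diploid population when absent (haploid
#'   when calls carry no `/`).
#' @return A [MigGenotypes-class] (consensus sequences are not stored in
#'   the TSV and come back as `NA`).
#' @export
readGenotypeTSV <- function(path, samples = NULL) {
    x <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
    meta <- c("locus_id", "snp_pos", "alleles")
    g <- as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
    g[g == "."] <- NA
    if (is.null(samples)) {
        hap <- apply(g, 2L, function(col) all(is.na(col) | !grepl("/", col)))
        samples <- data.frame(sample_id = colnames(g), population = "pop1",
                              ploidy = ifelse(hap, 1L, 2L),
                              stringsAsFactors = FALSE)
    }
    locusInfo <- data.frame(
        locus_id = x$locus_id,
        snp_pos = suppressWarnings(as.integer(x$snp_pos)),
        alleles = ifelse(x$alleles == "NA", NA, x$alleles),
        consensus = NA_character_, stringsAsFactors = FALSE)
    MigGenotypes(g, locusInfo = locusInfo,
                 sampleInfo = samples[match(colnames(g),
                                            samples$sample_id), ])
}

#' Minimal VCF 4.2 export
#'
#' One record per SNP row: CHROM is the locus id, POS the 1-based SNP
#' offset within the 80-base consensus, GT-only genotypes (`.` missing,
#' unphased).
#'
#' @param mg A [MigGenotypes-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenotypeVCF <- function(mg, path) {
    rd <- locusInfo(mg)
    g <- genoMatrix(mg)
    keep <- !is.na(rd$snp_pos) & !is.na(rd$alleles)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=migseqr",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(g)),
                       collapse = "\t")), con)
    for (i in which(keep)) {
        al <- strsplit(rd$alleles[i], "/", fixed = TRUE)[[1L]]
        ref <- al[1L]; alt <- paste(al[-1L], collapse = ",")
        gt <- vapply(g[i, ], function(x) {
            if (is.na(x)) return(".")
            a <- strsplit(x, "/", fixed = TRUE)[[1L]]
            paste(match(a, al) - 1L, collapse = "/")
        }, character(1))
        writeLines(paste(c(rd$locus_id[i], rd$snp_pos[i], rownames(g)[i],
                           ref, alt, ".", "PASS", ".", "GT", gt),
                         collapse = "\t"), con)
    }
    invisible(path)
}

#' Export locus consensus sequences as FASTA
#'
#' @param mg A [MigGenotypes-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeLocusFasta <- function(mg, path) {
    rd <- locusInfo(mg)
    rd <- rd[!duplicated(rd$locus_id) & !is.na(rd$consensus), ]
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(rd$consensus, rd$locus_id)), path)
    invisible(path)
}

#' Export a primer set as TSV
#'
#' Columns `name`, `direction`, `full_seq`, `core`, `anchor`, `set`; the
#' companion [readPrimerTSV()] restores a [MigPrimerSet-class].
#'
#' @param ps A [MigPrimerSet-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePrimerTSV <- function(ps, path) {
    p <- primerTable(ps)
    out <- data.frame(name = p$name, direction = p$direction,
                      full_seq = p$full_seq, core = p$core,
                      repeats = p$repeats, anchor = p$anchor,
                      annealing_seq = p$annealing_seq, set = setName(ps),
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePrimerTSV
#' @export
readPrimerTSV <- function(path) {
    x <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character")
    x$repeats <- as.integer(x$repeats)
    newMigPrimerSet(unique(x$set)[1L],
                    x[, c("name", "direction", "core", "repeats", "anchor",
                          "annealing_seq", "full_seq")])
}
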