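#' MigPrimerSet: a multiplex set of tailed ISSR primers
#'
#' Container for a multiplex 1st-PCR primer set. Each annealing design (a
#' 12-base SSR core plus 2-base anchor) contributes a forward and a reverse
#' tailed primer that differ only in their constant tail + 2nd-PCR anchor.
#'
#' @slot setName Set label, e.g. `"set-1"` or `"custom"`.
#' @slot primers `data.frame` with one row per tailed primer and columns
#'   `name`, `direction` (`"forward"`/`"reverse"`), `core`, `repeats`,
#'   `anchor`, `annealing_seq` (14 nt), `full_seq` (31 nt).
#' @slot compatibilityOk Logical; `TRUE` when no member's 3'-terminal 3-mer
#'   has a reverse-complement match inside any other member's full sequence.
#' @slot conflictLog `data.frame` of conflicting pairs (`primer_a`,
#'   `primer_b`, `conflict_seq`); zero rows when compatible.
#'
#' @aliases MigPrimerSet
#' @seealso [selectMultiplexSet()], [migPrimerSet1()]
#' @export
setClass("MigPrimerSet",
    representation(
        setName = "character",
        primers = "data.frame",
        compatibilityOk = "logical",
        conflictLog = "data.frame"
    )
)

setValidity("MigPrimerSet", function(object) {
    p <- object@primers
    need <- c("name", "direction", "core", "repeats", "anchor",
              "annealing_seq", "full_seq")
    if (!all(need %in% names(p)))
        return(paste("primers lacks columns:",
                     paste(setdiff(need, names(p)), collapse = ", ")))
    if (nrow(p) < 1L)
        return("a primer set must have at least one member")
    if (!all(p$direction %in% c("forward", "reverse")))
        return("direction must be 'forward' or 'reverse'")
    if (!all(nchar(p$annealing_seq) == 14L))
        return("annealing sequences must be 14 nt")
    if (!all(nchar(p$full_seq) == 31L))
        return("tailed primers must be 31 nt")
    TRUE
})

## Internal constructor from a tailed-primer table.
newMigPrimerSet <- function(setName, primers, compatibilityOk = NA,
                            conflictLog = emptyConflictLog()) {
    if (is.na(compatibilityOk)) {
        conflictLog <- crossDimerConflicts(primers)
        compatibilityOk <- nrow(conflictLog) == 0L
    }
    new("MigPrimerSet", setName = setName, primers = primers,
        compatibilityOk = compatibilityOk, conflictLog = conflictLog)
}

emptyConflictLog <- function() {
    data.frame(primer_a = character(0), primer_b = character(0),
               conflict_seq = character(0), stringsAsFactors = FALSE)
}

#' @describeIn MigPrimerSet-class Number of tailed primers (two per design).
#' @param x,object A `MigPrimerSet`.
#' @export
setMethod("length", "MigPrimerSet", function(x) nrow(x@primers))

#' Accessors for MigPrimerSet
#'
#' `primerTable()` returns the tailed-primer table; `setName()` the set
#' label; `isCompatible()` the multiplex-compatibility flag;
#' `conflictLog()` the table of 3'-complementarity conflicts.
#'
#' @param x A [MigPrimerSet-class].
#' @return See individual descriptions.
#' @name primerTable
#' @export
primerTable <- function(x) x@primers

#' @rdname primerTable
#' @export
setName <- function(x) x@setName

#' @rdname primerTable
#' @export
isCompatible <- function(x) x@compatibilityOk

#' @rdname primerTable
#' @export
conflictLog <- function(x) x@conflictLog

setMethod("show", "MigPrimerSet", function(object) {
    p <- object@primers
    cat("MigPrimerSet '", object@setName, "': ",
        sum(p$direction == "forward"), " designs, ", nrow(p),
        " tailed primers\n", sep = "")
    cat("  multiplex-compatible: ", object@compatibilityOk,
        if (!object@compatibilityOk)
            paste0(" (", nrow(object@conflictLog), " conflicts)") else "",
        "\n", sep = "")
    show_n <- utils::head(unique(p$name[p$direction == "forward"]), 8L)
    cat("  designs: ", paste(sub("-f$", "", show_n), collapse = ", "), "\n",
        sep = "")
})

#' MigGenotypes: a samples-by-loci SNP genotype container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with one row per
#' locus (or per SNP site when multiple SNPs per locus are kept) and one
#' column per sample. A locus not detected in a sample is missing data
#' (`NA`), never homozygous reference.
#'
#' Assays:
#' * `geno` — character; diploid calls as sorted `"A/T"` pairs, haploid
#'   calls as a single base, `NA` for missing.
#' * `depthMajor`, `depthMinor` — read depth of the major and minor allele
#'   at the row's SNP site (minor depth 0 for homozygous calls).
#' * `hetFlag` — logical; for haploid samples, `TRUE` when the diploid
#'   depth-ratio rule would have called a heterozygote (the duplicated-locus
#'   signature); `FALSE`/`NA` otherwise.
#'
#' Row metadata: `locus_id`, `snp_pos` (1-based offset within the 80-base
#' consensus, `NA` for monomorphic loci), `alleles` (`"A/T"`), `consensus`.
#' Column metadata: `sample_id`, `population`, `ploidy` (1 or 2).
#'
#' @aliases MigGenotypes
#' @seealso [genotypeSamples()], [genotypesFromTruth()]
#' @export
setClass("MigGenotypes", contains = "SummarizedExperiment")

setValidity("MigGenotypes", function(object) {
    need <- c("geno", "depthMajor", "depthMinor", "hetFlag")
    if (!all(need %in% SummarizedExperiment::assayNames(object)))
        return(paste("missing assays:",
                     paste(setdiff(need, SummarizedExperiment::assayNames(object)),
                           collapse = ", ")))
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("locus_id", "snp_pos", "alleles", "consensus") %in% names(rd)))
        return("rowData must have locus_id, snp_pos, alleles, consensus")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sample_id", "population", "ploidy") %in% names(cd)))
        return("colData must have sample_id, population, ploidy")
    if (!all(cd$ploidy %in% c(1L, 2L)))
        return("ploidy must be 1 or 2")
    TRUE
})

#' Construct a MigGenotypes object
#'
#' @param geno Character matrix (loci x samples) of genotype calls.
#' @param depthMajor,depthMinor Integer matrices of per-cell allele depths;
#'   default all-zero / all-`depthMajor` companions.
#' @param hetFlag Logical matrix of haploid-heterozygote flags; default all
#'   `FALSE`.
#' @param locusInfo `data.frame` with columns `locus_id`, `snp_pos`,
#'   `alleles`, `consensus` (one row per matrix row).
#' @param sampleInfo `data.frame` with columns `sample_id`, `population`,
#'   `ploidy` (one row per matrix column).
#' @return A [MigGenotypes-class].
#' @export
MigGenotypes <- function(geno, depthMajor = NULL, depthMinor = NULL,
                         hetFlag = NULL, locusInfo, sampleInfo) {
    geno <- as.matrix(geno)
    if (is.null(depthMajor))
        depthMajor <- matrix(0L, nrow(geno), ncol(geno))
    if (is.null(depthMinor))
        depthMinor <- matrix(0L, nrow(geno), ncol(geno))
    if (is.null(hetFlag))
        hetFlag <- matrix(FALSE, nrow(geno), ncol(geno))
    dimnames(geno) <- list(locusInfo$locus_row_id %||% rownames(geno),
                           sampleInfo$sample_id)
    if (is.null(rownames(geno)))
        rownames(geno) <- make.unique(locusInfo$locus_id, sep = "_snp")
    dn <- dimnames(geno)
    dimnames(depthMajor) <- dimnames(depthMinor) <- dimnames(hetFlag) <- dn
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(geno = geno, depthMajor = depthMajor,
                      depthMinor = depthMinor, hetFlag = hetFlag),
        rowData = locusInfo, colData = sampleInfo)
    new("MigGenotypes", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for MigGenotypes
#'
#' `genoMatrix()` returns the genotype-call matrix; `locusInfo()` and
#' `sampleInfo()` the row and column metadata as plain data.frames;
#' `consensusSeqs()` the per-locus 80-base consensus sequences (named by
#' locus id); `hetFlags()` the haploid-heterozygote flag matrix.
#'
#' @param x A [MigGenotypes-class].
#' @name genoMatrix
#' @export
genoMatrix <- function(x) SummarizedExperiment::assay(x, "geno")

#' @rdname genoMatrix
#' @export
locusInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname genoMatrix
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @rdname genoMatrix
#' @export
consensusSeqs <- function(x) {
    rd <- locusInfo(x)
    setNames(rd$consensus, rd$locus_id)
}

#' @rdname genoMatrix
#' @export
hetFlags <- function(x) SummarizedExperiment::assay(x, "hetFlag")

setMethod("show", "MigGenotypes", function(object) {
    g <- genoMatrix(object)
    cat("MigGenotypes: ", nrow(g), " locus rows x ", ncol(g), " samples\n",
        sep = "")
    rd <- locusInfo(object)
    cat("  polymorphic rows: ", sum(!is.na(rd$snp_pos)),
        "; missing cells: ", sum(is.na(g)), "/", length(g), "\n", sep = "")
    cd <- sampleInfo(object)
    cat("  populations: ", paste(unique(cd$population), collapse = ", "),
        "; haploid samples: ", sum(cd$ploidy == 1L), "\n", sep = "")
})
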