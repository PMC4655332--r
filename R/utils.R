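## Small sequence utilities shared across modules. All sequences handled as
## uppercase ACGT character vectors; Biostrings objects are converted at the
## boundary.

DNA_BASES_CHR <- c("A", "C", "G", "T")

#' Reverse complement of plain character sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on
#' character vectors, used throughout the primer-design and simulation code.
#'
#' @param x Character vector of DNA sequences (uppercase ACGT).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revComp(c("ACGT", "AACC"))
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Validate that sequences are uppercase ACGT only (ambiguity codes rejected).
assertACGT <- function(x, what = "sequence") {
    bad <- grepl("[^ACGT]", x)
    if (any(bad)) {
        stop(what, " contains non-ACGT characters: ",
             paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
    }
    invisible(x)
}

## Hamming distance between one query and a vector of equal-length subjects.
hammingDist <- function(a, y) {
    if (length(y) == 0L) return(integer(0))
    stopifnot(all(nchar(y) == nchar(a)))
    hamming_dist_cpp(a, y)
}

## All pairs (i, j) with hamming(x[i], y[j]) <= maxd, as a data.frame.
hammingPairs <- function(x, y, maxd) {
    m <- hamming_pairs_cpp(as.character(x), as.character(y), as.integer(maxd))
    data.frame(i = m[, 1L], j = m[, 2L], dist = m[, 3L])
}

#' Shifted-overlap sequence identity
#'
#' Ungapped identity between two equal-length reads when one is slid by a
#' fixed offset relative to the other: the number of matching positions in
#' the overlap divided by the full read length. This full-length denominator
#' is the quantity the shifted-priming pseudo-locus filter thresholds; two
#' identical 80-base reads offset by 16 bases at each end retain
#' (80 - 16 - 16) / 80 = 0.6 identity.
#'
#' @param a,b Equal-length DNA strings.
#' @param shift Integer offset applied to `b` relative to `a`; position
#'   `i + shift` of `a` is compared with position `i` of `b`.
#' @return Fraction of the full read length that matches, in `[0, 1]`.
#' @seealso [shiftedHomologyFilter()] which scans all offsets strictly
#'   inside `(-maxShift, maxShift)` and takes the maximum.
#' @export
#' @examples
#' shiftedIdentity("ACGTACGT", "ACGTACGT", 0)   # 1
#' shiftedIdentity("AAAACGTG", "ACGTGAAA", -3)  # 5/8
shiftedIdentity <- function(a, b, shift = 0L) {
    shifted_identity_cpp(as.character(a), as.character(b), as.integer(shift))
}

## Maximum shifted identity per sequence pair, pairs above threshold only.
maxShiftedIdentity <- function(seqs, maxShift = 16L, threshold = 0) {
    m <- max_shifted_identity_cpp(as.character(seqs), as.integer(maxShift),
                                  as.numeric(threshold))
    data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]),
               identity = m[, 3L], shift = as.integer(m[, 4L]))
}

## Draw `n` random bases as a single string each.
randomSeq <- function(n, len) {
    vapply(seq_len(n), function(i) {
        paste(sample(DNA_BASES_CHR, len, replace = TRUE), collapse = "")
    }, character(1))
}

## Substitute base `base` at position `pos` (1-based) of string `x`.
substituteBase <- function(x, pos, base) {
    substr(x, pos, pos) <- base
    x
}

## A base different from `b`, deterministic under the current RNG stream.
otherBase <- function(b) {
    vapply(b, function(x) sample(setdiff(DNA_BASES_CHR, x), 1L), character(1),
           USE.NAMES = FALSE)
}
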