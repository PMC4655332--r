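## Published constants of the MIG-seq library design: tail/anchor sequences of
## the 1st-PCR primers, the recommended set-1 primer pairs, the 2nd-PCR primer
## templates, and the adapter-read screening queries.

## 1st-PCR constant parts (5' tail + 3-base anchor for the 2nd PCR primers).
FORWARD_TAIL <- "CGCTCTTCCGATCT"
REVERSE_TAIL <- "TGCTCTTCCGATCT"
FORWARD_PCR2_ANCHOR <- "CTG"
REVERSE_PCR2_ANCHOR <- "GAC"

## 2nd-PCR common forward and indexed reverse primer templates; "xxxxxx"
## marks the six-base sample index.
PCR2_COMMON_FORWARD <-
    "AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCTCTG"
PCR2_INDEXED_REVERSE <-
    "CAAGCAGAAGACGGCATACGAGATxxxxxxGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTGAC"

## Sequencing-primer queries used to screen read-through of short inserts:
## the read-2 primer region searched in read 1, and the read-1 primer region
## searched in the trimmed read 2.
ADAPTER_QUERY_READ1 <- "GTCAGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
ADAPTER_QUERY_READ2 <- "CAGAGATCGGAAGAGCGTCGTGTAGGGAAAGA"

## Read geometry: 80-base read 1, 94-base read 2 (14-base SSR+anchor region
## retained), 6-base index read; 17 non-genomic tail bases per fragment end.
READ_LEN <- 80L
READ2_RAW_LEN <- 94L
INDEX_LEN <- 6L
TAIL_BASES_PER_END <- 17L
ANNEAL_LEN <- 14L

## The recommended set-1 annealing designs (motif, repeats, anchor). The
## forward and reverse primers share the annealing sequence and differ only
## in tail + 2nd-PCR anchor.
SET1_DESIGNS <- data.frame(
    core = c("ACT", "CTA", "TTG", "GTT", "GTT", "GTG", "GT", "TG"),
    repeats = c(4L, 4L, 4L, 4L, 4L, 4L, 6L, 6L),
    anchor = c("TG", "TG", "AC", "CC", "TC", "AC", "TC", "AC"),
    stringsAsFactors = FALSE
)

#' The published recommended multiplex primer set (set-1)
#'
#' Reconstructs the eight recommended annealing designs as tailed
#' forward/reverse primer pairs (16 oligos of 31 bases each).
#'
#' @return A [MigPrimerSet-class] named `"set-1"`.
#' @export
#' @examples
#' ps <- migPrimerSet1()
#' primerTable(ps)[, c("name", "full_seq")]
migPrimerSet1 <- function() {
    cands <- do.call(rbind, lapply(seq_len(nrow(SET1_DESIGNS)), function(i) {
        primerCandidate(SET1_DESIGNS$core[i], SET1_DESIGNS$repeats[i],
                        SET1_DESIGNS$anchor[i])
    }))
    tailed <- attachTails(cands)
    newMigPrimerSet("set-1", tailed)
}
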