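## ISSR primer-set design: enumerate 14-base annealing designs (12-base SSR
## core + 2-base anchor), reject unsuitable candidates by string rules,
## attach the constant 17-base tails, and assemble multiplex-compatible sets.

#' Admissible two-base anchor sequences
#'
#' The anchor fixes the primer's 3' end at the SSR boundary. Only anchors
#' ending in C or G anneal well, and the self-complementary CG/GC pair is
#' excluded, leaving six admissible anchors.
#'
#' @return Character vector `c("AC", "AG", "CC", "GG", "TC", "TG")`, in
#'   lexicographic order.
#' @export
#' @examples
#' enumerateAnchors()
enumerateAnchors <- function() {
    c("AC", "AG", "CC", "GG", "TC", "TG")
}

#' Enumerate candidate SSR core motifs
#'
#' Candidate repeat units for the 12-base primer core. Three classes are
#' admissible: (a) the 24 three-base motifs made of three different bases,
#' half assigned to the main set and their reverse complements to the
#' alternative set; (b) the two-base motifs AC/CA (main) and their reverse
#' complements TG/GT (alternative) — AG/GA (polypurine), TC/CT
#' (polypyrimidine), GC/CG (GC rich) and AT/TA (GC poor) repeats are
#' unsuitable; (c) the two-distinct-base three-base motifs AAC/CCA (main)
#' and TTG/GGT (alternative). Dimers are repeated six times and trimers
#' four times, so every core is 12 bases.
#'
#' @param set `"main"` or `"alternative"`; alternative-set motifs are the
#'   reverse complements of main-set motifs.
#' @return `data.frame` with columns `seq`, `repeats`, `class`
#'   (`"trimer3"`, `"dimer"`, `"trimer2"`) and `set`.
#' @export
#' @examples
#' subset(enumerateCoreMotifs("main"), class == "dimer")
enumerateCoreMotifs <- function(set = c("main", "alternative")) {
    set <- match.arg(set)
    perms <- expand.grid(a = DNA_BASES_CHR, b = DNA_BASES_CHR,
                         c = DNA_BASES_CHR, stringsAsFactors = FALSE)
    perms <- perms[perms$a != perms$b & perms$b != perms$c & perms$a != perms$c, ]
    tri3 <- sort(paste0(perms$a, perms$b, perms$c))
    stopifnot(length(tri3) == 24L)
    ## Main set: the lexicographically smaller member of each reverse-
    ## complement pair (no 3-mer of three distinct bases is palindromic).
    main3 <- tri3[tri3 < revComp(tri3)]
    motifs <- rbind(
        data.frame(seq = if (set == "main") main3 else revComp(main3),
                   repeats = 4L, class = "trimer3"),
        data.frame(seq = if (set == "main") c("AC", "CA") else c("GT", "TG"),
                   repeats = 6L, class = "dimer"),
        ## Reverse complements at the repeat level: (AAC)n / (CCA)n revcomp
        ## to the (TTG)n / (GGT)n rotations of the same SSR.
        data.frame(seq = if (set == "main") c("AAC", "CCA") else c("GGT", "TTG"),
                   repeats = 4L, class = "trimer2")
    )
    motifs$set <- set
    motifs <- motifs[order(motifs$class, motifs$seq), ]
    rownames(motifs) <- NULL
    motifs
}

#' Build a primer candidate from core motif, repeat count and anchor
#'
#' @param core 2- or 3-base repeat unit.
#' @param repeats Repeat count (6 for dimers, 4 for trimers; the core must
#'   span exactly 12 bases).
#' @param anchor 2-base anchor.
#' @return One-row `data.frame` with columns `core`, `repeats`, `anchor`,
#'   `annealing_seq` (14 nt).
#' @export
#' @examples
#' primerCandidate("ACT", 4, "TG")$annealing_seq
primerCandidate <- function(core, repeats, anchor) {
    assertACGT(core, "core motif"); assertACGT(anchor, "anchor")
    if (nchar(core) * repeats != 12L)
        stop("core motif must span exactly 12 bases (len x repeats)")
    if (nchar(anchor) != 2L)
        stop("anchor must be 2 bases")
    data.frame(core = core, repeats = as.integer(repeats), anchor = anchor,
               annealing_seq = paste0(strrep(core, repeats), anchor),
               stringsAsFactors = FALSE)
}

## The universe of pure 14-mer SSRs: 14-base prefixes of the infinite repeat
## of every 2- and 3-base motif (used by rejection rule ii).
pureRepeat14mers <- function() {
    motifs <- c(outer(DNA_BASES_CHR, DNA_BASES_CHR, paste0),
                outer(outer(DNA_BASES_CHR, DNA_BASES_CHR, paste0),
                      DNA_BASES_CHR, paste0))
    unique(substr(strrep(motifs, 7L), 1L, 14L))
}

#' Apply the candidate-rejection rules
#'
#' Tests each 14-base annealing design against five string rules and
#' records one failure. A design can violate several rules at once (a
#' GC-rich 3' end is often also one base away from a pure repeat), so
#' rules are evaluated from the most specific structural property to the
#' generic near-repeat rule — i, v, iii, iv, then ii — and the first hit
#' in that precedence is reported:
#' \describe{
#'   \item{i}{the design is nothing but a continuation of its own repeat
#'     (e.g. (AC)6+AC);}
#'   \item{ii}{the design differs from some pure 14-base SSR (any 2- or
#'     3-base motif) at exactly one position (e.g. (AC)6+AG);}
#'   \item{iii}{the three 3'-terminal bases are all G/C (e.g. (AC)6+CC);}
#'   \item{iv}{the design contains fewer than three different bases
#'     (e.g. (CA)6+CC);}
#'   \item{v}{the reverse complement of the 3'-terminal 4-mer occurs within
#'     the 14-base design, the terminal position included, which covers the
#'     palindromic case (ACC)4+GG.}
#' }
#'
#' @param candidates `data.frame` as from [primerCandidate()] (one or more
#'   rows).
#' @return The same `data.frame` with columns `rejection` (rule id
#'   `"i"`..`"v"` or `NA` for a pass) and `reason` appended.
#' @export
#' @examples
#' applyRejectionRules(primerCandidate("AC", 6, "AC"))$rejection   # "i"
#' applyRejectionRules(primerCandidate("ACT", 4, "TG"))$rejection  # NA
applyRejectionRules <- function(candidates) {
    stopifnot(all(nchar(candidates$annealing_seq) == 14L))
    pure <- pureRepeat14mers()
    res <- lapply(seq_len(nrow(candidates)), function(k) {
        seqk <- candidates$annealing_seq[k]
        core <- candidates$core[k]
        ownPure <- substr(strrep(core, 8L), 1L, 14L)
        if (seqk == ownPure)
            return(c("i", "annealing is a pure extension of the repeat"))
        rc4 <- revComp(substr(seqk, 11L, 14L))
        if (grepl(rc4, seqk, fixed = TRUE))
            return(c("v", paste0("revcomp of 3' 4-mer (", rc4,
                                 ") occurs in annealing sequence")))
        tail3 <- substr(seqk, 12L, 14L)
        if (grepl("^[GC]{3}$", tail3))
            return(c("iii", paste0("GC-rich 3' end ", tail3)))
        if (length(unique(strsplit(seqk, "")[[1L]])) < 3L)
            return(c("iv", "fewer than three different bases"))
        d <- hammingDist(seqk, pure)
        if (any(d == 1L))
            return(c("ii", paste0("one base from pure SSR ",
                                  pure[which(d == 1L)[1L]])))
        c(NA_character_, NA_character_)
    })
    candidates$rejection <- vapply(res, `[`, character(1), 1L)
    candidates$reason <- vapply(res, `[`, character(1), 2L)
    candidates
}

#' Enumerate and screen all primer candidates of a set
#'
#' Crosses every admissible core motif of the requested set with every
#' admissible anchor and applies [applyRejectionRules()].
#'
#' @inheritParams enumerateCoreMotifs
#' @param surviving If `TRUE` (default) return only candidates that pass
#'   all rules; otherwise all candidates with their `rejection` column.
#' @return `data.frame` of candidates, lexicographically ordered by
#'   annealing sequence.
#' @export
primerCandidates <- function(set = c("main", "alternative"),
                             surviving = TRUE) {
    motifs <- enumerateCoreMotifs(set)
    anchors <- enumerateAnchors()
    grid <- expand.grid(m = seq_len(nrow(motifs)), a = anchors,
                        stringsAsFactors = FALSE)
    cands <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
        primerCandidate(motifs$seq[grid$m[k]], motifs$repeats[grid$m[k]],
                        grid$a[k])
    }))
    cands <- applyRejectionRules(cands)
    cands <- cands[order(cands$annealing_seq), ]
    rownames(cands) <- NULL
    if (surviving) cands[is.na(cands$rejection), ] else cands
}

#' Attach constant tails to passing candidates
#'
#' Builds both direction variants of each design: 14-base 5' tail + 3-base
#' anchor for the 2nd-PCR primers + 14-base annealing sequence = 31 bases.
#' Forward and reverse primers share the annealing sequence and differ only
#' in tail (CGCTCTTCCGATCT vs TGCTCTTCCGATCT) and 2nd-PCR anchor (CTG vs
#' GAC). Names follow the `(ACT)_4TG-f` convention.
#'
#' @param candidates `data.frame` of passing candidates (columns `core`,
#'   `repeats`, `anchor`, `annealing_seq`).
#' @return `data.frame` with two rows per design and columns `name`,
#'   `direction`, `core`, `repeats`, `anchor`, `annealing_seq`, `full_seq`.
#' @export
#' @examples
#' attachTails(primerCandidate("ACT", 4, "TG"))$full_seq
attachTails <- function(candidates) {
    if ("rejection" %in% names(candidates) &&
        any(!is.na(candidates$rejection)))
        stop("cannot attach tails to rejected candidates")
    base <- paste0("(", candidates$core, ")_", candidates$repeats,
                   candidates$anchor)
    fwd <- data.frame(
        name = paste0(base, "-f"), direction = "forward",
        core = candidates$core, repeats = candidates$repeats,
        anchor = candidates$anchor, annealing_seq = candidates$annealing_seq,
        full_seq = paste0(FORWARD_TAIL, FORWARD_PCR2_ANCHOR,
                          candidates$annealing_seq),
        stringsAsFactors = FALSE)
    rev <- fwd
    rev$name <- paste0(base, "-r")
    rev$direction <- "reverse"
    rev$full_seq <- paste0(REVERSE_TAIL, REVERSE_PCR2_ANCHOR,
                           candidates$annealing_seq)
    out <- rbind(fwd, rev)
    out <- out[order(out$annealing_seq, out$direction), ]
    rownames(out) <- NULL
    out
}

#' Self/counterpart dimer check on tailed primers
#'
#' A tailed primer fails when the reverse complement of more than three 3'
#' bases (windows of 4 to 6 bases are scanned; a longer match implies the
#' shorter) occurs within its own full sequence or within its
#' opposite-direction counterpart.
#'
#' @param primer,counterpart One-row `data.frame`s as from [attachTails()]
#'   (the counterpart is the opposite-direction variant of the same
#'   design).
#' @return A list with `pass` (logical) and `conflict` (description or
#'   `NA`).
#' @export
checkTailedSelfDimer <- function(primer, counterpart) {
    stopifnot(primer$annealing_seq == counterpart$annealing_seq,
              primer$direction != counterpart$direction)
    for (w in 4L:6L) {
        term <- substr(primer$full_seq, 31L - w + 1L, 31L)
        rc <- revComp(term)
        for (target in c(own = primer$full_seq,
                         counterpart = counterpart$full_seq)) {
            if (grepl(rc, target, fixed = TRUE)) {
                return(list(pass = FALSE,
                            conflict = paste0("revcomp of 3' ", w, "-mer (",
                                              rc, ") found in ",
                                              if (target == primer$full_seq)
                                                  "own" else "counterpart",
                                              " sequence")))
            }
        }
    }
    list(pass = TRUE, conflict = NA_character_)
}

## Pairwise step-7 conflicts within a tailed-primer table: member A's
## 3'-terminal 3-mer reverse complement occurring inside member B.
crossDimerConflicts <- function(primers) {
    n <- nrow(primers)
    out <- emptyConflictLog()
    if (n < 2L) return(out)
    term3 <- substr(primers$full_seq, 29L, 31L)
    rc3 <- revComp(term3)
    for (i in seq_len(n)) {
        hit <- grepl(rc3[i], primers$full_seq, fixed = TRUE)
        hit[i] <- FALSE
        if (any(hit)) {
            out <- rbind(out, data.frame(
                primer_a = primers$name[i], primer_b = primers$name[hit],
                conflict_seq = rc3[i], stringsAsFactors = FALSE))
        }
    }
    rownames(out) <- NULL
    out
}

#' Validate a user-supplied multiplex set
#'
#' Applies the multiplex-compatibility rule to an existing set: no
#' member's 3'-terminal 3-mer may have a reverse-complement match inside
#' any other member's full sequence.
#'
#' @param primers A [MigPrimerSet-class] or a tailed-primer `data.frame`.
#' @param setName Label for the returned set.
#' @return A [MigPrimerSet-class] with `compatibilityOk` and `conflictLog`
#'   populated.
#' @export
#' @examples
#' isCompatible(validateMultiplexSet(migPrimerSet1()))
validateMultiplexSet <- function(primers, setName = "validated") {
    if (is(primers, "MigPrimerSet")) {
        setName <- primers@setName
        primers <- primerTable(primers)
    }
    newMigPrimerSet(setName, primers)
}

#' Assemble a multiplex-compatible primer set
#'
#' Deterministic greedy selection over lexicographically ordered designs:
#' each design (forward + reverse tailed primer) is added when neither
#' direction creates a step-7 conflict (3'-terminal 3-mer reverse
#' complement inside another member, or vice versa) with the current
#' selection. Because several conflict-free choices typically exist, an
#' optional number of seeded random restarts explores permutations and
#' keeps the largest set found.
#'
#' @param tailed `data.frame` of tailed primers ([attachTails()] output);
#'   both directions of each design must be present.
#' @param targetSize Number of designs wanted.
#' @param nRestarts Random restarts over shuffled design orders (0 =
#'   purely lexicographic greedy). Uses the current RNG stream.
#' @param setName Label for the returned set.
#' @return A [MigPrimerSet-class] with `targetSize` designs. When the
#'   target is infeasible the maximal conflict-free set found is returned
#'   with a warning describing the shortfall.
#' @export
selectMultiplexSet <- function(tailed, targetSize, nRestarts = 0L,
                               setName = "custom") {
    stopifnot(targetSize >= 1L)
    designs <- sort(unique(tailed$annealing_seq))
    if (length(designs) < 1L) stop("no candidate designs supplied")
    greedy <- function(order_idx) {
        sel <- character(0)
        rows <- NULL
        for (d in designs[order_idx]) {
            cand <- tailed[tailed$annealing_seq == d, , drop = FALSE]
            trial <- rbind(rows, cand)
            if (nrow(crossDimerConflicts(trial)) == 0L) {
                rows <- trial
                sel <- c(sel, d)
                if (length(sel) == targetSize) break
            }
        }
        rows
    }
    best <- greedy(seq_along(designs))
    if (nRestarts > 0L) {
        for (r in seq_len(nRestarts)) {
            if (!is.null(best) && nrow(best) / 2L >= targetSize) break
            trial <- greedy(sample(length(designs)))
            if (is.null(best) || nrow(trial) > nrow(best)) best <- trial
        }
    }
    got <- nrow(best) / 2L
    if (got < targetSize)
        warning("target size ", targetSize, " infeasible; returning maximal ",
                "conflict-free set of ", got, " designs")
    newMigPrimerSet(setName, best)
}
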