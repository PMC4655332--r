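## The combinatorial primer-design rules: anchors, core motifs, rejection
## rules, tails and multiplex compatibility.

table1_designs <- data.frame(
    core = c("ACT", "CTA", "TTG", "GTT", "GTT", "GTG", "GT", "TG"),
    repeats = c(4L, 4L, 4L, 4L, 4L, 4L, 6L, 6L),
    anchor = c("TG", "TG", "AC", "CC", "TC", "AC", "TC", "AC"),
    stringsAsFactors = FALSE)

test_that("admissible anchors are the six published ones", {
    a <- enumerateAnchors()
    expect_identical(a, c("AC", "AG", "CC", "GG", "TC", "TG"))
    expect_false("CG" %in% a)
    expect_false("AT" %in% a)
    expect_true(all(substr(a, 2L, 2L) %in% c("C", "G")))
})

test_that("core-motif enumeration has the published structure", {
    main <- enumerateCoreMotifs("main")
    alt <- enumerateCoreMotifs("alternative")
    ## 24 three-distinct-base trimers split evenly across the two sets
    expect_equal(sum(main$class == "trimer3"), 12L)
    expect_equal(sum(alt$class == "trimer3"), 12L)
    grid <- expand.grid(b1 = c("A","C","G","T"), b2 = c("A","C","G","T"),
                        b3 = c("A","C","G","T"), stringsAsFactors = FALSE)
    grid <- grid[grid$b1 != grid$b2 & grid$b2 != grid$b3 &
                 grid$b1 != grid$b3, ]
    all24 <- paste0(grid$b1, grid$b2, grid$b3)
    expect_equal(length(all24), 24L)
    expect_setequal(c(main$seq[main$class == "trimer3"],
                      alt$seq[alt$class == "trimer3"]), all24)
    ## alternative trimers are exact reverse complements of main trimers
    expect_setequal(alt$seq[alt$class == "trimer3"],
                    revComp(main$seq[main$class == "trimer3"]))
    expect_setequal(main$seq[main$class == "dimer"], c("AC", "CA"))
    expect_setequal(alt$seq[alt$class == "dimer"], c("TG", "GT"))
    expect_setequal(main$seq[main$class == "trimer2"], c("AAC", "CCA"))
    expect_setequal(alt$seq[alt$class == "trimer2"], c("TTG", "GGT"))
    ## excluded dimers never appear
    expect_false(any(c("AG", "GA", "TC", "CT", "GC", "CG", "AT", "TA") %in%
                     c(main$seq[main$class == "dimer"],
                       alt$seq[alt$class == "dimer"])))
    ## dimer and trimer repeats: every core spans 12 bases
    expect_true(all(nchar(main$seq) * main$repeats == 12L))
    ## repeat-level reverse complementarity holds for all classes: the
    ## 12-base repeated cores of the alternative set are the reverse
    ## complements of the main set's, up to rotation of the repeat unit
    rep12 <- function(df) strtrim(strrep(df$seq, 6L), 12L)
    main12 <- rep12(main); alt12 <- rep12(alt)
    expect_true(all(vapply(revComp(main12), function(rc) {
        any(vapply(alt12, function(a)
            grepl(a, strrep(rc, 2L), fixed = TRUE), logical(1)))
    }, logical(1))))
    expect_error(enumerateCoreMotifs("other"))
})

test_that("rejection rules reproduce the printed examples", {
    cases <- list(
        list("AC", 6L, "AC", "i"),
        list("AC", 6L, "AG", "ii"),
        list("AC", 6L, "CC", "iii"),
        list("CA", 6L, "CC", "iv"),
        list("ACC", 4L, "GG", "v"))
    for (cs in cases) {
        res <- applyRejectionRules(primerCandidate(cs[[1]], cs[[2]], cs[[3]]))
        expect_identical(res$rejection, cs[[4]],
                         label = paste0("(", cs[[1]], ")", cs[[2]], cs[[3]]))
    }
})

test_that("all eight published set-1 annealing designs pass the rules", {
    cands <- do.call(rbind, lapply(seq_len(nrow(table1_designs)), function(i)
        primerCandidate(table1_designs$core[i], table1_designs$repeats[i],
                        table1_designs$anchor[i])))
    res <- applyRejectionRules(cands)
    expect_true(all(is.na(res$rejection)))
    expect_true(all(nchar(res$annealing_seq) == 14L))
})

test_that("tail attachment reproduces the published oligos", {
    tp <- attachTails(primerCandidate("ACT", 4L, "TG"))
    fwd <- tp[tp$direction == "forward", ]
    rev <- tp[tp$direction == "reverse", ]
    expect_identical(fwd$full_seq, "CGCTCTTCCGATCTCTGACTACTACTACTTG")
    expect_identical(rev$full_seq, "TGCTCTTCCGATCTGACACTACTACTACTTG")
    expect_identical(fwd$name, "(ACT)_4TG-f")
    expect_identical(rev$name, "(ACT)_4TG-r")
    ## forward/reverse differ only in tail + 2nd-PCR anchor
    expect_identical(substr(fwd$full_seq, 18L, 31L),
                     substr(rev$full_seq, 18L, 31L))
    all16 <- primerTable(migPrimerSet1())
    expect_true(all(nchar(all16$full_seq) == 31L))
    expect_equal(nrow(all16), 16L)
})

test_that("self/counterpart dimer screen passes set-1 and catches CCGG", {
    p <- primerTable(migPrimerSet1())
    for (nm in unique(sub("-[fr]$", "", p$name))) {
        f <- p[p$name == paste0(nm, "-f"), ]
        r <- p[p$name == paste0(nm, "-r"), ]
        expect_true(checkTailedSelfDimer(f, r)$pass, label = nm)
        expect_true(checkTailedSelfDimer(r, f)$pass, label = nm)
    }
    ## a 3' CCGG is its own reverse complement: must fail against itself
    bad <- data.frame(name = "bad-f", direction = "forward", core = "X",
                      repeats = 4L, anchor = "GG",
                      annealing_seq = "AATTAATTAACCGG",
                      full_seq = paste0("CGCTCTTCCGATCTCTG",
                                        "AATTAATTAACCGG"))
    cp <- bad; cp$direction <- "reverse"
    cp$full_seq <- paste0("TGCTCTTCCGATCTGAC", "AATTAATTAACCGG")
    res <- checkTailedSelfDimer(bad, cp)
    expect_false(res$pass)
    expect_match(res$conflict, "CCGG")
})

test_that("the published set-1 validates conflict-free as a multiplex set", {
    ps <- validateMultiplexSet(migPrimerSet1())
    expect_true(isCompatible(ps))
    expect_equal(nrow(conflictLog(ps)), 0L)
})

test_that("greedy multiplex selection is deterministic and self-consistent", {
    tailed <- attachTails(primerCandidates("main"))
    ps1 <- selectMultiplexSet(tailed, 8L)
    ps2 <- selectMultiplexSet(tailed, 8L)
    expect_identical(primerTable(ps1), primerTable(ps2))
    expect_equal(length(ps1), 16L)
    ## end-to-end: enumerate -> reject -> tail -> select validates clean
    expect_true(isCompatible(validateMultiplexSet(ps1)))
    ## size-1 always feasible
    expect_equal(length(selectMultiplexSet(tailed, 1L)), 2L)
    ## conflicting primers are never co-selected
    sel <- primerTable(ps1)
    expect_equal(nrow(conflictLog(validateMultiplexSet(ps1))), 0L)
})

test_that("infeasible target size warns and returns the maximal set", {
    tailed <- attachTails(primerCandidates("main"))
    few <- tailed[tailed$annealing_seq %in%
                  unique(tailed$annealing_seq)[1:2], ]
    expect_warning(ps <- selectMultiplexSet(few, 10L), "infeasible")
    expect_lte(length(ps) / 2L, 2L)
})

test_that("candidate enumeration rejects ambiguity codes", {
    expect_error(primerCandidate("ANT", 4L, "TG"), "non-ACGT")
    expect_error(primerCandidate("ACT", 4L, "NG"), "non-ACGT")
})

test_that("the bundled set-1 constants file matches the in-code set", {
    tsv <- system.file("extdata", "migseq_primer_set1.tsv",
                       package = "migseqr")
    expect_true(nzchar(tsv))
    bundled <- readPrimerTSV(tsv)
    expect_identical(primerTable(bundled)$full_seq,
                     primerTable(migPrimerSet1())$full_seq)
    pcr2 <- read.table(system.file("extdata", "migseq_pcr2_primers.tsv",
                                   package = "migseqr"),
                       sep = "\t", header = TRUE)
    expect_equal(nrow(pcr2), 2L)
    expect_match(pcr2$sequence[2L], "xxxxxx")  # six-base index placeholder
})
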