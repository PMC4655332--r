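## Annealing-site scanning, amplicon pairing, end-read extraction, export.

test_that("planted exact annealing matches are found on both strands", {
    anneal <- "ACTACTACTACTTG"  # (ACT)_4TG
    ps <- migPrimerSet1()
    g_plus <- paste0(strrep("A", 100), anneal, strrep("G", 50))
    s <- findAnnealingSites(g_plus, ps)
    expect_equal(length(s), 1L)
    expect_equal(GenomicRanges::start(s), 101L)
    expect_equal(GenomicRanges::end(s), 114L)
    expect_equal(as.character(GenomicRanges::strand(s)), "+")
    expect_equal(S4Vectors::mcols(s)$primer_name, "(ACT)_4TG")

    g_minus <- paste0(strrep("A", 100), revComp(anneal), strrep("G", 50))
    s2 <- findAnnealingSites(g_minus, ps)
    expect_equal(length(s2), 1L)
    expect_equal(as.character(GenomicRanges::strand(s2)), "-")
})

test_that("site and amplicon lists match the naive oracle on seeded genomes", {
    ps <- migPrimerSet1()
    designs <- unique(data.frame(
        name = sub("-f$", "", primerTable(ps)$name[
            primerTable(ps)$direction == "forward"]),
        annealing_seq = primerTable(ps)$annealing_seq[
            primerTable(ps)$direction == "forward"]))
    for (seed in 1:5) {
        set.seed(seed)
        ## random background plus planted footprints to guarantee signal
        an <- designs$annealing_seq
        g <- paste0(
            paste(sample(c("A","C","G","T"), 4000, TRUE), collapse = ""),
            an[1L], paste(sample(c("A","C","G","T"), 300, TRUE),
                          collapse = ""),
            revComp(an[2L]),
            paste(sample(c("A","C","G","T"), 3000, TRUE), collapse = ""))
        for (mm5 in c(0L, 1L)) {
            got <- findAnnealingSites(g, ps, maxMismatch5 = mm5)
            want <- naiveSites(g, designs, mm5 = mm5)
            expect_equal(length(got), nrow(want), label = paste(seed, mm5))
            if (length(got)) {
                gdf <- data.frame(start = GenomicRanges::start(got),
                                  end = GenomicRanges::end(got),
                                  strand = as.character(
                                      GenomicRanges::strand(got)),
                                  primer_name =
                                      S4Vectors::mcols(got)$primer_name,
                                  mismatches =
                                      S4Vectors::mcols(got)$mismatches)
                gdf <- gdf[order(gdf$start, gdf$strand, gdf$primer_name), ]
                rownames(gdf) <- rownames(want) <- NULL
                expect_equal(gdf, want, label = paste(seed, mm5))
            }
            amp <- predictAmplicons(got)
            w_amp <- naiveAmplicons(want)
            expect_equal(length(amp), nrow(w_amp), label = paste(seed, mm5))
            if (length(amp)) {
                adf <- data.frame(start = GenomicRanges::start(amp),
                                  end = GenomicRanges::end(amp),
                                  fwd_primer = S4Vectors::mcols(amp)$fwd_primer,
                                  rev_primer = S4Vectors::mcols(amp)$rev_primer,
                                  library_len =
                                      S4Vectors::mcols(amp)$library_len)
                adf <- adf[order(adf$start, adf$end, adf$fwd_primer,
                                 adf$rev_primer), ]
                rownames(adf) <- rownames(w_amp) <- NULL
                expect_equal(adf, w_amp[, names(adf)],
                             label = paste(seed, mm5))
            }
        }
    }
})

test_that("amplicon arithmetic and gates behave as specified", {
    ## one + footprint at 101-114 and one - footprint at 481-494:
    ## genomic span 394, library length 428, inside 300-800
    anneal_f <- "ACTACTACTACTTG"
    anneal_r <- "TGTGTGTGTGTGAC"  # (TG)_6AC
    insert <- paste(rep("A", 494 - 114 - 14), collapse = "")
    g <- paste0(strrep("C", 100), anneal_f, insert, revComp(anneal_r),
                strrep("C", 50))
    sites <- findAnnealingSites(g, migPrimerSet1())
    expect_equal(length(sites), 2L)
    amp <- predictAmplicons(sites)
    expect_equal(length(amp), 1L)
    expect_equal(S4Vectors::mcols(amp)$genomic_len, 394L)
    expect_equal(S4Vectors::mcols(amp)$library_len, 428L)
    expect_equal(S4Vectors::mcols(amp)$sequenceable_fraction, 0.5)
    ## two same-strand sites cannot pair
    g2 <- paste0(strrep("C", 100), anneal_f, strrep("A", 300), anneal_r,
                 strrep("C", 50))
    expect_equal(length(predictAmplicons(findAnnealingSites(
        g2, migPrimerSet1()))), 0L)
    ## an oversized span is excluded by size selection
    g3 <- paste0(strrep("C", 100), anneal_f, strrep("A", 2000),
                 revComp(anneal_r), strrep("C", 50))
    expect_equal(length(predictAmplicons(findAnnealingSites(
        g3, migPrimerSet1()))), 0L)
})

test_that("widening gates and mismatch budgets never removes results", {
    cfg <- simConfig(seed = 31L, nLoci = 8L)
    sim <- simulateGenome(cfg)
    sites0 <- findAnnealingSites(sim$genome, sim$primers, maxMismatch5 = 0L)
    sites1 <- findAnnealingSites(sim$genome, sim$primers, maxMismatch5 = 2L)
    expect_gte(length(sites1), length(sites0))
    a_narrow <- predictAmplicons(sites0, 350L, 700L)
    a_wide <- predictAmplicons(sites0, 300L, 800L)
    expect_gte(length(a_wide), length(a_narrow))
    key <- function(a) paste(GenomicRanges::start(a), GenomicRanges::end(a),
                             S4Vectors::mcols(a)$fwd_primer,
                             S4Vectors::mcols(a)$rev_primer)
    expect_true(all(key(a_narrow) %in% key(a_wide)))
})

test_that("reverse-complementing the genome mirrors sites, keeps amplicons", {
    cfg <- simConfig(seed = 32L, nLoci = 6L)
    sim <- simulateGenome(cfg)
    g <- as.character(sim$genome[[1L]])
    sites_f <- findAnnealingSites(g, sim$primers)
    sites_r <- findAnnealingSites(revComp(g), sim$primers)
    expect_equal(length(sites_f), length(sites_r))
    L <- nchar(g)
    mirrored_start <- sort(L - GenomicRanges::end(sites_f) + 1L)
    expect_equal(sort(GenomicRanges::start(sites_r)), mirrored_start)
    expect_equal(table(as.character(GenomicRanges::strand(sites_f)))[["+"]],
                 table(as.character(GenomicRanges::strand(sites_r)))[["-"]])
    expect_equal(length(predictAmplicons(sites_f)),
                 length(predictAmplicons(sites_r)))
})

test_that("end reads are 80 bases, read 2 on the bottom strand", {
    cfg <- simConfig(seed = 33L, nLoci = 4L)
    sim <- simulateGenome(cfg)
    amps <- predictAmplicons(findAnnealingSites(sim$genome, sim$primers))
    tmpl <- extractLocusReads(amps, sim$genome)
    expect_true(all(nchar(tmpl$read1_seq) == 80L))
    expect_true(all(nchar(tmpl$read2_seq) == 80L))
    expect_false(any(tmpl$overlap_risk))
    g <- as.character(sim$genome[[1L]])
    for (i in seq_len(nrow(tmpl))) {
        expect_identical(tmpl$read1_seq[i],
                         substr(g, tmpl$insert_start[i],
                                tmpl$insert_start[i] + 79L))
        expect_identical(tmpl$read2_seq[i],
                         revComp(substr(g, tmpl$insert_end[i] - 79L,
                                        tmpl$insert_end[i])))
    }
    ## planted windows from the simulator agree with extraction
    mc <- as.data.frame(S4Vectors::mcols(sim$loci))
    expect_setequal(tmpl$read1_seq, mc$end1_seq)
    expect_setequal(tmpl$read2_seq, mc$end2_seq)
})

test_that("BED/FASTA export round-trips and uses half-open BED", {
    cfg <- simConfig(seed = 34L, nLoci = 3L)
    sim <- simulateGenome(cfg)
    amps <- predictAmplicons(findAnnealingSites(sim$genome, sim$primers))
    tmpl <- extractLocusReads(amps, sim$genome)
    bed_path <- tempfile(fileext = ".bed")
    fa_path <- tempfile(fileext = ".fa")
    bed <- exportLoci(tmpl, bed_path, fa_path)
    expect_equal(nrow(bed), 3L)
    expect_true(all(bed$chromStart < bed$chromEnd))
    expect_equal(bed$chromStart, tmpl$insert_start - 1L)
    fa <- Biostrings::readDNAStringSet(fa_path)
    expect_equal(length(fa), 6L)
    expect_identical(unname(as.character(
        fa[paste0(tmpl$locus_id, "|read1")])), tmpl$read1_seq)
    expect_identical(unname(as.character(
        fa[paste0(tmpl$locus_id, "|read2")])), tmpl$read2_seq)
})

test_that("degenerate inputs: empty genome and non-ACGT characters", {
    expect_equal(length(findAnnealingSites("ACGT", migPrimerSet1())), 0L)
    expect_warning(
        s <- findAnnealingSites(paste0(strrep("N", 50),
                                       "ACTACTACTACTTG"), migPrimerSet1()),
        "non-ACGT")
    expect_equal(length(s), 1L)
})
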