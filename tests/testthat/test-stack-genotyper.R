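## Stack building, depth-ratio genotype calls, catalog clustering, marker
## selection, and parameter recovery on clean simulations.

test_that("stack formation honours the minimum depth m", {
    s <- randSeq80(1L)
    expect_length(buildStacks(rep(s, 100L)), 1L)
    expect_equal(buildStacks(rep(s, 100L))[[1L]]$depth, 100L)
    expect_length(buildStacks(rep(s, 19L)), 0L)  # below m = 20
    expect_length(buildStacks(rep(s, 20L)), 1L)
    expect_error(buildStacks("ACGT"), "80 bases")
})

test_that("stacks within M merge into one sample locus with a depth table", {
    set.seed(61)
    a <- randSeq80(1L)
    b <- a; substr(b, 10L, 10L) <- if (substr(a, 10, 10) == "A") "C" else "A"
    loci <- buildStacks(c(rep(a, 60L), rep(b, 50L)))
    expect_length(loci, 1L)
    expect_equal(loci[[1L]]$n_stacks, 2L)
    expect_setequal(loci[[1L]]$seqs, c(a, b))
    expect_equal(sort(loci[[1L]]$depths), c(50L, 60L))
    expect_identical(loci[[1L]]$consensus, a)  # deepest seed
    ## beyond M: two separate loci
    c3 <- a
    for (p in c(5L, 25L, 45L))
        substr(c3, p, p) <- if (substr(a, p, p) == "G") "T" else "G"
    expect_length(buildStacks(c(rep(a, 60L), rep(c3, 50L))), 2L)
    ## secondary reads below m attach to the nearest locus
    sec <- a; substr(sec, 40L, 40L) <- if (substr(a, 40, 40) == "T") "G" else "T"
    loci2 <- buildStacks(c(rep(a, 30L), rep(sec, 3L)))
    expect_length(loci2, 1L)
    expect_equal(loci2[[1L]]$depth, 33L)
})

test_that("sample loci built from too many stacks are discarded", {
    set.seed(62)
    a <- randSeq80(1L)
    variants <- vapply(1:4, function(k) {
        x <- a; substr(x, k, k) <- if (substr(a, k, k) == "A") "C" else "A"; x
    }, character(1))
    reads <- c(rep(a, 50L), unlist(lapply(variants, rep, times = 25L)))
    expect_length(buildStacks(reads), 0L)   # 5 stacks > cap of 3
})

test_that("the depth-ratio rule calls genotypes as printed", {
    expect_identical(callGenotype(c(A = 100, T = 4))$geno, "A/A")   # 4% < 1/20
    g2 <- callGenotype(c(A = 100, T = 10))                          # 10% >= 1/20
    expect_identical(g2$geno, "A/T")
    expect_equal(g2$depthMajor, 100)
    expect_equal(g2$depthMinor, 10)
    expect_identical(callGenotype(c(A = 57))$geno, "A/A")
    ## exact boundary: 5/100 = 1/20 counts as heterozygous
    expect_identical(callGenotype(c(A = 100, T = 5))$geno, "A/T")
    ## haploid mode: major allele plus the heterozygote flag
    h <- callGenotype(c(A = 100, T = 40), ploidy = 1L)
    expect_identical(h$geno, "A")
    expect_true(h$hetFlag)
    expect_false(callGenotype(c(A = 100, T = 2), ploidy = 1L)$hetFlag)
    expect_true(is.na(callGenotype(numeric(0))$geno))
})

test_that("catalog clustering merges within n and separates beyond", {
    set.seed(63)
    a <- randSeq80(1L)
    sl <- lapply(setNames(nm = sprintf("s%02d", 1:10)), function(s)
        buildStacks(rep(a, 30L)))
    ct <- buildCatalog(sl)
    expect_equal(nrow(ct$catalog), 1L)
    expect_equal(nrow(ct$members), 10L)
    ## two loci 10 mismatches apart stay separate at n = 4
    b <- a
    for (p in seq(3L, 75L, by = 8L))
        substr(b, p, p) <- if (substr(a, p, p) == "C") "G" else "C"
    sl2 <- list(s1 = buildStacks(rep(a, 30L)), s2 = buildStacks(rep(b, 30L)))
    expect_equal(nrow(buildCatalog(sl2)$catalog), 2L)
    ## three mismatches merge at n = 4 (cross-checked against an
    ## independent pairwise distance)
    c3 <- a
    for (p in c(7L, 33L, 61L))
        substr(c3, p, p) <- if (substr(a, p, p) == "T") "A" else "T"
    expect_equal(sum(strsplit(a, "")[[1L]] != strsplit(c3, "")[[1L]]), 3L)
    sl3 <- list(s1 = buildStacks(rep(a, 30L)), s2 = buildStacks(rep(c3, 30L)))
    ct3 <- buildCatalog(sl3)
    expect_equal(nrow(ct3$catalog), 1L)
    expect_equal(nrow(ct3$members), 2L)
})

test_that("marker selection applies the r/p and single-SNP rules", {
    ## locus A: genotyped in 4/8 samples of one population (r = 0.5 keeps);
    ## locus B: genotyped in 3/8 of each of two populations (p = 2 drops)
    g <- rbind(c(rep("A/A", 4L), rep(NA, 4L), rep("A/T", 4L), rep(NA, 4L)),
               c(rep("C/C", 3L), rep(NA, 5L), rep("C/G", 3L), rep(NA, 5L)))
    mg <- makeGeno(g, population = rep(c("pop1", "pop2"), each = 8L),
                   ploidy = rep(2L, 16L))
    kept1 <- populationFilter(mg, genotyperConfig(r = 0.5, p = 1L))
    expect_identical(locusInfo(kept1)$locus_id, "L001")
    ## locus B (3/8 per population) fails r = 0.5 everywhere; locus A
    ## (4/8 in both) survives even at p = 2
    kept2 <- populationFilter(mg, genotyperConfig(r = 0.5, p = 2L))
    expect_identical(locusInfo(kept2)$locus_id, "L001")
    ## single-SNP: three sites of one locus reduce to the leftmost
    g3 <- matrix("A/A", 3L, 4L)
    g3[2L, 1L] <- "A/C"; g3[1L, 2L] <- "A/T"; g3[3L, 3L] <- "A/G"
    li <- data.frame(locus_id = rep("cat1", 3L), snp_pos = c(30L, 10L, 50L),
                     alleles = c("A/T", "A/C", "A/G"),
                     consensus = randSeq80(1L))
    mg3 <- MigGenotypes(g3, locusInfo = li,
                        sampleInfo = data.frame(
                            sample_id = sprintf("s%d", 1:4),
                            population = "pop1", ploidy = 2L))
    one <- populationFilter(mg3, genotyperConfig(singleSnp = TRUE))
    expect_equal(nrow(genoMatrix(one)), 1L)
    expect_equal(locusInfo(one)$snp_pos, 10L)
})

test_that("error-free simulated reads genotype to truth exactly", {
    cfg <- simConfig(seed = 64L, nLoci = 25L, depthMean = 60,
                     seqErrorRate = 0, pcrErrorRate = 0)
    sim <- simulateGenome(cfg)
    truth <- simulateCohort(sim, cohortSpec("megagametophyte_panel",
                                            nSamples = 8L, nHetLoci = 15L))
    rs <- simulateReads(sim, truth)
    pp <- preprocessRun(rs)
    mg <- genotypeSamples(pp$pools,
                          truth$samples[, c("sample_id", "population",
                                            "ploidy")])
    conc <- genotypeConcordance(mg, truth)
    expect_equal(conc$byLocus, 1)
    expect_equal(conc$byCell, 1)
    expect_gt(conc$nRows, 10L)
})

test_that("raising m or r never increases retained loci", {
    cfg <- simConfig(seed = 65L, nLoci = 15L, depthMean = 40)
    sim <- simulateGenome(cfg)
    truth <- simulateCohort(sim, cohortSpec("megagametophyte_panel",
                                            nSamples = 6L, nHetLoci = 10L))
    rs <- simulateReads(sim, truth)
    pp <- preprocessRun(rs)
    samples <- truth$samples[, c("sample_id", "population", "ploidy")]
    n_at <- function(m, r) {
        cfgG <- genotyperConfig(m = m, r = r)
        mgx <- populationFilter(genotypeSamples(pp$pools, samples, cfgG),
                                cfgG)
        length(unique(locusInfo(mgx)$locus_id))
    }
    expect_gte(n_at(5L, 0.5), n_at(20L, 0.5))
    expect_gte(n_at(20L, 0.5), n_at(20L, 0.75))
    expect_gte(n_at(20L, 0.75), n_at(35L, 0.75))
})

test_that("singleton error reads never change a genotype at depth >= m", {
    set.seed(66)
    a <- randSeq80(1L)
    err <- a; substr(err, 50L, 50L) <- if (substr(a, 50, 50) == "A") "G" else "A"
    loci <- buildStacks(c(rep(a, 80L), err))
    expect_length(loci, 1L)
    d <- setNames(loci[[1L]]$depths, loci[[1L]]$seqs)
    base_at <- substr(names(d), 50L, 50L)
    site <- vapply(split(d, base_at), sum, numeric(1))
    expect_identical(callGenotype(site)$geno,
                     paste(substr(a, 50, 50), substr(a, 50, 50), sep = "/"))
})

test_that("genotype exports round-trip (TSV) and produce valid VCF", {
    g <- rbind(c("A/A", "A/T", NA), c("C", "G", "C"))
    mg <- makeGeno(g, ploidy = c(2L, 2L, 1L))
    tsv <- tempfile(fileext = ".tsv")
    writeGenotypeTSV(mg, tsv)
    back <- readGenotypeTSV(tsv)
    expect_identical(unname(genoMatrix(back)), unname(genoMatrix(mg)))
    vcf <- tempfile(fileext = ".vcf")
    writeGenotypeVCF(mg, vcf)
    lines <- readLines(vcf)
    expect_match(lines[1L], "VCFv4.2", fixed = TRUE)
    body <- lines[!startsWith(lines, "#")]
    expect_length(body, 2L)
    expect_match(body[1L], "\t0/0\t0/1\t\\.$")
})
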