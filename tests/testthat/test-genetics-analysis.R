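## Segregation chi-square, clone identification, population differentiation.

## Build a haploid panel matrix with a heterozygous mother replicate pair
## and prescribed haploid allele counts per locus.
segFixture <- function(counts) {   # list of c(a, b) per locus
    nH <- sum(counts[[1L]])
    hap <- sprintf("h%02d", seq_len(nH))
    g <- do.call(rbind, lapply(counts, function(ab)
        c("A/T", "A/T", rep(c("A", "T"), times = ab))))
    colnames(g) <- c("mother_rep1", "mother_rep2", hap)
    rownames(g) <- sprintf("L%03d", seq_along(counts))
    makeGeno(g, ploidy = c(2L, 2L, rep(1L, nH)))
}

test_that("segregation chi-square matches hand-computed values", {
    mg <- segFixture(list(c(8L, 8L), c(10L, 6L), c(15L, 1L)))
    res <- segregationTest(mg, c("mother_rep1", "mother_rep2"),
                           sprintf("h%02d", 1:16))
    expect_equal(nrow(res), 3L)
    expect_equal(res$chi_square, c(0, 1, 12.25))
    expect_equal(res$p_value[1L], 1)
    expect_equal(res$p_value[2L], 0.3173105, tolerance = 1e-6)
    expect_lt(res$p_value[3L], 0.001)
    expect_identical(res$deviant, c(FALSE, FALSE, TRUE))
    expect_equal(res$informative_n, rep(16L, 3L))
})

test_that("segregation testing enforces its qualifying conditions", {
    ## discordant mother replicates disqualify a locus
    mg <- segFixture(list(c(8L, 8L)))
    g <- genoMatrix(mg); g[1L, "mother_rep2"] <- "A/A"
    mg2 <- makeGeno(g, ploidy = c(2L, 2L, rep(1L, 16L)))
    expect_warning(res <- segregationTest(
        mg2, c("mother_rep1", "mother_rep2"), sprintf("h%02d", 1:16)),
        "no loci qualify")
    expect_equal(nrow(res), 0L)
    ## fewer informative haploids than the minimum
    mg3 <- segFixture(list(c(4L, 4L)))
    expect_warning(segregationTest(mg3, "mother_rep1",
                                   sprintf("h%02d", 1:8)), "no loci")
    ## haploid heterozygote flags disqualify (duplicated loci)
    hf <- hetFlags(mg); hf[1L, "h01"] <- TRUE
    mg4 <- makeGeno(genoMatrix(mg), ploidy = c(2L, 2L, rep(1L, 16L)),
                    hetFlag = hf)
    expect_warning(segregationTest(mg4, "mother_rep1",
                                   sprintf("h%02d", 1:16)), "no loci")
    ## Yates correction shrinks the statistic
    res5 <- segregationTest(segFixture(list(c(10L, 6L))), "mother_rep1",
                            sprintf("h%02d", 1:16), yates = TRUE)
    expect_equal(res5$chi_square, 9 / 16)
})

test_that("a simulated 1:1 panel rejects at the exact discrete null rate", {
    cfg <- simConfig(seed = 81L, nLoci = 300L)
    sim <- simulateGenome(cfg)
    truth <- simulateCohort(sim, cohortSpec("megagametophyte_panel",
                                            nSamples = 16L,
                                            nHetLoci = 300L))
    mg <- genotypesFromTruth(truth)
    res <- segregationTest(mg, c("mother_rep1", "mother_rep2"),
                           truth$samples$sample_id[truth$samples$ploidy == 1L])
    expect_gt(nrow(res), 250L)
    ## independent oracle: the discrete null rate of the uncorrected
    ## chi-square at n = 16 is P(|a - 8| >= 4) under Binomial(16, 1/2)
    a <- 0:16
    null_rate <- sum(dbinom(a[pchisq((2 * a - 16)^2 / 16, 1,
                                     lower.tail = FALSE) < 0.05],
                            16, 0.5))
    expect_equal(null_rate, 0.0768, tolerance = 1e-3)
    expect_lt(abs(mean(res$deviant) - null_rate),
              3 * sqrt(null_rate * (1 - null_rate) / nrow(res)))
    ## the continuity-corrected variant is conservative
    resY <- segregationTest(mg, c("mother_rep1", "mother_rep2"),
                            truth$samples$sample_id[truth$samples$ploidy ==
                                                    1L], yates = TRUE)
    expect_lte(mean(resY$deviant), 0.05)
})

test_that("pairwise differences match a naive double loop", {
    set.seed(82)
    g <- matrix(sample(c("A/A", "A/T", "T/T", NA), 30L * 6L, TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), 30L, 6L)
    mg <- makeGeno(g, ploidy = rep(2L, 6L))
    ca <- pairwiseDifferenceMatrix(mg)
    for (a in 1:6) for (b in 1:6) {
        ok <- !is.na(g[, a]) & !is.na(g[, b])
        expect_equal(ca$diff[a, b], sum(g[ok, a] != g[ok, b]))
        expect_equal(ca$shared[a, b],
                     if (a == b) sum(!is.na(g[, a])) else sum(ok))
    }
    expect_true(isSymmetric(ca$diff))
    expect_equal(diag(ca$diff), setNames(rep(0L, 6L), colnames(ca$diff)))
    ## identical vectors differ by zero; three planted differences count 3
    g2 <- cbind(s1 = g[, 1L], s2 = g[, 1L])
    g2[1:3, 2L] <- ifelse(is.na(g2[1:3, 1L]) | g2[1:3, 1L] == "A/A",
                          "T/T", "A/A")
    ca2 <- pairwiseDifferenceMatrix(makeGeno(g2, ploidy = c(2L, 2L)))
    expect_equal(ca2$diff["s1", "s2"], sum(!is.na(g2[1:3, 1L])))
    ## zero co-genotyped loci -> missing cell
    g3 <- cbind(s1 = c("A/A", NA), s2 = c(NA, "T/T"))
    expect_true(is.na(pairwiseDifferenceMatrix(
        makeGeno(g3, ploidy = c(2L, 2L)))$diff["s1", "s2"]))
})

test_that("auto thresholding recovers planted clonal structure exactly", {
    cfg <- simConfig(seed = 83L, nLoci = 120L)
    sim <- simulateGenome(cfg)
    truth <- simulateCohort(sim, cohortSpec("clonal_ramets", nGenets = 3L,
                                            rametsPerGenet = 6L,
                                            somaticDiffCount = 2L))
    mg <- genotypesFromTruth(truth)
    ca <- assignClones(pairwiseDifferenceMatrix(mg))
    expect_equal(length(unique(ca$groups)), 3L)
    want <- as.integer(factor(truth$samples$genet))
    got <- as.integer(factor(ca$groups[truth$samples$sample_id]))
    ## same partition up to label permutation
    expect_equal(length(unique(paste(want, got))), 3L)
    ## intra-genet differences are small, inter-genet large
    d <- ca$diff
    same <- outer(truth$samples$genet, truth$samples$genet, "==")
    expect_lte(max(d[same & upper.tri(d)]), 6L)
    expect_gte(min(d[!same & upper.tri(d)]), 27L)
})

test_that("clone grouping edge cases behave as contracted", {
    g <- matrix("A/A", 10L, 4L)
    mg <- makeGeno(g, ploidy = rep(2L, 4L))
    ca <- assignClones(pairwiseDifferenceMatrix(mg))
    expect_equal(length(unique(ca$groups)), 1L)
    ## threshold 0 on distinct samples: every sample its own group
    g2 <- rbind(c("A/A", "T/T", "C/C"), c("A/T", "A/A", "T/T"))
    ca2 <- assignClones(pairwiseDifferenceMatrix(
        makeGeno(g2, ploidy = rep(2L, 3L))), threshold = 0)
    expect_equal(length(unique(ca2$groups)), 3L)
})

test_that("population differentiation matches the estimator's definition", {
    ## pop1 at frequency 0.8, pop2 at 0.2, five diploids each
    g <- matrix(NA_character_, 1L, 10L)
    g[1L, 1:5] <- c("T/T", "T/T", "T/T", "T/A", "T/A")  # 8/10 T
    g[1L, 6:10] <- c("A/A", "A/A", "A/A", "A/T", "T/A") # wait: sorted pairs
    g[1L, 6:10] <- c("A/A", "A/A", "A/A", "A/T", "A/T") # 2/10 T
    mg <- makeGeno(g, ploidy = rep(2L, 10L),
                   population = rep(c("pop1", "pop2"), each = 5L))
    pd <- populationDifferentiation(mg)
    p1 <- 0.8; p2 <- 0.2; n1 <- n2 <- 10
    hudson <- ((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
               p2 * (1 - p2) / (n2 - 1)) /
              (p1 * (1 - p2) + p2 * (1 - p1))
    expect_equal(unname(pd$fst[1L]), hudson, tolerance = 1e-12)
    ## fixed identical -> 0; fixed opposite -> 1 (the first locus is
    ## annotated polymorphic, fixed for the same allele in both groups)
    gf <- rbind(rep("A/A", 4L), rep(c("C/C", "G/G"), each = 2L))
    mgf <- MigGenotypes(gf,
        locusInfo = data.frame(locus_id = c("L1", "L2"), snp_pos = c(1L, 1L),
                               alleles = c("A/T", "C/G"),
                               consensus = randSeq80(2L)),
        sampleInfo = data.frame(sample_id = sprintf("s%d", 1:4),
                                population = rep(c("pop1", "pop2"), each = 2L),
                                ploidy = 2L))
    pdf <- populationDifferentiation(mgf)
    expect_equal(unname(pdf$fst), c(0, 1))
    expect_error(populationDifferentiation(
        makeGeno(gf, ploidy = rep(2L, 4L))), "two populations")
})

test_that("differentiated simulated populations separate by allele sharing", {
    cfg <- simConfig(seed = 84L, nLoci = 150L)
    sim <- simulateGenome(cfg)
    truth <- simulateCohort(sim, cohortSpec("population_pair",
                                            nSamples = 4L, fstLike = 0.3))
    mg <- genotypesFromTruth(truth)
    pd <- populationDifferentiation(mg)
    expect_gt(pd$meanFst, 0.05)
    ash <- pd$alleleSharing
    pop <- truth$samples$population
    within <- ash[outer(pop, pop, "==") & upper.tri(ash)]
    between <- ash[outer(pop, pop, "!=") & upper.tri(ash)]
    expect_gt(mean(between), mean(within))
})
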