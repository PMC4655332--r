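## Downstream validation analyses: chi-square tests of 1:1 gametic
## segregation in haploid panels, clone identification from pairwise SNP
## mismatch counts, and allele-frequency differentiation summaries.

#' Chi-square test of 1:1 segregation in haploid samples
#'
#' For each locus at which the mother (or both declared replicates of
#' her) is heterozygous, at least `minInformative` haploids are
#' genotyped, and no haploid carries the heterozygote flag, counts the
#' two alleles among the haploids and tests the 1:1 gametic expectation:
#' chi-square = (a - b)^2 / (a + b), df = 1, by default without Yates
#' correction.
#'
#' @param mg A [MigGenotypes-class].
#' @param motherIds Character vector of the mother's sample id(s); with
#'   two ids (a replicate pair) both must carry a concordant heterozygous
#'   genotype for the locus to qualify.
#' @param haploidIds Sample ids of the haploid panel.
#' @param minInformative Minimum genotyped haploids (default 10).
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @param alpha Deviation flag level (default 0.05).
#' @return `data.frame` with one row per qualifying locus: `locus_id`,
#'   `allele_a`, `allele_b`, `count_a`, `count_b`, `informative_n`,
#'   `chi_square`, `p_value`, `deviant`. Zero qualifying loci yield an
#'   empty result with a warning.
#' @export
segregationTest <- function(mg, motherIds, haploidIds,
                            minInformative = 10L, yates = FALSE,
                            alpha = 0.05) {
    si <- sampleInfo(mg)
    stopifnot(all(motherIds %in% si$sample_id),
              all(haploidIds %in% si$sample_id))
    g <- genoMatrix(mg)
    hf <- hetFlags(mg)
    rd <- locusInfo(mg)
    rows <- list()
    for (i in seq_len(nrow(g))) {
        mo <- g[i, motherIds]
        if (any(is.na(mo))) next
        al <- unique(unlist(strsplit(mo[1L], "/", fixed = TRUE)))
        if (length(al) != 2L) next               # mother not heterozygous
        if (length(mo) > 1L && !all(mo == mo[1L])) next # replicates discordant
        hap <- g[i, haploidIds]
        typed <- !is.na(hap)
        if (sum(typed) < minInformative) next
        if (any(hf[i, haploidIds][typed])) next  # duplicated-locus signature
        a <- sum(hap[typed] == al[1L]); b <- sum(hap[typed] == al[2L])
        if (a + b < minInformative) next
        obs <- abs(a - b)
        if (yates) obs <- max(obs - 1, 0)
        chi <- obs^2 / (a + b)
        pval <- pchisq(chi, df = 1L, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            locus_id = rownames(g)[i], allele_a = al[1L], allele_b = al[2L],
            count_a = a, count_b = b, informative_n = a + b,
            chi_square = chi, p_value = pval, deviant = pval < alpha,
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) {
        warning("no loci qualify for segregation testing")
        return(data.frame(locus_id = character(0), allele_a = character(0),
                          allele_b = character(0), count_a = integer(0),
                          count_b = integer(0), informative_n = integer(0),
                          chi_square = numeric(0), p_value = numeric(0),
                          deviant = logical(0)))
    }
    do.call(rbind, rows)
}

#' Pairwise SNP-difference matrix between samples
#'
#' For each sample pair, counts the loci genotyped in both at which the
#' genotypes differ (any allelic mismatch counts as one difference);
#' loci missing in either sample are excluded from that pair's
#' comparison. Pairs with zero co-genotyped loci get `NA`.
#'
#' @param mg A [MigGenotypes-class].
#' @return List of class `CloneAssignment`: `diff` (symmetric integer
#'   matrix, zero diagonal), `shared` (co-genotyped locus counts),
#'   `histogram` (table of off-diagonal difference values), `groups`
#'   (`NULL` until [assignClones()]).
#' @export
pairwiseDifferenceMatrix <- function(mg) {
    g <- genoMatrix(mg)
    stopifnot(ncol(g) >= 2L)
    nS <- ncol(g)
    diffm <- matrix(NA_integer_, nS, nS,
                    dimnames = list(colnames(g), colnames(g)))
    shared <- matrix(0L, nS, nS, dimnames = dimnames(diffm))
    for (a in seq_len(nS)) {
        diffm[a, a] <- 0L
        shared[a, a] <- sum(!is.na(g[, a]))
        for (b in seq_len(a - 1L)) {
            ok <- !is.na(g[, a]) & !is.na(g[, b])
            shared[a, b] <- shared[b, a] <- sum(ok)
            if (!any(ok)) next
            d <- sum(g[ok, a] != g[ok, b])
            diffm[a, b] <- diffm[b, a] <- d
        }
    }
    vals <- diffm[upper.tri(diffm)]
    structure(list(diff = diffm, shared = shared,
                   histogram = table(vals[!is.na(vals)]), groups = NULL,
                   threshold = NA_real_), class = "CloneAssignment")
}

#' Group samples into clones from the difference matrix
#'
#' With clonal structure the pairwise-difference distribution is bimodal:
#' a near-zero peak of within-clone pairs (somatic differences only) and
#' a distant peak of between-clone pairs. The automatic threshold is the
#' midpoint of the largest gap between consecutive sorted difference
#' values; clones are the single-linkage connected components at or
#' below it.
#'
#' @param assignment A `CloneAssignment` from
#'   [pairwiseDifferenceMatrix()].
#' @param threshold Manual threshold (differences <= threshold join a
#'   clone); `"auto"` for the largest-gap rule.
#' @return The `CloneAssignment` with `groups` (named integer vector,
#'   sample to clone) and `threshold` filled in.
#' @export
assignClones <- function(assignment, threshold = "auto") {
    d <- assignment$diff
    vals <- sort(unique(d[upper.tri(d)]))
    vals <- vals[!is.na(vals)]
    if (identical(threshold, "auto")) {
        if (length(vals) < 2L) {
            threshold <- if (length(vals)) vals[1L] else 0
        } else {
            gaps <- diff(vals)
            k <- which.max(gaps)
            if (max(gaps) <= 1L)
                warning("pairwise differences look unimodal; ",
                        "auto threshold may be arbitrary")
            threshold <- (vals[k] + vals[k + 1L]) / 2
        }
    }
    dd <- d
    dd[is.na(dd)] <- max(vals, 1L) + 1L  # never joined
    if (all(dd[upper.tri(dd)] <= threshold)) {
        groups <- setNames(rep(1L, ncol(d)), colnames(d))
    } else {
        hc <- hclust(as.dist(dd), method = "single")
        groups <- cutree(hc, h = threshold)
    }
    assignment$groups <- groups
    assignment$threshold <- threshold
    assignment
}

#' Per-locus allele frequencies and differentiation between populations
#'
#' Computes per-population allele frequencies at every biallelic SNP
#' row, the Hudson-style differentiation estimator per locus
#' (frequency-variance based, with within-population sampling
#' correction) and its mean over loci, and an allele-sharing distance
#' matrix suitable for external ordination.
#'
#' @param mg A [MigGenotypes-class]; `sampleInfo(mg)$population` must
#'   hold two or more populations with at least 2 samples each.
#' @return List of class `PopDiffSummary`: `freqs` (loci x populations
#'   alt-allele frequencies), `fst` (per-locus), `meanFst`,
#'   `alleleSharing` (samples x samples distance matrix).
#' @export
populationDifferentiation <- function(mg) {
    si <- sampleInfo(mg)
    pops <- unique(si$population)
    if (length(pops) < 2L)
        stop("need at least two populations")
    if (any(table(si$population) < 2L))
        stop("each population needs at least 2 samples")
    g <- genoMatrix(mg)
    rd <- locusInfo(mg)
    poly <- which(!is.na(rd$snp_pos))
    freqs <- matrix(NA_real_, length(poly), length(pops),
                    dimnames = list(rownames(g)[poly], pops))
    ns <- freqs
    for (k in seq_along(poly)) {
        i <- poly[k]
        al <- sort(strsplit(rd$alleles[i], "/", fixed = TRUE)[[1L]])
        if (length(al) != 2L) next
        alt <- al[2L]
        for (pp in pops) {
            cols <- si$sample_id[si$population == pp]
            alleles <- unlist(lapply(g[i, cols], function(x)
                if (is.na(x)) NULL else strsplit(x, "/", fixed = TRUE)[[1L]]))
            if (length(alleles) == 0L) next
            freqs[k, pp] <- mean(alleles == alt)
            ns[k, pp] <- length(alleles)
        }
    }
    fst <- rep(NA_real_, nrow(freqs))
    if (length(pops) >= 2L) {
        p1 <- freqs[, 1L]; p2 <- freqs[, 2L]
        n1 <- ns[, 1L]; n2 <- ns[, 2L]
        num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
               p2 * (1 - p2) / pmax(n2 - 1, 1)
        den <- p1 * (1 - p2) + p2 * (1 - p1)
        fst <- ifelse(!is.na(den) & den > 0, num / den,
                      ifelse(!is.na(num) & abs(num) < 1e-12, 0, NA))
        ## Both populations fixed: identical allele -> 0, opposite -> 1.
        fixed_same <- !is.na(p1) & !is.na(p2) & p1 == p2 & (p1 %in% c(0, 1))
        fst[fixed_same] <- 0
    }
    ## Allele-sharing distance: 1 - mean shared-allele fraction per pair.
    nS <- ncol(g)
    ash <- matrix(0, nS, nS, dimnames = list(colnames(g), colnames(g)))
    split_al <- function(x) strsplit(x, "/", fixed = TRUE)
    for (a in seq_len(nS)) {
        for (b in seq_len(a - 1L)) {
            ok <- which(!is.na(g[poly, a]) & !is.na(g[poly, b]))
            if (length(ok) == 0L) { ash[a, b] <- ash[b, a] <- NA; next }
            sh <- vapply(ok, function(k) {
                x <- split_al(g[poly[k], a])[[1L]]
                y <- split_al(g[poly[k], b])[[1L]]
                if (length(x) == 1L) x <- rep(x, 2L)
                if (length(y) == 1L) y <- rep(y, 2L)
                ## multiset intersection: shared alleles out of 2
                tx <- table(x); ty <- table(y)
                common <- intersect(names(tx), names(ty))
                sum(pmin(tx[common], ty[common])) / 2
            }, numeric(1))
            ash[a, b] <- ash[b, a] <- 1 - mean(sh)
        }
    }
    structure(list(freqs = freqs, n_alleles = ns, fst = fst,
                   meanFst = mean(fst, na.rm = TRUE), alleleSharing = ash),
              class = "PopDiffSummary")
}
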