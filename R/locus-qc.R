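## Locus-level artifact control: singleton pseudo-variants (PCR errors
## visible in one sample only), replicate discordance with a depth
## chi-square signature, shifted-priming pseudo-locus homology groups,
## duplicated-locus classification from haploid heterozygote flags, and
## paired-end locus detection by perfect linkage.

qcStatuses <- c("kept", "removed_singleton", "removed_replicate_discordant",
                "removed_homology_group", "removed_paired_end")

newQCReport <- function(locus_ids) {
    data.frame(locus_id = locus_ids, status = "kept",
               evidence = NA_character_, flag = NA_character_,
               stringsAsFactors = FALSE)
}

## Alleles carried by each sample at a row, as a list of character vectors.
rowAlleles <- function(g_row) {
    lapply(g_row, function(x) if (is.na(x)) character(0)
           else strsplit(x, "/", fixed = TRUE)[[1L]])
}

#' Remove loci whose minor allele appears in a single sample
#'
#' Pseudo-variants from PCR errors cannot be shared among samples: a
#' locus whose minor allele (across all samples) is carried by exactly
#' one sample is removed. Monomorphic loci are untouched.
#'
#' @param mg A [MigGenotypes-class].
#' @return List with `mg` (filtered) and `report` (per-locus `status` and
#'   `evidence`).
#' @export
removeSingletonVariantLoci <- function(mg) {
    stopifnot(ncol(mg) >= 2L)
    rd <- locusInfo(mg)
    g <- genoMatrix(mg)
    report <- newQCReport(rownames(g))
    drop <- logical(nrow(g))
    for (i in which(!is.na(rd$snp_pos))) {
        al <- rowAlleles(g[i, ])
        carriers <- table(unlist(lapply(al, unique)))
        if (length(carriers) < 2L) next
        minor_n <- min(carriers)
        minor_allele <- names(carriers)[which.min(carriers)]
        if (minor_n == 1L) {
            drop[i] <- TRUE
            report$status[i] <- "removed_singleton"
            report$evidence[i] <- paste0("minor allele ", minor_allele,
                                         " in 1 sample")
        }
    }
    list(mg = mg[!drop, ], report = report)
}

#' Remove loci discordant between declared replicate pairs
#'
#' A genotype difference between two replicates of one individual cannot
#' be biological; such loci are removed. For each discordant locus a
#' chi-square test of the heterozygote's two allele depths against the
#' 1:1 ratio is reported — a significantly biased ratio (P < 0.05) is the
#' signature of an early-cycle PCR error rather than a sequencing error.
#'
#' @param mg A [MigGenotypes-class].
#' @param replicatePairs Two-column matrix or data.frame of sample-id
#'   pairs.
#' @return List with `mg`, `report`, and `depthTests` (`data.frame` of
#'   per-discordant-locus chi-square results with `biased` = P < 0.05).
#' @export
replicateConcordanceFilter <- function(mg, replicatePairs) {
    replicatePairs <- as.matrix(replicatePairs)
    si <- sampleInfo(mg)
    if (!all(replicatePairs %in% si$sample_id))
        stop("replicate sample(s) missing from the genotype matrix: ",
             paste(setdiff(replicatePairs, si$sample_id), collapse = ", "))
    g <- genoMatrix(mg)
    dM <- SummarizedExperiment::assay(mg, "depthMajor")
    dm <- SummarizedExperiment::assay(mg, "depthMinor")
    report <- newQCReport(rownames(g))
    tests <- list()
    drop <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
        for (k in seq_len(nrow(replicatePairs))) {
            a <- replicatePairs[k, 1L]; b <- replicatePairs[k, 2L]
            ga <- g[i, a]; gb <- g[i, b]
            if (is.na(ga) || is.na(gb) || ga == gb) next
            drop[i] <- TRUE
            ## Depth chi-square on the heterozygous replicate's two alleles.
            het <- if (grepl("/", ga) &&
                       length(unique(strsplit(ga, "/")[[1L]])) > 1L) a
                   else b
            d1 <- dM[i, het]; d2 <- dm[i, het]
            chi <- if (d1 + d2 > 0) (d1 - d2)^2 / (d1 + d2) else NA_real_
            pval <- if (is.na(chi)) NA_real_ else
                pchisq(chi, df = 1L, lower.tail = FALSE)
            tests[[length(tests) + 1L]] <- data.frame(
                locus_row = rownames(g)[i], pair = k, chi_square = chi,
                p_value = pval, biased = !is.na(pval) && pval < 0.05,
                stringsAsFactors = FALSE)
            report$status[i] <- "removed_replicate_discordant"
            report$evidence[i] <- paste0(a, "=", ga, " vs ", b, "=", gb)
        }
    }
    depthTests <- if (length(tests)) do.call(rbind, tests) else
        data.frame(locus_row = character(0), pair = integer(0),
                   chi_square = numeric(0), p_value = numeric(0),
                   biased = logical(0))
    list(mg = mg[!drop, ], report = report, depthTests = depthTests)
}

#' Remove shifted-priming pseudo-locus homology groups
#'
#' Shifted priming within one SSR run creates near-duplicate loci offset
#' by a few bases. For every locus pair the ungapped identity (matching
#' positions divided by the full 80-base read length) is computed at
#' every offset strictly inside `(-maxShift, maxShift)`; pairs whose
#' maximum identity exceeds `identityThreshold` form edges, and every
#' locus in a connected component of two or more is removed — whole
#' groups are eliminated even though they inevitably contain some true
#' loci. Two identical reads 16 bases apart at each end retain
#' (80-16-16)/80 = 0.6 identity, hence the 0.6 default threshold.
#'
#' @param mg A [MigGenotypes-class].
#' @param identityThreshold Identity above which a pair is linked
#'   (default 0.6, strict inequality).
#' @param maxShift Offsets scanned are strictly smaller in magnitude
#'   (default 16).
#' @param bothStrands Also scan reverse-complement alignments (default
#'   `FALSE`: shifted priming produces same-strand copies).
#' @param keepOne Keep the first locus of each group instead of removing
#'   the whole group (default `FALSE`).
#' @return List with `mg`, `report`, and `hits` (`data.frame` of linked
#'   pairs with identity and best shift).
#' @export
shiftedHomologyFilter <- function(mg, identityThreshold = 0.6,
                                  maxShift = 16L, bothStrands = FALSE,
                                  keepOne = FALSE) {
    rd <- locusInfo(mg)
    loci <- unique(rd$locus_id)
    cons <- rd$consensus[match(loci, rd$locus_id)]
    hits <- maxShiftedIdentity(cons, maxShift, identityThreshold)
    if (bothStrands) {
        rc_hits <- do.call(rbind, lapply(seq_along(cons), function(i) {
            if (i == length(cons)) return(NULL)
            others <- (i + 1L):length(cons)
            h <- maxShiftedIdentity(c(cons[i], revComp(cons[others])),
                                    maxShift, identityThreshold)
            h <- h[h$i == 1L, , drop = FALSE]
            if (nrow(h) == 0L) return(NULL)
            data.frame(i = i, j = others[h$j - 1L], identity = h$identity,
                       shift = h$shift)
        }))
        hits <- unique(rbind(hits, rc_hits))
    }
    report <- newQCReport(rownames(genoMatrix(mg)))
    if (nrow(hits) == 0L)
        return(list(mg = mg, report = report, hits = hits))
    ## Connected components by union-find over linked pairs.
    parent <- seq_along(loci)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in seq_len(nrow(hits)))
        parent[find(hits$i[k])] <- find(hits$j[k])
    comp <- vapply(seq_along(loci), find, integer(1))
    grp_size <- table(comp)
    in_group <- grp_size[as.character(comp)] >= 2L
    removed_loci <- loci[in_group]
    if (keepOne) {
        keep_first <- !duplicated(comp) & in_group
        removed_loci <- loci[in_group & !keep_first]
    }
    drop <- rd$locus_id %in% removed_loci
    report$status[drop] <- "removed_homology_group"
    for (k in seq_len(nrow(hits))) {
        for (side in c("i", "j")) {
            lid <- loci[hits[[side]][k]]
            rowsel <- rd$locus_id == lid
            report$evidence[rowsel] <- paste0(
                "partner=", loci[hits[[if (side == "i") "j" else "i"]][k]],
                " identity=", round(hits$identity[k], 3),
                " shift=", hits$shift[k])
        }
    }
    hits$locus_a <- loci[hits$i]; hits$locus_b <- loci[hits$j]
    list(mg = mg[!drop, ], report = report, hits = hits)
}

#' Classify duplicated loci from haploid heterozygote flags
#'
#' Two co-assembled genome copies make haploid samples look heterozygous.
#' The flag pattern across haploids separates the duplication types:
#' every genotyped haploid flagged — `dup_homo_homo` (copies fixed for
#' different alleles); flagged and unflagged near 1:1 (two-sided exact
#' binomial against 0.5 not rejected at `alpha`) with one allele among
#' the unflagged — `dup_homo_hetero`; both alleles among the unflagged —
#' `dup_hetero_hetero` (the 1:2:1 pattern); a minority class of 1-3
#' samples — `dup_linkage` (this small-count rule takes precedence); no
#' flags — `normal`.
#'
#' @param mg A [MigGenotypes-class].
#' @param haploidIds Sample ids of the haploid panel (at least
#'   `minHaploids` must be genotyped per locus to classify).
#' @param alpha Binomial test level (default 0.05).
#' @param minHaploids Minimum genotyped haploids per locus (default 8).
#' @return `data.frame` per locus row: `locus_id`, `type`, `n_flagged`,
#'   `n_unflagged`, `binom_p`.
#' @export
classifyDuplicatedLoci <- function(mg, haploidIds, alpha = 0.05,
                                   minHaploids = 8L) {
    si <- sampleInfo(mg)
    if (length(haploidIds) < minHaploids)
        stop("duplicated-locus classification needs at least ", minHaploids,
             " haploid samples; got ", length(haploidIds))
    stopifnot(all(haploidIds %in% si$sample_id))
    g <- genoMatrix(mg)[, haploidIds, drop = FALSE]
    hf <- hetFlags(mg)[, haploidIds, drop = FALSE]
    rd <- locusInfo(mg)
    out <- lapply(seq_len(nrow(g)), function(i) {
        typed <- !is.na(g[i, ])
        nf <- sum(hf[i, typed]); nu <- sum(typed) - nf
        if (sum(typed) < minHaploids)
            return(data.frame(locus_id = rd$locus_id[i], type = NA_character_,
                              n_flagged = nf, n_unflagged = nu,
                              binom_p = NA_real_))
        type <- if (nf == 0L) "normal"
            else if (nu == 0L) "dup_homo_homo"
            else if (min(nf, nu) <= 3L) "dup_linkage"
            else {
                pb <- binom.test(nf, nf + nu, 0.5)$p.value
                un_alleles <- unique(g[i, typed][!hf[i, typed]])
                if (length(un_alleles) >= 2L) "dup_hetero_hetero"
                else "dup_homo_hetero"
            }
        pb <- if (nf > 0L && nu > 0L)
            binom.test(nf, nf + nu, 0.5)$p.value else NA_real_
        data.frame(locus_id = rd$locus_id[i], type = type, n_flagged = nf,
                   n_unflagged = nu, binom_p = pb, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Detect paired-end loci by perfect linkage
#'
#' The two 80-base ends of one amplicon segregate as one fragment, so
#' their genotype vectors are perfectly concordant: across co-genotyped
#' samples the mapping between the two loci's genotype values is a
#' bijection with zero recombinants. Such pairs are reported and the
#' higher-ID locus of each pair removed.
#'
#' @param mg A [MigGenotypes-class].
#' @param minInformative Minimum co-genotyped samples, both loci
#'   polymorphic among them (default 8).
#' @return List with `mg` (one of each pair removed), `pairs`
#'   (`data.frame` `locus_a`, `locus_b`, `n_informative`), `report`.
#' @export
detectPairedEndLoci <- function(mg, minInformative = 8L) {
    g <- genoMatrix(mg)
    rd <- locusInfo(mg)
    poly <- which(!is.na(rd$snp_pos))
    pairs <- list()
    for (ii in seq_along(poly)) {
        for (jj in seq_len(ii - 1L)) {
            i <- poly[ii]; j <- poly[jj]
            ok <- !is.na(g[i, ]) & !is.na(g[j, ])
            if (sum(ok) < minInformative) next
            gi <- g[i, ok]; gj <- g[j, ok]
            if (length(unique(gi)) < 2L || length(unique(gj)) < 2L) next
            map <- unique(cbind(gi, gj))
            bij <- !anyDuplicated(map[, 1L]) && !anyDuplicated(map[, 2L])
            if (bij)
                pairs[[length(pairs) + 1L]] <- data.frame(
                    locus_a = rownames(g)[min(i, j)],
                    locus_b = rownames(g)[max(i, j)],
                    n_informative = sum(ok), stringsAsFactors = FALSE)
        }
    }
    report <- newQCReport(rownames(g))
    if (length(pairs) == 0L)
        return(list(mg = mg, pairs = data.frame(locus_a = character(0),
                                                locus_b = character(0),
                                                n_informative = integer(0)),
                    report = report))
    pairs <- do.call(rbind, pairs)
    drop_rows <- unique(pairs$locus_b)
    sel <- rownames(g) %in% drop_rows
    report$status[sel] <- "removed_paired_end"
    report$evidence[sel] <- vapply(rownames(g)[sel], function(r)
        paste0("paired with ", pairs$locus_a[match(r, pairs$locus_b)]),
        character(1))
    list(mg = mg[!sel, ], pairs = pairs, report = report)
}

#' Run the artifact filters in pipeline order
#'
#' Applies, in order: singleton-variant removal, replicate concordance
#' (when replicate pairs are declared), shifted-homology group removal,
#' and paired-end locus removal. The order is fixed and matches the
#' analysis pipeline; re-running on filtered output is idempotent.
#'
#' @param mg A [MigGenotypes-class].
#' @param replicatePairs Optional two-column matrix of replicate sample
#'   ids.
#' @param homology,pairedEnd Logical switches (default `TRUE`).
#' @return List with `mg` and `report` (one row per input locus row;
#'   kept + removed counts conserve the input).
#' @export
qcPipeline <- function(mg, replicatePairs = NULL, homology = TRUE,
                       pairedEnd = TRUE) {
    report <- newQCReport(rownames(genoMatrix(mg)))
    rownames(report) <- report$locus_id <- rownames(genoMatrix(mg))
    merge_report <- function(rep_new) {
        sel <- rep_new$status != "kept"
        report[rownames(rep_new)[sel], c("status", "evidence")] <<-
            rep_new[sel, c("status", "evidence")]
    }
    s1 <- removeSingletonVariantLoci(mg)
    rownames(s1$report) <- s1$report$locus_id
    merge_report(s1$report); mg <- s1$mg
    if (!is.null(replicatePairs)) {
        s2 <- replicateConcordanceFilter(mg, replicatePairs)
        rownames(s2$report) <- s2$report$locus_id
        merge_report(s2$report); mg <- s2$mg
    }
    if (homology) {
        s3 <- shiftedHomologyFilter(mg)
        rownames(s3$report) <- s3$report$locus_id
        merge_report(s3$report); mg <- s3$mg
    }
    if (pairedEnd) {
        s4 <- detectPairedEndLoci(mg)
        rownames(s4$report) <- s4$report$locus_id
        merge_report(s4$report); mg <- s4$mg
    }
    list(mg = mg, report = report)
}
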