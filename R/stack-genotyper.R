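## Simplified de-novo stack-based SNP genotyper: identical 80-base reads are
## bundled into stacks per sample, stacks within M mismatches merge into
## sample loci, sample loci cluster across samples into a catalog within n
## mismatches, and genotypes are called by the depth-ratio rule. This is a
## functional desk-scale stand-in for the ustacks/cstacks/sstacks/populations
## chain, not a bit-exact reproduction.

#' Genotyper configuration
#'
#' @param m Minimum depth of coverage required to create a stack
#'   (default 20).
#' @param M Maximum distance between merged stacks within a sample
#'   (default 2).
#' @param n Allowed mismatches between samples when building the catalog
#'   (default 4).
#' @param hetRatio Minimum minor/major depth ratio to call a heterozygote
#'   (default 1/20; a minor allele below it is rejected from the
#'   genotype).
#' @param r Minimum fraction of samples per population in which a locus
#'   must be genotyped (default 0.5).
#' @param p Minimum number of populations meeting `r` (default 1).
#' @param singleSnp Keep only the first (leftmost) SNP per locus
#'   (default `TRUE`).
#' @param maxStacksPerLocus Sample loci assembled from more than this many
#'   stacks are discarded — the documented simplification standing in for
#'   the deleveraging/removal algorithms (default 3).
#' @return A list of class `GenotyperConfig`.
#' @export
genotyperConfig <- function(m = 20L, M = 2L, n = 4L, hetRatio = 1 / 20,
                            r = 0.5, p = 1L, singleSnp = TRUE,
                            maxStacksPerLocus = 3L) {
    stopifnot(m >= 1L, hetRatio > 0, hetRatio < 1, r > 0, r <= 1, p >= 1L)
    structure(list(m = as.integer(m), M = as.integer(M), n = as.integer(n),
                   hetRatio = hetRatio, r = r, p = as.integer(p),
                   singleSnp = singleSnp,
                   maxStacksPerLocus = as.integer(maxStacksPerLocus)),
              class = "GenotyperConfig")
}

#' Build stacks and merge them into sample loci
#'
#' Identical reads are bundled into stacks; stacks with depth below `m`
#' cannot seed a locus but are retained as secondary reads. Seeds are
#' processed greedily from the deepest (ties broken lexicographically by
#' sequence): each unassigned seed starts a locus and absorbs every
#' unassigned seed within `M` substitutions of it. Loci assembled from
#' more than `maxStacksPerLocus` seeds are discarded. Secondary reads are
#' then added to the locus whose seed consensus is nearest within `M`.
#'
#' @param reads Character vector of 80-base reads for one sample.
#' @param config A [genotyperConfig()].
#' @return List of sample loci; each has `consensus` (the deepest seed),
#'   `seqs`, `depths`, `n_stacks` and `depth` (total).
#' @export
buildStacks <- function(reads, config = genotyperConfig()) {
    if (length(reads) == 0L) return(list())
    if (any(nchar(reads) != READ_LEN))
        stop("all reads must be ", READ_LEN, " bases")
    tab <- table(reads)
    seqs <- names(tab)
    depths <- as.integer(tab)
    is_seed <- depths >= config$m
    if (!any(is_seed)) return(list())
    seed_seq <- seqs[is_seed]
    seed_depth <- depths[is_seed]
    ord <- order(-seed_depth, seed_seq)
    seed_seq <- seed_seq[ord]; seed_depth <- seed_depth[ord]

    assigned <- rep(NA_integer_, length(seed_seq))
    locus_of_seed <- 0L
    for (i in seq_along(seed_seq)) {
        if (!is.na(assigned[i])) next
        locus_of_seed <- locus_of_seed + 1L
        assigned[i] <- locus_of_seed
        free <- which(is.na(assigned))
        if (length(free)) {
            d <- hammingDist(seed_seq[i], seed_seq[free])
            assigned[free[d <= config$M]] <- locus_of_seed
        }
    }
    loci <- lapply(seq_len(locus_of_seed), function(l) {
        idx <- which(assigned == l)
        list(consensus = seed_seq[idx[1L]], seqs = seed_seq[idx],
             depths = seed_depth[idx], n_stacks = length(idx))
    })
    loci <- Filter(function(x) x$n_stacks <= config$maxStacksPerLocus, loci)
    if (length(loci) == 0L) return(list())

    sec_seq <- seqs[!is_seed]; sec_depth <- depths[!is_seed]
    if (length(sec_seq)) {
        cons <- vapply(loci, `[[`, character(1), "consensus")
        hp <- hammingPairs(sec_seq, cons, config$M)
        if (nrow(hp)) {
            ## nearest locus; ties to the first (deepest) locus
            hp <- hp[order(hp$i, hp$dist, hp$j), ]
            hp <- hp[!duplicated(hp$i), ]
            for (k in seq_len(nrow(hp))) {
                l <- hp$j[k]
                loci[[l]]$seqs <- c(loci[[l]]$seqs, sec_seq[hp$i[k]])
                loci[[l]]$depths <- c(loci[[l]]$depths, sec_depth[hp$i[k]])
            }
        }
    }
    lapply(loci, function(x) { x$depth <- sum(x$depths); x })
}

#' Call a genotype from per-allele depths at one site
#'
#' Diploid: heterozygous iff the minor/major depth ratio reaches
#' `hetRatio`, else homozygous for the major allele. Haploid: always the
#' major allele, with a haploid-heterozygote flag recorded whenever the
#' diploid rule would have called a heterozygote (input to the
#' duplicated-locus classifier). Ties in depth break lexicographically.
#'
#' @param depths Named numeric vector of per-allele read depths.
#' @param ploidy 1 or 2.
#' @param config A [genotyperConfig()].
#' @return List with `geno` (e.g. `"A/T"`, `"A"`, or `NA` for zero
#'   depth), `depthMajor`, `depthMinor`, `hetFlag`.
#' @export
callGenotype <- function(depths, ploidy = 2L, config = genotyperConfig()) {
    depths <- depths[depths > 0]
    if (length(depths) == 0L)
        return(list(geno = NA_character_, depthMajor = 0L, depthMinor = 0L,
                    hetFlag = FALSE))
    ord <- order(-depths, names(depths))
    major <- names(depths)[ord[1L]]
    d1 <- depths[[ord[1L]]]
    d2 <- if (length(depths) > 1L) depths[[ord[2L]]] else 0
    minor <- if (length(depths) > 1L) names(depths)[ord[2L]] else NA
    is_het <- d2 / d1 >= config$hetRatio && d2 > 0
    if (ploidy == 2L) {
        geno <- if (is_het) paste(sort(c(major, minor)), collapse = "/")
                else paste(major, major, sep = "/")
        list(geno = geno, depthMajor = d1, depthMinor = if (is_het) d2 else 0L,
             hetFlag = FALSE)
    } else {
        list(geno = major, depthMajor = d1, depthMinor = if (is_het) d2 else 0L,
             hetFlag = is_het)
    }
}

#' Cluster sample loci across samples into a catalog
#'
#' Greedy clustering of sample-locus consensus sequences: loci are
#' processed from the deepest (ties lexicographic); each locus joins the
#' nearest existing catalog locus within `n` substitutions or founds a
#' new one whose consensus is its own (so every catalog consensus is its
#' first, deepest member). Each sample locus matches at most one catalog
#' locus.
#'
#' @param sampleLoci Named list (sample id) of [buildStacks()] outputs.
#' @param config A [genotyperConfig()].
#' @return List with `catalog` (`data.frame`: `catalog_id`, `consensus`)
#'   and `members` (`data.frame`: `catalog_id`, `sample_id`, `locus_idx`,
#'   `depth`).
#' @export
buildCatalog <- function(sampleLoci, config = genotyperConfig()) {
    entries <- do.call(rbind, lapply(names(sampleLoci), function(s) {
        loci <- sampleLoci[[s]]
        if (length(loci) == 0L) return(NULL)
        data.frame(sample_id = s, locus_idx = seq_along(loci),
                   consensus = vapply(loci, `[[`, character(1), "consensus"),
                   depth = vapply(loci, `[[`, numeric(1), "depth"),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(entries) || nrow(entries) == 0L)
        return(list(catalog = data.frame(catalog_id = character(0),
                                         consensus = character(0)),
                    members = data.frame()))
    entries <- entries[order(-entries$depth, entries$consensus), ]
    cat_cons <- character(0)
    assign <- integer(nrow(entries))
    for (k in seq_len(nrow(entries))) {
        if (length(cat_cons)) {
            d <- hammingDist(entries$consensus[k], cat_cons)
            j <- which.min(d)
            if (d[j] <= config$n) { assign[k] <- j; next }
        }
        cat_cons <- c(cat_cons, entries$consensus[k])
        assign[k] <- length(cat_cons)
    }
    catalog <- data.frame(catalog_id = sprintf("cat%05d",
                                               seq_along(cat_cons)),
                          consensus = cat_cons, stringsAsFactors = FALSE)
    members <- data.frame(catalog_id = catalog$catalog_id[assign],
                          sample_id = entries$sample_id,
                          locus_idx = entries$locus_idx,
                          depth = entries$depth, stringsAsFactors = FALSE)
    list(catalog = catalog, members = members)
}

#' Genotype preprocessed samples into a MigGenotypes matrix
#'
#' Runs [buildStacks()] per sample, [buildCatalog()] across samples,
#' identifies SNP sites per catalog locus (positions where the
#' depth-ratio rule retains two or more alleles across samples), and
#' calls per-sample genotypes. A locus not detected in a sample is
#' missing data, never homozygous reference.
#'
#' @param pools Named list (sample id) of 80-base read vectors, as from
#'   [preprocessRun()].
#' @param samples `data.frame` with `sample_id`, `population`, `ploidy`;
#'   defaults to one population of diploids.
#' @param config A [genotyperConfig()].
#' @return A [MigGenotypes-class] with one row per catalog locus SNP site
#'   (monomorphic loci keep a single row with `snp_pos = NA`). Apply
#'   [populationFilter()] for the r/p/single-SNP marker selection.
#' @export
genotypeSamples <- function(pools, samples = NULL,
                            config = genotyperConfig()) {
    if (is.null(samples))
        samples <- data.frame(sample_id = names(pools), population = "pop1",
                              ploidy = 2L, stringsAsFactors = FALSE)
    stopifnot(all(names(pools) %in% samples$sample_id))
    sampleLoci <- lapply(pools, buildStacks, config = config)
    cat <- buildCatalog(sampleLoci, config)
    nS <- nrow(samples)
    rows <- list()
    mem_split <- split(cat$members,
                       factor(cat$members$catalog_id,
                              levels = cat$catalog$catalog_id))
    ploidy_of <- setNames(samples$ploidy, samples$sample_id)
    for (ci in seq_len(nrow(cat$catalog))) {
        cid <- cat$catalog$catalog_id[ci]
        cons <- cat$catalog$consensus[ci]
        mem <- mem_split[[ci]]
        mem_by_sample <- split(mem$locus_idx, mem$sample_id)
        ## Pool each sample's member loci into one seq/depth table.
        per_sample <- lapply(setNames(nm = samples$sample_id), function(s) {
            li <- mem_by_sample[[s]]
            if (is.null(li)) return(NULL)
            sq <- unlist(lapply(li, function(l) sampleLoci[[s]][[l]]$seqs))
            dp <- unlist(lapply(li, function(l) sampleLoci[[s]][[l]]$depths))
            us <- unique(sq)
            dagg <- vapply(split(dp, factor(sq, levels = us)), sum,
                           numeric(1))
            list(useqs = us, depths = unname(dagg))
        })
        ## Candidate variable positions: where any member sequence differs
        ## from the catalog consensus.
        all_seqs <- unique(unlist(lapply(per_sample, function(x)
            if (is.null(x)) NULL else x$useqs)))
        cand <- variablePositions(cons, all_seqs)
        site_calls <- list()
        for (pos in cand) {
            calls <- lapply(samples$sample_id, function(s) {
                x <- per_sample[[s]]
                if (is.null(x)) return(NULL)
                base_at <- substr(x$useqs, pos, pos)
                d <- vapply(split(x$depths, base_at), sum, numeric(1))
                callGenotype(d, ploidy = ploidy_of[[s]], config = config)
            })
            alleles <- unique(unlist(lapply(calls, function(cl) {
                if (is.null(cl) || is.na(cl$geno)) return(NULL)
                strsplit(cl$geno, "/", fixed = TRUE)[[1L]]
            })))
            if (length(alleles) >= 2L)
                site_calls[[as.character(pos)]] <- calls
        }
        if (length(site_calls) == 0L) {
            ## Monomorphic locus: record presence with a homozygous
            ## consensus-base call.
            geno <- rep(NA_character_, nS)
            dM <- integer(nS)
            present <- !vapply(per_sample, is.null, logical(1))
            base1 <- substr(cons, 1L, 1L)
            geno[present] <- ifelse(samples$ploidy[present] == 1L, base1,
                                    paste(base1, base1, sep = "/"))
            dM[present] <- vapply(per_sample[present], function(x)
                as.integer(sum(x$depths)), integer(1))
            rows[[length(rows) + 1L]] <- list(
                locus_id = cid, snp_pos = NA_integer_,
                alleles = NA_character_, consensus = cons, geno = geno,
                dM = dM, dm = integer(nS), hf = rep(FALSE, nS))
            next
        }
        for (pos_chr in names(site_calls)) {
            calls <- site_calls[[pos_chr]]
            geno <- vapply(calls, function(cl)
                if (is.null(cl)) NA_character_ else cl$geno, character(1))
            dM <- vapply(calls, function(cl)
                if (is.null(cl)) 0L else as.integer(cl$depthMajor), integer(1))
            dm <- vapply(calls, function(cl)
                if (is.null(cl)) 0L else as.integer(cl$depthMinor), integer(1))
            hf <- vapply(calls, function(cl)
                if (is.null(cl)) FALSE else cl$hetFlag, logical(1))
            alle <- sort(unique(unlist(strsplit(geno[!is.na(geno)], "/"))))
            rows[[length(rows) + 1L]] <- list(
                locus_id = cid, snp_pos = as.integer(pos_chr),
                alleles = paste(alle, collapse = "/"), consensus = cons,
                geno = geno, dM = dM, dm = dm, hf = hf)
        }
    }
    if (length(rows) == 0L) stop("no catalog loci were formed")
    locusInfo <- data.frame(
        locus_id = vapply(rows, `[[`, character(1), "locus_id"),
        snp_pos = vapply(rows, `[[`, integer(1), "snp_pos"),
        alleles = vapply(rows, `[[`, character(1), "alleles"),
        consensus = vapply(rows, `[[`, character(1), "consensus"),
        stringsAsFactors = FALSE)
    geno <- do.call(rbind, lapply(rows, `[[`, "geno"))
    MigGenotypes(geno,
                 depthMajor = do.call(rbind, lapply(rows, `[[`, "dM")),
                 depthMinor = do.call(rbind, lapply(rows, `[[`, "dm")),
                 hetFlag = do.call(rbind, lapply(rows, `[[`, "hf")),
                 locusInfo = locusInfo,
                 sampleInfo = samples[, c("sample_id", "population",
                                          "ploidy")])
}

## Positions at which any of `seqs` differs from the consensus.
variablePositions <- function(cons, seqs) {
    seqs <- setdiff(seqs, cons)
    if (length(seqs) == 0L) return(integer(0))
    cl <- strsplit(cons, "")[[1L]]
    pos <- unique(unlist(lapply(strsplit(seqs, ""), function(x)
        which(x != cl))))
    sort(pos)
}

#' Marker selection: r/p presence filter and single-SNP rule
#'
#' Keeps loci genotyped in at least a fraction `r` of the samples of at
#' least `p` populations; optionally keeps only the first (leftmost) SNP
#' of each locus and drops monomorphic loci.
#'
#' @param mg A [MigGenotypes-class].
#' @param config A [genotyperConfig()] supplying `r`, `p` and
#'   `singleSnp`.
#' @param dropMonomorphic Drop loci without a SNP (default `FALSE`).
#' @return The filtered [MigGenotypes-class].
#' @export
populationFilter <- function(mg, config = genotyperConfig(),
                             dropMonomorphic = FALSE) {
    si <- sampleInfo(mg)
    g <- genoMatrix(mg)
    rd <- locusInfo(mg)
    pops <- unique(si$population)
    ## Presence per locus (any row of the locus genotyped in the sample).
    loci <- unique(rd$locus_id)
    keep_locus <- vapply(loci, function(l) {
        pres <- colSums(!is.na(g[rd$locus_id == l, , drop = FALSE])) > 0L
        ok <- vapply(pops, function(pp) {
            idx <- si$population == pp
            mean(pres[idx]) >= config$r
        }, logical(1))
        sum(ok) >= config$p
    }, logical(1))
    keep <- rd$locus_id %in% loci[keep_locus]
    if (config$singleSnp) {
        ord <- order(match(rd$locus_id, loci), rd$snp_pos)
        first <- !duplicated(rd$locus_id[ord])
        keep_first <- logical(nrow(rd)); keep_first[ord] <- first
        keep <- keep & keep_first
    }
    if (dropMonomorphic) keep <- keep & !is.na(rd$snp_pos)
    mg[keep, ]
}
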