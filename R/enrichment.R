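#' Pathway enrichment for GWAS results
#'
#' The core computation: each gene is represented by its most significant
#' SNP, genes are ranked by `r = -log10(p_min)`, and a pathway is scored
#' with a weighted Kolmogorov-Smirnov-like running sum that is incremented
#' by `|r|^p / N_R` at pathway members (with `N_R` the sum of `|r|^p` over
#' members) and decremented by `1 / (N - N_S)` at non-members. The
#' enrichment score ES is the maximum positive deviation of the running
#' sum; significance comes from re-running the whole pipeline under
#' phenotype-label permutations.
#'
#' @name enrichment
NULL

# ---- internal fast path --------------------------------------------------

# Pre-resolve the SNP -> gene assignment once per analysis. SNP indices are
# sorted by gene then SNP id so that ties in min-p resolve to the
# lexicographically smallest SNP id deterministically.
.genePrep <- function(snpIds, snpGeneMap) {
    if (is.null(names(snpGeneMap)))
        stop("snpGeneMap must be a named character vector (snp -> gene)")
    if (anyDuplicated(names(snpGeneMap)))
        stop("each SNP may map to at most one gene")
    gene <- unname(snpGeneMap[snpIds])
    keep <- which(!is.na(gene))
    if (length(keep)) {
        ord <- orderRadix(gene[keep], snpIds[keep])
        keep <- keep[ord]
    }
    g <- gene[keep]
    lev <- unique(g)                         # already sorted by radix order
    list(snpIdx = keep, snpIds = snpIds[keep],
         geneLevels = lev,
         split = split(keep, factor(g, levels = lev)))
}

# Minimum surviving p per gene; NA when every SNP of the gene is flagged.
.geneMinP <- function(p, split) {
    vapply(split, function(ix) {
        v <- p[ix]
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1))
}

.rankStat <- function(pmin, statistic) {
    pmin <- pmax(pmin, 1e-300)
    switch(statistic,
        mlog10p = -log10(pmin),
        chisq = stats::qchisq(pmin, df = 1, lower.tail = FALSE),
        stop("unknown ranking statistic: ", statistic))
}

# Weighted KS running sum over a ranked statistic vector and a hit mask.
.esCore <- function(r, hit, weightP) {
    N <- length(hit)
    nS <- sum(hit)
    w <- abs(r)^weightP
    nr <- sum(w[hit])
    if (nr == 0) {                 # all member statistics are zero: the
        w[] <- 1                   # weighted increments degenerate, fall
        nr <- nS                   # back to equal weights
    }
    step <- rep(-1 / (N - nS), N)
    step[hit] <- w[hit] / nr
    cs <- cumsum(step)
    peak <- which.max(cs)
    es <- cs[peak]
    if (es < 0) es <- 0
    list(es = es, runningSum = cs, peak = peak)
}

# ---- public operations ---------------------------------------------------

#' Gene-level statistics from an association scan
#'
#' Collapses per-SNP results to one statistic per gene: the smallest
#' p-value among the gene's surviving (non-flagged) SNPs, transformed to
#' the ranking statistic `r`. Genes whose SNPs were all removed by QC or
#' flagged in the scan are omitted. A tie in the minimum p is resolved to
#' the lexicographically smallest SNP id.
#'
#' @param scan `DataFrame` from [associationScan()] (needs columns `snp`,
#'   `p`; rows with `NA` p are treated as flagged and ignored).
#' @param snpGeneMap named character vector mapping SNP id to gene id.
#' @param statistic ranking statistic: `"mlog10p"` for `-log10(p_min)`
#'   (default) or `"chisq"` for the 1-df chi-square quantile of `p_min`.
#' @return `DataFrame` with columns `geneId`, `bestSnp`, `pMin`, `r`,
#'   ordered by gene id.
#' @examples
#' scan <- S4Vectors::DataFrame(snp = c("a", "b", "c"),
#'                              p = c(0.5, 0.01, 0.2))
#' geneStatistics(scan, c(a = "g1", b = "g1", c = "g1"))  # r = 2
#' @export
geneStatistics <- function(scan, snpGeneMap,
                           statistic = c("mlog10p", "chisq")) {
    statistic <- match.arg(statistic)
    snp <- if ("snp" %in% colnames(scan)) scan$snp else rownames(scan)
    p <- scan$p
    prep <- .genePrep(snp, snpGeneMap)
    pmin <- .geneMinP(p, prep$split)
    best <- vapply(prep$split, function(ix) {
        v <- p[ix]
        if (all(is.na(v))) NA_character_ else snp[ix[which.min(v)]]
    }, character(1))
    ok <- !is.na(pmin)
    S4Vectors::DataFrame(geneId = prep$geneLevels[ok],
                         bestSnp = unname(best[ok]),
                         pMin = unname(pmin[ok]),
                         r = .rankStat(unname(pmin[ok]), statistic))
}

#' Rank genes by association evidence
#'
#' Sorts gene statistics from largest to smallest `r`; ties break by gene
#' id ascending so the order is deterministic.
#'
#' @param stats `DataFrame` from [geneStatistics()].
#' @return A [RankedGeneList].
#' @export
rankGenes <- function(stats) {
    if (anyDuplicated(stats$geneId))
        stop("duplicate gene ids in gene statistics")
    ord <- orderRadix(-stats$r, stats$geneId)
    methods::new("RankedGeneList",
                 stats = S4Vectors::DataFrame(stats)[ord, , drop = FALSE])
}

#' @describeIn rankGenes gene ids in rank order.
#' @param x a `RankedGeneList`.
#' @export
geneIds <- function(x) {
    stopifnot(methods::is(x, "RankedGeneList"))
    x@stats$geneId
}

#' @describeIn rankGenes the underlying statistics table in rank order.
#' @export
geneRanking <- function(x) {
    stopifnot(methods::is(x, "RankedGeneList"))
    x@stats
}

setMethod("show", "RankedGeneList", function(object) {
    n <- nrow(object@stats)
    cat("RankedGeneList:", n, "genes\n")
    if (n) {
        top <- utils::head(as.data.frame(object@stats), 5L)
        print(top)
        if (n > 5L) cat("  ...", n - 5L, "more\n")
    }
})

#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list from top to bottom, adding `|r_j|^p / N_R`
#' when gene j belongs to the set (with `N_R` the sum of `|r|^p` over the
#' set members present in the list) and subtracting `1 / (N - N_S)`
#' otherwise. The enrichment score is the maximum positive deviation of
#' this running sum; the leading edge is the set members ranked at or
#' before the position where the maximum is attained. Set members absent
#' from the ranked list simply reduce the effective set size `N_S`.
#'
#' @param ranked a [RankedGeneList].
#' @param geneSet character vector of member gene ids.
#' @param weightP weight exponent `p` (default 1; 0 gives the classic
#'   unweighted Kolmogorov-Smirnov statistic).
#' @return List with `es`, `runningSum` (named by ranked gene id),
#'   `leadingEdge`, `peakIndex`, `nS`.
#' @examples
#' rl <- rankGenes(S4Vectors::DataFrame(
#'     geneId = c("g1", "g2", "g3"), bestSnp = NA_character_,
#'     pMin = c(1e-3, 1e-2, 1e-1), r = c(3, 2, 1)))
#' enrichmentScore(rl, "g1")$es  # 1
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1) {
    stopifnot(methods::is(ranked, "RankedGeneList"))
    .assertScalarNumber(weightP, "weightP", lo = 0)
    s <- ranked@stats
    N <- nrow(s)
    hit <- s$geneId %in% geneSet
    nS <- sum(hit)
    if (nS == 0L)
        stop("gene set shares no genes with the ranked list: untestable")
    if (nS == N)
        stop("gene set covers the whole ranked list: no misses to walk")
    core <- .esCore(s$r, hit, weightP)
    rs <- core$runningSum
    names(rs) <- s$geneId
    list(es = core$es,
         runningSum = rs,
         leadingEdge = s$geneId[hit & seq_len(N) <= core$peak],
         peakIndex = core$peak,
         nS = nS)
}

# Enrichment scores of several sets against one ranked statistic vector.
# `membership` is a list of logical masks in gene-level order; `ord` is the
# ranking permutation.
.esManySets <- function(r, ord, membership, weightP) {
    rOrd <- r[ord]
    vapply(membership, function(memb) {
        .esCore(rOrd, memb[ord], weightP)$es
    }, numeric(1))
}

# ---- permutation machinery ----------------------------------------------

.observedPipeline <- function(ge, snpGeneMap, statistic, useCovariates) {
    scan <- associationScan(ge, useCovariates = useCovariates)
    stats <- geneStatistics(scan, snpGeneMap, statistic = statistic)
    list(scan = scan, stats = stats, ranked = rankGenes(stats))
}

#' Multi-set pathway analysis with a shared permutation stream
#'
#' Runs the full pipeline — association scan, gene statistics, ranking,
#' enrichment score — on the observed phenotype labels, then repeats it
#' `k` times with the case/control labels permuted uniformly at random
#' across subjects (genotypes and covariates stay attached to their
#' subjects). Every permutation's re-ranked list is scored against every
#' set, so all sets share one permutation stream. The nominal p-value of a
#' set is the fraction of permuted scores greater than or equal to the
#' observed score, and `NES = ES / mean(positive permuted ES)`.
#'
#' @param ge a QC-passed [GenotypeExperiment] with `status` (and
#'   optionally `age`, `sex`) in `colData`.
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param snpGeneMap named character vector, SNP id -> gene id.
#' @param k number of permutations (default 1000).
#' @param seed integer master seed for the permutation stream.
#' @param weightP weight exponent of the running sum (default 1).
#' @param statistic gene ranking statistic, see [geneStatistics()].
#' @param useCovariates fit age/sex covariates when present (default TRUE).
#' @param mode `"phenotype"` (canonical: permute case/control labels and
#'   recompute everything) or `"gene"` (fast approximation: keep the
#'   observed ranking and redraw random sets of the same size; does not
#'   preserve inter-SNP correlation and is not the reference method).
#' @param adjustBH add a Benjamini-Hochberg adjusted p-value column
#'   across sets (default FALSE; no cross-pathway correction otherwise).
#' @return `DataFrame` with one row per set: `set`, `nS`, `es`, `nes`,
#'   `nominalP`, `k`, `seed` (+ `pBH` if requested), with the per-set
#'   [EnrichmentResult] objects in `metadata(...)$results` and the
#'   observed ranking in `metadata(...)$ranked`.
#' @seealso [permutationTest()] for the single-set interface.
#' @export
runPathwayAnalysis <- function(ge, geneSets, snpGeneMap, k = 1000,
                               seed = 1, weightP = 1,
                               statistic = c("mlog10p", "chisq"),
                               useCovariates = TRUE,
                               mode = c("phenotype", "gene"),
                               adjustBH = FALSE) {
    statistic <- match.arg(statistic)
    mode <- match.arg(mode)
    stopifnot(methods::is(ge, "GenotypeExperiment"))
    if (!is.list(geneSets) || length(geneSets) == 0L ||
        is.null(names(geneSets)) || any(names(geneSets) == ""))
        stop("geneSets must be a non-empty named list of gene id vectors")
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("k must be >= 1")
    seed <- as.integer(seed)

    obs <- .observedPipeline(ge, snpGeneMap, statistic, useCovariates)
    rankedIds <- obs$ranked@stats$geneId
    N <- length(rankedIds)

    observed <- lapply(geneSets, function(s)
        enrichmentScore(obs$ranked, s, weightP = weightP))

    # gene-level objects in the (stable) unranked order used per permutation
    geneLevels <- obs$stats$geneId
    # membership masks over the *current* gene universe; genes may drop out
    # in a permutation (all SNPs flagged), handled by recomputing the
    # statistics from scratch each time below.
    d <- dosage(ge)
    status <- caseStatus(ge)
    cd <- SummarizedExperiment::colData(ge)
    have <- intersect(c("age", "sex"), colnames(cd))
    cm <- .covariateMatrix(
        if (useCovariates && length(have))
            as.data.frame(cd[, have, drop = FALSE]) else NULL, ncol(d))
    prep <- .genePrep(rownames(d), snpGeneMap)
    dt <- t(d)

    permEs <- matrix(NA_real_, nrow = k, ncol = length(geneSets),
                     dimnames = list(NULL, names(geneSets)))
    withSeed(deriveSeed(seed, "permutations"), {
        if (mode == "phenotype") {
            y <- as.numeric(status)
            for (i in seq_len(k)) {
                yp <- sample(y)
                fit <- .waldScanCpp(dt, yp, cm)
                p <- 2 * stats::pnorm(-abs(fit[, 1L] / fit[, 2L]))
                p[fit[, 4L] != 0] <- NA_real_
                pmin <- .geneMinP(p, prep$split)
                ok <- !is.na(pmin)
                r <- .rankStat(pmin[ok], statistic)
                ids <- prep$geneLevels[ok]
                ord <- orderRadix(-r, ids)
                membership <- lapply(geneSets, function(s) ids %in% s)
                permEs[i, ] <- .esManySets(r, ord, membership, weightP)
            }
        } else {
            rObs <- obs$ranked@stats$r
            for (i in seq_len(k)) {
                permEs[i, ] <- vapply(observed, function(o) {
                    hit <- logical(N)
                    hit[sample.int(N, o$nS)] <- TRUE
                    .esCore(rObs, hit, weightP)$es
                }, numeric(1))
            }
        }
    })

    results <- lapply(seq_along(geneSets), function(j) {
        o <- observed[[j]]
        pe <- permEs[, j]
        methods::new("EnrichmentResult",
            setName = names(geneSets)[j],
            es = o$es,
            nes = o$es / mean(pe[pe > 0]),
            nominalP = mean(pe >= o$es),
            runningSum = unname(o$runningSum),
            leadingEdge = o$leadingEdge,
            permEs = unname(pe),
            nS = as.integer(o$nS),
            nGenes = as.integer(N),
            weightP = weightP, k = k, seed = seed)
    })
    names(results) <- names(geneSets)

    out <- S4Vectors::DataFrame(
        set = names(geneSets),
        nS = vapply(results, function(x) x@nS, integer(1)),
        es = vapply(results, function(x) x@es, numeric(1)),
        nes = vapply(results, function(x) x@nes, numeric(1)),
        nominalP = vapply(results, function(x) x@nominalP, numeric(1)),
        k = k, seed = seed, row.names = names(geneSets))
    if (adjustBH)
        out$pBH <- stats::p.adjust(out$nominalP, method = "BH")
    S4Vectors::metadata(out) <- list(results = results, ranked = obs$ranked,
                                     scan = obs$scan, geneSets = geneSets)
    out
}

#' Phenotype-permutation enrichment test for one pathway
#'
#' Single-set convenience wrapper around [runPathwayAnalysis()]: permutes
#' the case/control labels `k` times, recomputing the association scan,
#' gene statistics, ranking and enrichment score for every permutation.
#'
#' @inheritParams runPathwayAnalysis
#' @param geneSet character vector of member gene ids, or a named list of
#'   length one.
#' @param setName label for the set (default `"set"`).
#' @return An [EnrichmentResult].
#' @export
permutationTest <- function(ge, geneSet, snpGeneMap, k = 1000, seed = 1,
                            weightP = 1,
                            statistic = c("mlog10p", "chisq"),
                            useCovariates = TRUE, setName = "set") {
    if (is.list(geneSet)) {
        if (length(geneSet) != 1L)
            stop("permutationTest takes a single gene set")
        setName <- names(geneSet) %||% setName
        geneSet <- geneSet[[1L]]
    }
    sets <- stats::setNames(list(geneSet), setName)
    tab <- runPathwayAnalysis(ge, sets, snpGeneMap, k = k, seed = seed,
                              weightP = weightP, statistic = statistic,
                              useCovariates = useCovariates)
    S4Vectors::metadata(tab)$results[[1L]]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult for set '", object@setName, "'\n", sep = "")
    cat(sprintf("  ES = %.4f  NES = %.3f  nominal p = %s  (K = %d)\n",
                object@es, object@nes,
                formatPermP(object@nominalP, object@k), object@k))
    cat("  set size in list:", object@nS, "of", object@nGenes, "genes\n")
    le <- object@leadingEdge
    cat("  leading edge (", length(le), "): ",
        paste(utils::head(le, 10L), collapse = ", "),
        if (length(le) > 10L) ", ..." else "", "\n", sep = "")
})

#' Format a permutation p-value
#'
#' A permutation p of exactly zero is reported as below the resolution of
#' the permutation count, e.g. `"<0.001"` for K = 1000.
#'
#' @param p nominal permutation p-value.
#' @param k number of permutations.
#' @return Character scalar.
#' @export
formatPermP <- function(p, k) {
    if (is.na(p)) return("NA")
    if (p == 0) sprintf("<%.3g", 1 / k) else sprintf("%.4g", p)
}
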