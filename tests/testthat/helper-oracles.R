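# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the package's own code paths.

# Literal cumulative-loop enrichment score: walks the ranked list one gene
# at a time, recomputing the hit normaliser from scratch at every step.
bruteEnrichmentScore <- function(r, isHit, weightP = 1) {
    N <- length(r)
    nS <- sum(isHit)
    nR <- 0
    for (j in seq_len(N)) if (isHit[j]) nR <- nR + abs(r[j])^weightP
    if (nR == 0) {
        # degenerate all-zero member statistics: equal weights
        cum <- numeric(N); acc <- 0
        for (j in seq_len(N)) {
            acc <- acc + if (isHit[j]) 1 / nS else -1 / (N - nS)
            cum[j] <- acc
        }
    } else {
        cum <- numeric(N); acc <- 0
        for (j in seq_len(N)) {
            acc <- acc + if (isHit[j]) abs(r[j])^weightP / nR
                         else -1 / (N - nS)
            cum[j] <- acc
        }
    }
    list(es = max(max(cum), 0), cum = cum)
}

# Exact HWE p by direct enumeration with exact binomial coefficients:
# P(het | n, nA) = C(n; nmm, nhet, nMM) * 2^nhet / C(2n, nA).
bruteHweExact <- function(nMinorHom, nHet, nMajorHom) {
    n <- nMinorHom + nHet + nMajorHom
    nA <- 2 * nMinorHom + nHet
    if (nA > n) nA <- 2 * n - nA
    if (nA == 0) return(1)
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    pr <- vapply(hets, function(h) {
        mm <- (nA - h) / 2
        MM <- n - mm - h
        exp(lchoose(n, mm) + lchoose(n - mm, h) + h * log(2) -
            lchoose(2 * n, nA))
    }, numeric(1))
    pObs <- pr[match(nHet, hets)]
    sum(pr[pr <= pObs * (1 + 1e-10)])
}

# Random ranked-list / gene-set instance for property tests.
randomEsInstance <- function(maxN = 50) {
    N <- sample(3:maxN, 1)
    r <- sort(round(runif(N, 0, 5), 3), decreasing = TRUE)
    nS <- sample(seq_len(N - 1), 1)
    hit <- logical(N)
    hit[sample.int(N, nS)] <- TRUE
    list(r = r, hit = hit, N = N, nS = nS)
}

# Build a RankedGeneList directly from r values (largest first).
makeRanked <- function(r, ids = sprintf("g%02d", seq_along(r))) {
    rankGenes(S4Vectors::DataFrame(geneId = ids,
                                   bestSnp = NA_character_,
                                   pMin = 10^(-r), r = r))
}

# The 5-SNP QC fixture: one SNP at call rate 0.5, one monomorphic, one at
# MAF 0.005 (below threshold), two clean. 200 subjects.
qcFixture <- function() {
    n <- 200
    d <- rbind(
        lowCall = c(rep(NA_real_, 100), rbinom(100, 2, 0.3)),
        mono    = rep(0, n),
        rare    = c(rep(1, 2), rep(0, n - 2)),          # maf 2/400 = 0.005
        clean1  = rbinom(n, 2, 0.25),
        clean2  = rbinom(n, 2, 0.40))
    # guard against the random draws being degenerate
    d["clean1", 1:40] <- rep(c(0, 1, 2, 1), 10)
    d["clean2", 1:40] <- rep(c(0, 1, 2, 0), 10)
    GenotypeExperiment(d)
}

# glm-based reference for a single-SNP Wald fit (independent of the
# package's IRLS code).
glmWald <- function(dosage, status, covariates = NULL) {
    keep <- !is.na(dosage)
    df <- data.frame(y = status[keep], d = dosage[keep])
    if (!is.null(covariates))
        df <- cbind(df, as.data.frame(covariates)[keep, , drop = FALSE])
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    cf <- summary(fit)$coefficients
    list(beta = cf["d", 1], se = cf["d", 2], p = cf["d", 4])
}
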