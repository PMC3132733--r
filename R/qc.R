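#' SNP quality control
#'
#' Per-SNP quality control for case-control genotype data: genotype
#' counting, call rate, minor allele frequency, the Hardy-Weinberg exact
#' test, and the combined filter [applyQc()]. The default thresholds
#' discard SNPs with call rate below 90%, HWE exact p below 1e-7, or MAF
#' below 0.01 in the total sample; values exactly at a threshold are
#' retained.
#'
#' @name qc
NULL

#' Quality-control thresholds
#'
#' @param minCallRate minimum call rate to retain a SNP (default 0.90).
#' @param hwePFloor minimum Hardy-Weinberg exact p to retain (default 1e-7).
#' @param minMaf minimum minor allele frequency to retain (default 0.01).
#' @return A [QcThresholds] object.
#' @export
qcThresholds <- function(minCallRate = 0.90, hwePFloor = 1e-7,
                         minMaf = 0.01) {
    methods::new("QcThresholds", minCallRate = minCallRate,
                 hwePFloor = hwePFloor, minMaf = minMaf)
}

#' Genotype counts for one SNP
#'
#' Tallies a dosage vector into the four genotype classes used by the QC
#' statistics.
#'
#' @param d numeric vector of minor-allele dosages (0/1/2, `NA` missing).
#' @return Named integer vector with elements `nMinorHom`, `nHet`,
#'   `nMajorHom`, `nMissing`.
#' @examples
#' genotypeCounts(c(0, 0, 1, 2, NA))
#' @export
genotypeCounts <- function(d) {
    c(nMinorHom = sum(d == 2, na.rm = TRUE),
      nHet      = sum(d == 1, na.rm = TRUE),
      nMajorHom = sum(d == 0, na.rm = TRUE),
      nMissing  = sum(is.na(d)))
}

.countsTotal <- function(counts) {
    counts <- .asCounts(counts)
    sum(counts)
}

# Accept either the named vector from genotypeCounts() or a plain
# length-4 vector in the same order.
.asCounts <- function(counts) {
    if (length(counts) != 4L || anyNA(counts) || any(counts < 0))
        stop("genotype counts must be 4 non-negative values ",
             "(nMinorHom, nHet, nMajorHom, nMissing)", call. = FALSE)
    as.integer(counts)
}

#' Call rate of a SNP
#'
#' Fraction of subjects with a non-missing genotype call.
#'
#' @param counts genotype counts as returned by [genotypeCounts()].
#' @return Proportion in \[0, 1\].
#' @examples
#' callRate(c(10, 10, 70, 10))  # 0.90
#' @export
callRate <- function(counts) {
    counts <- .asCounts(counts)
    total <- sum(counts)
    if (total == 0L) stop("no subjects: all four counts are zero")
    (total - counts[4L]) / total
}

#' Minor allele frequency
#'
#' Frequency of the minor allele among non-missing genotypes. If the
#' computed frequency exceeds 0.5 the allele labels are assumed swapped and
#' the complement is returned with attribute `swapped = TRUE`.
#'
#' @inheritParams callRate
#' @return Frequency in \[0, 0.5\] with logical attribute `swapped`.
#' @examples
#' minorAlleleFreq(c(25, 50, 25, 0))  # 0.5
#' minorAlleleFreq(c(2, 17, 681, 0))  # 21/1400
#' @export
minorAlleleFreq <- function(counts) {
    counts <- .asCounts(counts)
    nObs <- sum(counts[1:3])
    if (nObs == 0L) stop("all genotypes missing: MAF undefined")
    f <- (2 * counts[1L] + counts[2L]) / (2 * nObs)
    swapped <- f > 0.5
    if (swapped) f <- 1 - f
    structure(unname(f), swapped = swapped)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions. Given the number
#' of subjects and the minor-allele count, the probability of every
#' possible heterozygote count is evaluated under the null, and the
#' p-value is the sum of probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed count (two-sided,
#' probability ordering). Monomorphic SNPs have a single possible outcome
#' and p = 1.
#'
#' @inheritParams callRate
#' @return p-value in (0, 1\].
#' @examples
#' hweExactTest(c(0, 2, 0, 0))  # 1.0
#' hweExactTest(c(1, 0, 1, 0))  # 1/3
#' @export
hweExactTest <- function(counts) {
    counts <- .asCounts(counts)
    n <- sum(counts[1:3])
    if (n == 0L) stop("all genotypes missing: HWE test undefined")
    nA <- 2L * counts[1L] + counts[2L]          # minor allele copies
    if (nA > n) {                               # labels swapped; symmetric
        nA <- 2L * n - nA
    }
    if (nA == 0L) return(1.0)
    hets <- seq(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
    # log P(het | n, nA) up to a constant: multinomial x 2^het
    lp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
        lfactorial(n - (nA + hets) / 2)
    lp <- lp - max(lp)
    pr <- exp(lp) / sum(exp(lp))
    obs <- counts[2L]
    pObs <- pr[match(obs, hets)]
    if (is.na(pObs))
        stop("inconsistent genotype counts: impossible heterozygote count")
    min(1, sum(pr[pr <= pObs * (1 + 1e-10)]))
}

#' Apply SNP quality-control filters
#'
#' Retains a SNP iff call rate >= `minCallRate` AND Hardy-Weinberg exact
#' p >= `hwePFloor` AND minor allele frequency >= `minMaf`, with all
#' statistics computed on non-missing genotypes in the total sample. The
#' filters commute: applying them in any order yields the same retained
#' set. SNPs whose raw coding turns out to count the major allele (freq >
#' 0.5) are re-coded to minor-allele dosage in the returned object.
#'
#' @param ge a [GenotypeExperiment].
#' @param thresholds a [QcThresholds] (defaults: 0.90, 1e-7, 0.01).
#' @return A list with elements `genotypes` (the filtered, minor-coded
#'   [GenotypeExperiment]) and `report` (a [QcReport]).
#' @examples
#' ge <- simulateGenotypes(simulationConfig(
#'     nSubjects = 100, snpMafs = c(rs1 = 0.3, rs2 = 0.005), seed = 1))
#' applyQc(ge)$report
#' @export
applyQc <- function(ge, thresholds = qcThresholds()) {
    stopifnot(methods::is(ge, "GenotypeExperiment"),
              methods::is(thresholds, "QcThresholds"))
    methods::validObject(thresholds)
    d <- dosage(ge)
    m <- nrow(d)
    if (m == 0L) {
        rep0 <- methods::new("QcReport", nInput = 0L, nFailCallRate = 0L,
            nFailHwe = 0L, nFailMaf = 0L, nPass = 0L,
            perSnp = S4Vectors::DataFrame(snp = character(),
                callRate = numeric(), maf = numeric(), hweP = numeric(),
                pass = logical(), reason = character()),
            thresholds = thresholds)
        return(list(genotypes = ge, report = rep0))
    }
    cr <- maf <- hwe <- numeric(m)
    swapped <- logical(m)
    for (i in seq_len(m)) {
        cts <- genotypeCounts(d[i, ])
        cr[i] <- callRate(cts)
        if (sum(cts[1:3]) == 0L) {           # nothing observed
            maf[i] <- NA_real_; hwe[i] <- NA_real_
            next
        }
        f <- minorAlleleFreq(cts)
        maf[i] <- f
        swapped[i] <- attr(f, "swapped")
        hwe[i] <- hweExactTest(cts)
    }
    failCr <- cr < thresholds@minCallRate
    failHwe <- !is.na(hwe) & hwe < thresholds@hwePFloor
    failMaf <- !is.na(maf) & maf < thresholds@minMaf
    failMaf <- failMaf | is.na(maf)          # fully missing SNP cannot pass
    pass <- !(failCr | failHwe | failMaf)
    reason <- vapply(seq_len(m), function(i) {
        paste(c("call_rate", "hwe", "maf")[c(failCr[i], failHwe[i],
                                             failMaf[i])], collapse = ",")
    }, character(1))
    report <- methods::new("QcReport",
        nInput = m,
        nFailCallRate = sum(failCr),
        nFailHwe = sum(failHwe),
        nFailMaf = sum(failMaf),
        nPass = sum(pass),
        perSnp = S4Vectors::DataFrame(snp = rownames(d), callRate = cr,
            maf = maf, hweP = hwe, pass = pass, reason = reason),
        thresholds = thresholds)
    out <- ge[pass, ]
    if (any(swapped & pass)) {
        dd <- dosage(out)
        sw <- swapped[pass]
        dd[sw, ] <- 2 - dd[sw, ]
        SummarizedExperiment::assay(out, "dosage") <- dd
    }
    SummarizedExperiment::rowData(out)$maf <- maf[pass]
    SummarizedExperiment::rowData(out)$callRate <- cr[pass]
    SummarizedExperiment::rowData(out)$hweP <- hwe[pass]
    list(genotypes = out, report = report)
}

setMethod("show", "QcReport", function(object) {
    cat("QcReport:", object@nInput, "SNPs in,", object@nPass, "retained\n")
    cat(sprintf("  fail call rate < %g : %d\n",
                object@thresholds@minCallRate, object@nFailCallRate))
    cat(sprintf("  fail HWE p < %g     : %d\n",
                object@thresholds@hwePFloor, object@nFailHwe))
    cat(sprintf("  fail MAF < %g       : %d\n",
                object@thresholds@minMaf, object@nFailMaf))
})
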