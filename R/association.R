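#' Case-control association testing
#'
#' Per-SNP association by Wald test in an additive-coded logistic
#' regression (`status ~ dosage + age + sex`), fitted by maximum
#' likelihood on the subjects with a non-missing genotype at that SNP.
#' The per-allele odds ratio is `exp(beta)` and its 95% CI is
#' `exp(beta -/+ 1.959964 * se)`.
#'
#' @name association
NULL

.Z975 <- stats::qnorm(0.975)
.CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)   # 0.4549364

# Drop covariate columns that are constant (they carry no information and
# make the weighted normal equations singular).
.covariateMatrix <- function(covariates, n) {
    if (is.null(covariates))
        return(matrix(numeric(0), nrow = n, ncol = 0))
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    if (nrow(cm) != n)
        stop("covariates must have one row per subject", call. = FALSE)
    if (anyNA(cm))
        stop("covariates must not contain missing values", call. = FALSE)
    keep <- apply(cm, 2L, function(x) diff(range(x)) > 0)
    cm[, keep, drop = FALSE]
}

.scanToFrame <- function(fit, snpIds, d) {
    beta <- fit[, 1L]; se <- fit[, 2L]
    code <- as.integer(fit[, 4L])
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
    flagged <- code != 0L
    p[flagged] <- NA_real_
    maf <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(maf, 1 - maf)
    S4Vectors::DataFrame(
        snp = snpIds,
        beta = beta, se = se, waldZ = z, p = p,
        oddsRatio = exp(beta),
        ciLow = exp(beta - .Z975 * se),
        ciHigh = exp(beta + .Z975 * se),
        maf = maf,
        nUsed = as.integer(fit[, 3L]),
        flagged = flagged,
        flagReason = c("", "monomorphic", "separation")[code + 1L],
        row.names = snpIds)
}

#' Wald test for one SNP
#'
#' Fits `status ~ intercept + dosage (+ covariates)` by maximum-likelihood
#' logistic regression on subjects with a non-missing dosage, and tests
#' the dosage coefficient with the Wald statistic `z = beta / se`.
#'
#' @param dosage numeric vector of minor-allele counts (0/1/2, `NA`
#'   missing), one per subject.
#' @param status integer vector, 0 = control / 1 = case, no missing.
#' @param covariates optional matrix or data.frame of numeric covariates
#'   (e.g. age and sex), one row per subject; constant columns are dropped.
#' @return One-row `DataFrame` with `beta`, `se`, `waldZ`, `p`,
#'   `oddsRatio`, `ciLow`, `ciHigh`, `maf`, `nUsed`, `flagged`,
#'   `flagReason`. Complete separation or non-convergence is flagged
#'   (`p = NA`) rather than silently reported.
#' @examples
#' # 2x2 table: 30/70 exposed among cases, 10/90 among controls
#' d <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
#' y <- rep(c(1, 0), c(100, 100))
#' waldTest(d, y)$oddsRatio  # 27/7
#' @export
waldTest <- function(dosage, status, covariates = NULL) {
    dosage <- as.numeric(dosage)
    status <- as.integer(status)
    n <- length(dosage)
    if (length(status) != n)
        stop("dosage and status lengths differ")
    if (anyNA(status) || !all(status %in% c(0L, 1L)))
        stop("status must be 0/1 with no missing values")
    obs <- !is.na(dosage)
    if (sum(status[obs] == 1L) < 2L || sum(status[obs] == 0L) < 2L)
        stop("need at least 2 cases and 2 controls with observed dosage")
    if (diff(range(dosage[obs])) == 0)
        stop("monomorphic SNP: dosage constant among non-missing subjects")
    cm <- .covariateMatrix(covariates, n)
    fit <- .waldScanCpp(matrix(dosage, ncol = 1L), as.numeric(status), cm)
    .scanToFrame(fit, "snp", matrix(dosage, nrow = 1L))[, -1L]
}

#' Association scan over all SNPs
#'
#' Runs [waldTest()] for every SNP of a (QC-passed) [GenotypeExperiment].
#' Subjects with a missing genotype are dropped per SNP. Monomorphic SNPs
#' and fits with suspected complete separation are flagged (their `p` is
#' `NA`) so that downstream gene statistics can exclude them. Output rows
#' are in input SNP order.
#'
#' @param ge a [GenotypeExperiment].
#' @param status optional 0/1 labels; defaults to `colData(ge)$status`.
#' @param covariates optional covariate matrix/data.frame; defaults to the
#'   `age` and `sex` columns of `colData(ge)` when present. Pass `NULL`
#'   explicitly via `useCovariates = FALSE` to fit without covariates.
#' @param useCovariates logical; fit age/sex covariates when available.
#' @return `DataFrame` with one row per SNP (see [waldTest()] for columns).
#' @export
associationScan <- function(ge, status = NULL, covariates = NULL,
                            useCovariates = TRUE) {
    stopifnot(methods::is(ge, "GenotypeExperiment"))
    d <- dosage(ge)
    n <- ncol(d)
    if (is.null(status)) {
        status <- caseStatus(ge)
        if (is.null(status))
            stop("no 'status' column in colData(ge) and none supplied")
    } else if (!is.null(names(status))) {
        if (!setequal(names(status), colnames(d)))
            stop("subject ids of status do not match the genotypes")
        status <- status[colnames(d)]
    }
    status <- as.integer(status)
    if (length(status) != n || anyNA(status) ||
        !all(status %in% c(0L, 1L)))
        stop("status must be 0/1 for every subject")
    if (length(unique(status)) < 2L)
        stop("status is constant: cannot run a case-control scan")
    if (is.null(covariates) && useCovariates) {
        cd <- SummarizedExperiment::colData(ge)
        have <- intersect(c("age", "sex"), colnames(cd))
        if (length(have))
            covariates <- as.data.frame(cd[, have, drop = FALSE])
    }
    if (!is.null(covariates) && !is.null(rownames(covariates)) &&
        nrow(covariates) == n && !setequal(rownames(covariates),
                                           colnames(d)))
        stop("subject ids of covariates do not match the genotypes")
    cm <- .covariateMatrix(if (useCovariates) covariates else NULL, n)
    if (nrow(d) == 0L)
        return(.scanToFrame(matrix(numeric(0), ncol = 4L), character(0),
                            d))
    fit <- .waldScanCpp(t(d), as.numeric(status), cm)
    .scanToFrame(fit, rownames(d), d)
}

#' Genomic control
#'
#' Converts two-sided p-values to 1-df chi-square statistics, estimates
#' the inflation factor `lambda = median(chisq) / 0.4549364`, and — when
#' `lambda > 1` — deflates every statistic by `lambda` before converting
#' back to p-values. When `lambda <= 1` the p-values are returned
#' unchanged (no correction is applied for deflation), which is standard
#' genomic-control practice.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return List with `lambda` (the inflation factor) and `adjustedP`.
#' @examples
#' p <- stats::pchisq(2 * stats::qchisq(stats::runif(100), 1), 1,
#'                    lower.tail = FALSE)
#' genomicControl(p)$lambda  # ~2
#' @export
genomicControl <- function(pvalues) {
    pvalues <- as.numeric(pvalues)
    if (length(pvalues) == 0L)
        stop("empty p-value list")
    if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
        stop("p-values must lie in (0, 1]")
    chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
    lambda <- stats::median(chisq) / .CHISQ1_MEDIAN
    adjusted <- if (lambda > 1)
        stats::pchisq(chisq / lambda, df = 1, lower.tail = FALSE)
    else pvalues
    list(lambda = lambda, adjustedP = adjusted)
}
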