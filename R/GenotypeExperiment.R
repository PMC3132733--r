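#' Construct a GenotypeExperiment
#'
#' Wraps a SNPs-by-subjects minor-allele dosage matrix, optional per-SNP
#' metadata and optional per-subject covariates into a
#' [GenotypeExperiment].
#'
#' @param dosage numeric matrix, SNPs in rows, subjects in columns; entries
#'   0/1/2 count minor alleles, `NA` marks a missing genotype call. Row and
#'   column names become SNP and subject ids (defaults are generated).
#' @param snpInfo `DataFrame` or `data.frame` of per-SNP metadata
#'   (e.g. `chr`, `pos`, `alleleMinor`, `alleleMajor`), one row per SNP.
#' @param subjectInfo `DataFrame` or `data.frame` of per-subject data;
#'   columns `age`, `sex` (0 = female, 1 = male) and `status`
#'   (0 = control, 1 = case) are the ones the pipeline consumes.
#' @return A [GenotypeExperiment].
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 0), nrow = 2,
#'             dimnames = list(c("rs1", "rs2"), NULL))
#' ge <- GenotypeExperiment(d)
#' dosage(ge)
#' @export
GenotypeExperiment <- function(dosage,
                               snpInfo = S4Vectors::DataFrame(),
                               subjectInfo = S4Vectors::DataFrame()) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "double"
    if (is.null(rownames(dosage)))
        rownames(dosage) <- padIds("snp", nrow(dosage))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- padIds("subj", ncol(dosage))
    if (!nrow(snpInfo)) {
        snpInfo <- S4Vectors::DataFrame(row.names = rownames(dosage))
    } else {
        snpInfo <- S4Vectors::DataFrame(snpInfo)
        rownames(snpInfo) <- rownames(dosage)
    }
    if (!nrow(subjectInfo)) {
        subjectInfo <- S4Vectors::DataFrame(row.names = colnames(dosage))
    } else {
        subjectInfo <- S4Vectors::DataFrame(subjectInfo)
        rownames(subjectInfo) <- colnames(dosage)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = snpInfo, colData = subjectInfo)
    methods::new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment Extract the dosage matrix (SNPs x
#'   subjects).
#' @param x a `GenotypeExperiment`.
#' @export
dosage <- function(x) {
    stopifnot(methods::is(x, "GenotypeExperiment"))
    SummarizedExperiment::assay(x, "dosage")
}

#' @describeIn GenotypeExperiment Case/control labels from `colData`
#'   (`status`: 0 = control, 1 = case), or `NULL` when absent.
#' @export
caseStatus <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!("status" %in% colnames(cd))) return(NULL)
    v <- as.integer(cd$status)
    names(v) <- rownames(cd)
    v
}

setMethod("show", "GenotypeExperiment", function(object) {
    d <- dosage(object)
    cat("GenotypeExperiment:", nrow(d), "SNPs x", ncol(d), "subjects\n")
    miss <- mean(is.na(d))
    cat(sprintf("  missing genotype fraction: %.4f\n", miss))
    st <- caseStatus(object)
    if (!is.null(st))
        cat("  cases:", sum(st == 1L, na.rm = TRUE),
            " controls:", sum(st == 0L, na.rm = TRUE), "\n")
    cv <- colnames(SummarizedExperiment::colData(object))
    if (length(cv)) cat("  colData:", paste(cv, collapse = ", "), "\n")
})
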