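#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Genotype container for case-control cohorts
#'
#' `GenotypeExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a single `"dosage"` assay holding minor-allele counts (0, 1, 2 or
#' `NA` for a missing genotype call), SNPs as rows and subjects as columns.
#' Per-SNP metadata (chromosome, position, allele labels, frequencies) lives
#' in `rowData`; per-subject covariates and the case/control label live in
#' `colData` (columns `age`, `sex` coded 0 = female / 1 = male, and `status`
#' coded 0 = control / 1 = case).
#'
#' @slot .  Inherits all slots from `SummarizedExperiment`.
#' @seealso [GenotypeExperiment()], [dosage()], [applyQc()],
#'   [associationScan()]
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'dosage' is required")
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!is.numeric(d))
        return("'dosage' assay must be numeric")
    v <- d[!is.na(d)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
        return("'dosage' values must be 0, 1, 2 or NA")
    TRUE
})

#' Per-SNP quality-control thresholds
#'
#' Holds the three exclusion thresholds applied to every SNP: minimum call
#' rate, Hardy-Weinberg exact-test p-value floor, and minimum minor allele
#' frequency. Boundary values pass: a SNP is discarded only when its
#' statistic is strictly below (call rate, MAF) or strictly below the floor
#' (HWE p).
#'
#' @slot minCallRate numeric; retain SNPs with call rate >= this (default 0.90).
#' @slot hwePFloor numeric; retain SNPs with HWE exact p >= this (default 1e-7).
#' @slot minMaf numeric; retain SNPs with MAF >= this (default 0.01).
#' @seealso [qcThresholds()], [applyQc()]
#' @exportClass QcThresholds
setClass("QcThresholds",
    representation(minCallRate = "numeric", hwePFloor = "numeric",
                   minMaf = "numeric"),
    prototype(minCallRate = 0.90, hwePFloor = 1e-7, minMaf = 0.01))

setValidity("QcThresholds", function(object) {
    v <- c(object@minCallRate, object@hwePFloor, object@minMaf)
    if (length(v) != 3L || anyNA(v) || any(v < 0) || any(v > 1))
        return("all thresholds must be single values in [0, 1]")
    TRUE
})

#' Quality-control report
#'
#' Summarises the outcome of [applyQc()]: how many SNPs entered, how many
#' failed each filter (a SNP failing several filters is tallied once per
#' filter but once overall), and per-SNP statistics with pass flags.
#'
#' @slot nInput integer; SNPs before filtering.
#' @slot nFailCallRate integer; SNPs below the call-rate threshold.
#' @slot nFailHwe integer; SNPs below the HWE p floor.
#' @slot nFailMaf integer; SNPs below the MAF threshold.
#' @slot nPass integer; SNPs surviving all filters.
#' @slot perSnp `DataFrame` with columns `snp`, `callRate`, `maf`, `hweP`,
#'   `pass` and `reason` (comma-separated failing filters, `""` if passed).
#' @slot thresholds the [QcThresholds] applied.
#' @exportClass QcReport
setClass("QcReport",
    representation(nInput = "integer", nFailCallRate = "integer",
                   nFailHwe = "integer", nFailMaf = "integer",
                   nPass = "integer", perSnp = "DataFrame",
                   thresholds = "QcThresholds"))

setValidity("QcReport", function(object) {
    excluded <- sum(!object@perSnp$pass)
    if (object@nPass + excluded != object@nInput)
        return("pass + excluded must equal input SNP count")
    TRUE
})

#' Ranked gene list for enrichment scoring
#'
#' Genes ordered by their association statistic `r` from largest to
#' smallest; `r = -log10(p_min)` of the best SNP in the gene by default.
#' Ties in `r` are broken by gene id ascending, so the order is
#' deterministic.
#'
#' @slot stats `DataFrame` with columns `geneId`, `bestSnp`, `pMin`, `r`,
#'   rows sorted by decreasing `r`.
#' @seealso [rankGenes()], [enrichmentScore()]
#' @exportClass RankedGeneList
setClass("RankedGeneList", representation(stats = "DataFrame"))

setValidity("RankedGeneList", function(object) {
    s <- object@stats
    need <- c("geneId", "bestSnp", "pMin", "r")
    if (!all(need %in% colnames(s)))
        return(paste("stats needs columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(s$geneId))
        return("gene ids must be unique")
    if (nrow(s) > 1 && any(diff(s$r) > 1e-12))
        return("r must be non-increasing")
    TRUE
})

#' Result of a pathway enrichment permutation test
#'
#' Holds the observed weighted running-sum enrichment score, the full
#' running-sum profile, the leading-edge genes (set members ranked at or
#' before the position where the score is attained), the permutation null
#' scores, the nominal p-value and the normalized enrichment score
#' (NES = observed ES / mean of positive permuted ES).
#'
#' @slot setName character; the gene set tested.
#' @slot es numeric; observed enrichment score in \[0, 1\].
#' @slot nes numeric; normalized enrichment score.
#' @slot nominalP numeric; fraction of permuted ES >= observed ES.
#' @slot runningSum numeric; cumulative sum after each ranked gene.
#' @slot leadingEdge character; leading-edge gene ids.
#' @slot permEs numeric; the permuted enrichment scores (length `k`).
#' @slot nS integer; set members present in the ranked list.
#' @slot nGenes integer; total genes in the ranked list.
#' @slot weightP numeric; the weight exponent used.
#' @slot k integer; number of permutations.
#' @slot seed integer; seed that drove the permutation stream.
#' @seealso [permutationTest()], [runPathwayAnalysis()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(setName = "character", es = "numeric", nes = "numeric",
                   nominalP = "numeric", runningSum = "numeric",
                   leadingEdge = "character", permEs = "numeric",
                   nS = "integer", nGenes = "integer", weightP = "numeric",
                   k = "integer", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
    if (length(object@permEs) != object@k)
        return("permEs must have length k")
    if (!is.na(object@nominalP) &&
        (object@nominalP < 0 || object@nominalP > 1))
        return("nominalP must lie in [0, 1]")
    if (!is.na(object@es) && (object@es < -1e-12 || object@es > 1 + 1e-12))
        return("es must lie in [0, 1]")
    TRUE
})

#' Configuration of the synthetic cohort generator
#'
#' Describes one simulated case-control cohort: biallelic SNPs sampled
#' under Hardy-Weinberg equilibrium at given minor-allele frequencies,
#' independent per-entry missingness, Gaussian age, Bernoulli sex, and a
#' logistic disease model with per-minor-allele log-odds effects for a
#' chosen subset of SNPs. Identical configuration and seed give
#' bit-identical output.
#'
#' @slot nSubjects integer >= 2.
#' @slot snpMafs named numeric; minor-allele frequencies in (0, 0.5], names
#'   are the SNP ids.
#' @slot missingRate numeric in \[0, 1); probability a genotype call is missing.
#' @slot effectMap named numeric; per-minor-allele log-odds by SNP id
#'   (absent SNPs have effect 0).
#' @slot baselineLogOdds numeric; intercept of the disease model.
#' @slot ageMean,ageSd numeric; years.
#' @slot sexBalance numeric in (0, 1); probability of male.
#' @slot ageEffect numeric; log-odds per year of age (centred at `ageMean`);
#'   default 0.
#' @slot sexEffect numeric; log-odds for males; default 0.
#' @slot seed integer; master seed.
#' @seealso [simulationConfig()], [simulateGenotypes()], [simulateCohort()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(nSubjects = "integer", snpMafs = "numeric",
                   missingRate = "numeric", effectMap = "numeric",
                   baselineLogOdds = "numeric", ageMean = "numeric",
                   ageSd = "numeric", sexBalance = "numeric",
                   ageEffect = "numeric", sexEffect = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@nSubjects < 2L)
        return("nSubjects must be >= 2")
    m <- object@snpMafs
    if (length(m) == 0L || is.null(names(m)) || anyDuplicated(names(m)))
        return("snpMafs must be non-empty with unique names")
    if (any(m <= 0 | m > 0.5))
        return("every MAF must lie in (0, 0.5]")
    if (object@missingRate < 0 || object@missingRate >= 1)
        return("missingRate must lie in [0, 1)")
    if (object@sexBalance <= 0 || object@sexBalance >= 1)
        return("sexBalance must lie in (0, 1)")
    if (object@ageSd < 0)
        return("ageSd must be >= 0")
    e <- object@effectMap
    if (length(e) && (is.null(names(e)) || !all(names(e) %in% names(m))))
        return("every effectMap SNP must appear in snpMafs")
    TRUE
})

#' Ground-truth annotation for a simulated study
#'
#' The SNP-to-gene assignment, the gene sets, and the name of the set that
#' carries any planted effects, so downstream power and type-I-error checks
#' know the truth.
#'
#' @slot snpGeneMap named character; `snp id -> gene id` (many-to-one).
#' @slot geneSets named list of character vectors.
#' @slot enrichedSetName character; which set holds planted effects.
#' @seealso [simulateAnnotation()], [plantEffects()]
#' @exportClass AnnotationTruth
setClass("AnnotationTruth",
    representation(snpGeneMap = "character", geneSets = "list",
                   enrichedSetName = "character"))

setValidity("AnnotationTruth", function(object) {
    if (is.null(names(object@snpGeneMap)))
        return("snpGeneMap must be named by SNP id")
    if (anyDuplicated(names(object@snpGeneMap)))
        return("each SNP maps to exactly one gene")
    if (length(object@geneSets) && is.null(names(object@geneSets)))
        return("geneSets must be named")
    if (length(object@enrichedSetName) == 1L &&
        !is.na(object@enrichedSetName) &&
        !(object@enrichedSetName %in% names(object@geneSets)))
        return("enrichedSetName must name one of geneSets")
    TRUE
})
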