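#' Synthetic case-control cohorts with known truth
#'
#' The generator emulates the data a pathway-based case-control GWAS
#' consumes: biallelic SNPs drawn independently per subject under
#' Hardy-Weinberg equilibrium (`Binomial(2, MAF)` minor-allele dosage),
#' independent per-entry missingness, Gaussian age and Bernoulli sex
#' covariates, and a logistic disease model with per-minor-allele
#' log-odds effects planted in a designated pathway. No linkage
#' disequilibrium or population structure is simulated.
#'
#' @name synthetic
NULL

#' Create a simulation configuration
#'
#' Defaults describe an elderly case-control cohort: age 69.4 (6.8) years
#' and 42% male, with a balanced baseline disease risk.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param snpMafs numeric vector of minor-allele frequencies in (0, 0.5];
#'   names become the SNP ids (auto-generated when unnamed).
#' @param missingRate per-entry genotype missingness probability in \[0, 1).
#' @param effectMap named numeric of per-minor-allele log-odds effects;
#'   names must be SNP ids from `snpMafs`.
#' @param baselineLogOdds intercept of the logistic disease model.
#' @param ageMean,ageSd age distribution in years.
#' @param sexBalance probability a subject is male.
#' @param ageEffect log-odds per year of age (centred at `ageMean`).
#' @param sexEffect log-odds added for males.
#' @param seed master seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return A [SimulationConfig].
#' @examples
#' cfg <- simulationConfig(200, snpMafs = rep(0.3, 10), seed = 42)
#' @export
simulationConfig <- function(nSubjects, snpMafs, missingRate = 0,
                             effectMap = numeric(0), baselineLogOdds = 0,
                             ageMean = 69.4, ageSd = 6.8,
                             sexBalance = 0.42, ageEffect = 0,
                             sexEffect = 0, seed = 1) {
    if (is.null(names(snpMafs)))
        names(snpMafs) <- padIds("snp", length(snpMafs))
    methods::new("SimulationConfig",
        nSubjects = as.integer(nSubjects), snpMafs = snpMafs,
        missingRate = missingRate, effectMap = effectMap,
        baselineLogOdds = baselineLogOdds, ageMean = ageMean,
        ageSd = ageSd, sexBalance = sexBalance, ageEffect = ageEffect,
        sexEffect = sexEffect, seed = as.integer(seed))
}

# Draw one block of genotypes + covariates + status for `n` subjects.
.drawSubjects <- function(config, n) {
    mafs <- config@snpMafs
    m <- length(mafs)
    d <- matrix(NA_real_, nrow = m, ncol = n,
                dimnames = list(names(mafs), NULL))
    for (i in seq_len(m))
        d[i, ] <- stats::rbinom(n, 2L, mafs[i])
    if (config@missingRate > 0) {
        miss <- matrix(stats::runif(m * n) < config@missingRate, nrow = m)
        d[miss] <- NA_real_
    }
    age <- stats::rnorm(n, config@ageMean, config@ageSd)
    sex <- stats::rbinom(n, 1L, config@sexBalance)
    eta <- rep(config@baselineLogOdds, n)
    eff <- config@effectMap
    if (length(eff)) {
        for (s in names(eff)) {
            ds <- d[s, ]
            ds[is.na(ds)] <- 2 * mafs[s]   # expected dosage, risk model only
            eta <- eta + eff[s] * ds
        }
    }
    eta <- eta + config@ageEffect * (age - config@ageMean) +
        config@sexEffect * sex
    status <- stats::rbinom(n, 1L, stats::plogis(eta))
    list(dosage = d, age = age, sex = sex, status = status)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP's minor-allele dosage is drawn independently per subject as
#' `Binomial(2, MAF)`; entries are then set missing independently with
#' probability `missingRate`. Allele letters (a minor/major pair per SNP)
#' and map positions are attached so the cohort can be written to PLINK
#' PED/MAP files.
#'
#' @param config a [SimulationConfig].
#' @return A [GenotypeExperiment] (no phenotype columns).
#' @export
simulateGenotypes <- function(config) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    withSeed(deriveSeed(config@seed, "genotypes"), {
        m <- length(config@snpMafs)
        n <- config@nSubjects
        d <- matrix(NA_real_, nrow = m, ncol = n,
                    dimnames = list(names(config@snpMafs),
                                    padIds("subj", n)))
        for (i in seq_len(m))
            d[i, ] <- stats::rbinom(n, 2L, config@snpMafs[i])
        if (config@missingRate > 0) {
            miss <- matrix(stats::runif(m * n) < config@missingRate,
                           nrow = m)
            d[miss] <- NA_real_
        }
        alleles <- t(vapply(seq_len(m), function(i)
            sample(c("A", "C", "G", "T"), 2L), character(2)))
        snpInfo <- S4Vectors::DataFrame(
            chr = rep(1L, m),
            pos = seq_len(m) * 1000L,
            alleleMinor = alleles[, 1L],
            alleleMajor = alleles[, 2L],
            mafTrue = unname(config@snpMafs))
        GenotypeExperiment(d, snpInfo = snpInfo)
    })
}

#' Simulate phenotypes and covariates for given genotypes
#'
#' Age is Gaussian, sex Bernoulli, and case/control status Bernoulli with
#' `logit P(case) = baseline + sum(effect * dosage) + ageEffect * (age -
#' ageMean) + sexEffect * sex`. A missing genotype at an effect SNP
#' contributes its expected dosage `2 * MAF` to the risk (the association
#' stage instead drops such subjects per SNP; the two choices are
#' independent).
#'
#' @param ge a [GenotypeExperiment] from [simulateGenotypes()].
#' @param config the [SimulationConfig]; every `effectMap` SNP must exist
#'   in `ge`.
#' @param seed optional seed override (defaults to the config seed).
#' @return `DataFrame` with columns `age`, `sex`, `status`, one row per
#'   subject.
#' @export
simulatePhenotypes <- function(ge, config, seed = config@seed) {
    stopifnot(methods::is(ge, "GenotypeExperiment"),
              methods::is(config, "SimulationConfig"))
    d <- dosage(ge)
    eff <- config@effectMap
    if (length(eff) && !all(names(eff) %in% rownames(d)))
        stop("effect SNP absent from genotypes: ",
             paste(setdiff(names(eff), rownames(d)), collapse = ", "))
    n <- ncol(d)
    withSeed(deriveSeed(seed, "phenotypes"), {
        age <- stats::rnorm(n, config@ageMean, config@ageSd)
        sex <- stats::rbinom(n, 1L, config@sexBalance)
        eta <- rep(config@baselineLogOdds, n)
        for (s in names(eff)) {
            ds <- d[s, ]
            ds[is.na(ds)] <- 2 * config@snpMafs[s]
            eta <- eta + eff[s] * ds
        }
        eta <- eta + config@ageEffect * (age - config@ageMean) +
            config@sexEffect * sex
        status <- stats::rbinom(n, 1L, stats::plogis(eta))
        S4Vectors::DataFrame(age = age, sex = sex,
                             status = as.integer(status),
                             row.names = colnames(d))
    })
}

#' Simulate a complete cohort
#'
#' Genotypes plus phenotypes in one [GenotypeExperiment]. With
#' `fixedCounts = c(cases, controls)` the generator switches to
#' case-control (rejection) sampling: subjects are drawn in blocks from
#' the population model and the first `cases` cases and `controls`
#' controls encountered are kept, mirroring a matched fracture/control
#' design.
#'
#' @param config a [SimulationConfig].
#' @param fixedCounts optional integer vector `c(nCases, nControls)`;
#'   their sum replaces `nSubjects`.
#' @return A [GenotypeExperiment] with `age`, `sex`, `status` in
#'   `colData`.
#' @examples
#' cfg <- simulationConfig(100, snpMafs = rep(0.25, 5), seed = 7)
#' ge <- simulateCohort(cfg)
#' table(caseStatus(ge))
#' @export
simulateCohort <- function(config, fixedCounts = NULL) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    if (is.null(fixedCounts)) {
        ge <- simulateGenotypes(config)
        ph <- simulatePhenotypes(ge, config)
        SummarizedExperiment::colData(ge) <- ph
        return(ge)
    }
    fixedCounts <- as.integer(fixedCounts)
    if (length(fixedCounts) != 2L || any(fixedCounts < 1L))
        stop("fixedCounts must be c(nCases, nControls), both >= 1")
    nCase <- fixedCounts[1L]; nCtrl <- fixedCounts[2L]
    withSeed(deriveSeed(config@seed, "cohort-fixed"), {
        got <- list()
        haveCase <- haveCtrl <- 0L
        guard <- 0L
        while (haveCase < nCase || haveCtrl < nCtrl) {
            guard <- guard + 1L
            if (guard > 10000L)
                stop("rejection sampling failed to fill the design; ",
                     "is the baseline risk too extreme?")
            blk <- .drawSubjects(config, max(64L, nCase + nCtrl))
            keepCase <- which(blk$status == 1L)[
                seq_len(min(nCase - haveCase, sum(blk$status == 1L)))]
            keepCtrl <- which(blk$status == 0L)[
                seq_len(min(nCtrl - haveCtrl, sum(blk$status == 0L)))]
            keep <- c(keepCase, keepCtrl)
            if (length(keep))
                got[[length(got) + 1L]] <- lapply(
                    list(dosage = blk$dosage[, keep, drop = FALSE],
                         age = blk$age[keep], sex = blk$sex[keep],
                         status = blk$status[keep]), identity)
            haveCase <- haveCase + length(keepCase)
            haveCtrl <- haveCtrl + length(keepCtrl)
        }
        d <- do.call(cbind, lapply(got, `[[`, "dosage"))
        colnames(d) <- padIds("subj", ncol(d))
        alleles <- t(vapply(seq_len(nrow(d)), function(i)
            sample(c("A", "C", "G", "T"), 2L), character(2)))
        snpInfo <- S4Vectors::DataFrame(
            chr = rep(1L, nrow(d)), pos = seq_len(nrow(d)) * 1000L,
            alleleMinor = alleles[, 1L], alleleMajor = alleles[, 2L],
            mafTrue = unname(config@snpMafs))
        subjectInfo <- S4Vectors::DataFrame(
            age = unlist(lapply(got, `[[`, "age")),
            sex = unlist(lapply(got, `[[`, "sex")),
            status = as.integer(unlist(lapply(got, `[[`, "status"))),
            row.names = colnames(d))
        GenotypeExperiment(d, snpInfo = snpInfo,
                           subjectInfo = subjectInfo)
    })
}

#' Simulate a SNP-to-gene annotation and gene sets
#'
#' Assigns disjoint consecutive SNP blocks to genes and samples gene sets
#' without replacement from the gene universe; one set is designated as
#' the carrier of any planted effects.
#'
#' @param nGenes number of genes.
#' @param snpsPerGene SNPs assigned to each gene.
#' @param setSizes integer vector of gene-set sizes (each <= `nGenes`).
#' @param enrichedSetIndex which set carries planted effects (default 1).
#' @param seed integer seed.
#' @return An [AnnotationTruth].
#' @examples
#' tr <- simulateAnnotation(38, 1, setSizes = 38, seed = 3)
#' length(unique(tr@snpGeneMap))  # 38 genes
#' @export
simulateAnnotation <- function(nGenes, snpsPerGene = 1L, setSizes,
                               enrichedSetIndex = 1L, seed = 1) {
    nGenes <- as.integer(nGenes)
    snpsPerGene <- as.integer(snpsPerGene)
    setSizes <- as.integer(setSizes)
    if (any(setSizes > nGenes))
        stop("a gene set cannot be larger than the gene universe")
    if (any(setSizes < 1L)) stop("set sizes must be >= 1")
    if (enrichedSetIndex < 1L || enrichedSetIndex > length(setSizes))
        stop("enrichedSetIndex out of range")
    withSeed(deriveSeed(seed, "annotation"), {
        genes <- padIds("gene", nGenes)
        snps <- padIds("snp", nGenes * snpsPerGene)
        map <- stats::setNames(rep(genes, each = snpsPerGene), snps)
        setNames_ <- padIds("set", length(setSizes))
        sets <- lapply(setSizes, function(sz) sort(sample(genes, sz)))
        names(sets) <- setNames_
        methods::new("AnnotationTruth", snpGeneMap = map, geneSets = sets,
                     enrichedSetName = setNames_[enrichedSetIndex])
    })
}

#' Plant per-allele effects inside the enriched set
#'
#' Chooses `nCausal` genes from the enriched set and assigns the given
#' per-minor-allele log-odds effect to the first (lowest-id) SNP of each,
#' producing the `effectMap` for [simulationConfig()].
#'
#' @param truth an [AnnotationTruth].
#' @param nCausal number of causal genes.
#' @param effectSize per-minor-allele log-odds (e.g. `log(1.6)`).
#' @param seed integer seed.
#' @return Named numeric vector, SNP id -> log-odds.
#' @export
plantEffects <- function(truth, nCausal, effectSize, seed = 1) {
    stopifnot(methods::is(truth, "AnnotationTruth"))
    set <- truth@geneSets[[truth@enrichedSetName]]
    if (nCausal > length(set))
        stop("more causal genes requested than the enriched set holds")
    withSeed(deriveSeed(seed, "effects"), {
        causal <- sort(sample(set, nCausal))
        snps <- vapply(causal, function(g) {
            s <- names(truth@snpGeneMap)[truth@snpGeneMap == g]
            sort(s)[1L]
        }, character(1))
        stats::setNames(rep(effectSize, nCausal), unname(snps))
    })
}

#' Simulate a full pathway-GWAS study
#'
#' One-call generator combining annotation, effect planting, and cohort
#' simulation, used throughout the package's validation: a gene universe
#' with `snpsPerGene` SNPs per gene, gene sets of the given sizes, and
#' `nCausal` causal genes (each with one planted SNP at `effectSize`
#' log-odds, MAF `causalMaf`) inside the first set. Non-causal SNP MAFs
#' are drawn uniformly from `mafRange`.
#'
#' @param nSubjects subjects (ignored when `fixedCounts` given).
#' @param nGenes gene universe size.
#' @param snpsPerGene SNPs per gene.
#' @param setSizes gene-set sizes (first set is the enriched one).
#' @param nCausal causal genes in the enriched set.
#' @param effectSize per-minor-allele log-odds of each causal SNP.
#' @param causalMaf MAF of causal SNPs.
#' @param mafRange range for background SNP MAFs.
#' @param missingRate genotype missingness.
#' @param fixedCounts optional `c(nCases, nControls)` design.
#' @param seed master seed.
#' @return List with `genotypes` (a [GenotypeExperiment] with phenotypes),
#'   `truth` (the [AnnotationTruth]), `effectMap`, `causalGenes`, and
#'   `config`.
#' @examples
#' st <- simulateStudy(nSubjects = 200, nGenes = 30, setSizes = c(10, 10),
#'                     nCausal = 3, effectSize = log(2), seed = 11)
#' st$causalGenes
#' @export
simulateStudy <- function(nSubjects, nGenes, snpsPerGene = 1L, setSizes,
                          nCausal = 0L, effectSize = 0,
                          causalMaf = 0.3, mafRange = c(0.05, 0.5),
                          missingRate = 0, fixedCounts = NULL, seed = 1) {
    truth <- simulateAnnotation(nGenes, snpsPerGene, setSizes,
                                enrichedSetIndex = 1L, seed = seed)
    effectMap <- if (nCausal > 0L)
        plantEffects(truth, nCausal, effectSize, seed = seed)
    else numeric(0)
    snps <- names(truth@snpGeneMap)
    mafs <- withSeed(deriveSeed(seed, "mafs"),
        stats::runif(length(snps), mafRange[1L], mafRange[2L]))
    names(mafs) <- snps
    mafs[names(effectMap)] <- causalMaf
    cfg <- simulationConfig(
        nSubjects = if (is.null(fixedCounts)) nSubjects
                    else sum(fixedCounts),
        snpMafs = mafs, missingRate = missingRate, effectMap = effectMap,
        seed = seed)
    ge <- simulateCohort(cfg, fixedCounts = fixedCounts)
    causalGenes <- unname(truth@snpGeneMap[names(effectMap)])
    list(genotypes = ge, truth = truth, effectMap = effectMap,
         causalGenes = causalGenes, config = cfg)
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSubjects, "subjects,",
        length(object@snpMafs), "SNPs\n")
    cat(sprintf("  missingRate %.3g; baseline log-odds %.3g; %d effect SNPs\n",
                object@missingRate, object@baselineLogOdds,
                length(object@effectMap)))
    cat(sprintf("  age %.1f (%.1f); P(male) %.2f; seed %d\n",
                object@ageMean, object@ageSd, object@sexBalance,
                object@seed))
})

setMethod("show", "AnnotationTruth", function(object) {
    cat("AnnotationTruth:", length(object@snpGeneMap), "SNPs ->",
        length(unique(object@snpGeneMap)), "genes;",
        length(object@geneSets), "gene sets\n")
    if (length(object@enrichedSetName) && !is.na(object@enrichedSetName))
        cat("  enriched set:", object@enrichedSetName, "(",
            length(object@geneSets[[object@enrichedSetName]]), "genes)\n")
})
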