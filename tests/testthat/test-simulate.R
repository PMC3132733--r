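test_that("identical configuration and seed give bit-identical cohorts", {
    cfg <- simulationConfig(60, snpMafs = runif(20, 0.05, 0.5),
                            missingRate = 0.05,
                            effectMap = c(snp001 = log(1.5)), seed = 99)
    g1 <- simulateCohort(cfg)
    g2 <- simulateCohort(cfg)
    expect_identical(dosage(g1), dosage(g2))
    expect_identical(as.data.frame(SummarizedExperiment::colData(g1)),
                     as.data.frame(SummarizedExperiment::colData(g2)))
    a1 <- simulateAnnotation(30, 2, c(10, 5), seed = 8)
    a2 <- simulateAnnotation(30, 2, c(10, 5), seed = 8)
    expect_identical(a1@snpGeneMap, a2@snpGeneMap)
    expect_identical(a1@geneSets, a2@geneSets)
})

test_that("genotypes follow the binomial HWE model", {
    cfg <- simulationConfig(10000, snpMafs = c(s = 0.5), seed = 3)
    d <- dosage(simulateGenotypes(cfg))[1, ]
    expect_lt(abs(mean(d) / 2 - 0.5), 0.015)
    expect_lt(abs(mean(d == 1) - 0.5), 0.015)
    expect_equal(sum(is.na(d)), 0L)       # missingRate 0 -> nothing missing
})

test_that("missingness hits the configured rate", {
    cfg <- simulationConfig(10000, snpMafs = c(s = 0.3),
                            missingRate = 0.1, seed = 4)
    d <- dosage(simulateGenotypes(cfg))
    expect_lt(abs(mean(is.na(d)) - 0.1), 0.01)
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(100, snpMafs = c(s = 0.6), seed = 1),
                 "MAF")
    expect_error(simulationConfig(100, snpMafs = c(s = 0.3),
                                  missingRate = 1, seed = 1),
                 "missingRate")
    expect_error(simulationConfig(1, snpMafs = c(s = 0.3), seed = 1),
                 "nSubjects")
    expect_error(simulationConfig(100, snpMafs = c(s = 0.3),
                                  effectMap = c(other = 1), seed = 1),
                 "effectMap")
})

test_that("the null disease model yields a balanced case fraction", {
    cfg <- simulationConfig(10000, snpMafs = c(s = 0.3),
                            baselineLogOdds = 0, seed = 5)
    ge <- simulateCohort(cfg)
    expect_lt(abs(mean(caseStatus(ge)) - 0.5), 0.015)
})

test_that("a saturated baseline produces all controls", {
    cfg <- simulationConfig(500, snpMafs = c(s = 0.3),
                            baselineLogOdds = -30, seed = 6)
    expect_true(all(caseStatus(simulateCohort(cfg)) == 0L))
})

test_that("phenotype simulation refuses unknown effect SNPs", {
    cfg <- simulationConfig(50, snpMafs = c(a = 0.3), seed = 7)
    ge <- simulateGenotypes(cfg)
    bad <- methods::new("SimulationConfig", nSubjects = 50L,
        snpMafs = c(a = 0.3, ghost = 0.3),
        missingRate = 0, effectMap = c(ghost = 1), baselineLogOdds = 0,
        ageMean = 69, ageSd = 7, sexBalance = 0.5, ageEffect = 0,
        sexEffect = 0, seed = 7L)
    expect_error(simulatePhenotypes(ge, bad), "absent")
})

test_that("a planted log(2) effect is recovered by the Wald fit", {
    cfg <- simulationConfig(5000, snpMafs = c(s1 = 0.3),
                            effectMap = c(s1 = log(2)), seed = 8)
    ge <- simulateCohort(cfg)
    w <- waldTest(dosage(ge)[1, ], caseStatus(ge))
    expect_gt(w$oddsRatio, 1.7)
    expect_lt(w$oddsRatio, 2.3)
})

test_that("annotation construction matches its contract", {
    tr <- simulateAnnotation(38, 1, setSizes = 38, seed = 9)
    expect_equal(length(tr@snpGeneMap), 38L)
    expect_equal(length(unique(tr@snpGeneMap)), 38L)
    tr2 <- simulateAnnotation(500, 3, setSizes = 38, seed = 10)
    expect_equal(length(tr2@geneSets[[1]]), 38L)
    expect_true(all(tr2@geneSets[[1]] %in% unique(tr2@snpGeneMap)))
    expect_error(simulateAnnotation(10, 1, setSizes = 11, seed = 1),
                 "larger")
})

test_that("planted effects land inside the enriched set", {
    tr <- simulateAnnotation(100, 2, setSizes = c(20, 30), seed = 11)
    eff <- plantEffects(tr, 7, log(1.6), seed = 12)
    genes <- unname(tr@snpGeneMap[names(eff)])
    expect_equal(length(eff), 7L)
    expect_true(all(genes %in% tr@geneSets[[tr@enrichedSetName]]))
    expect_true(all(eff == log(1.6)))
})

test_that("fixed case/control designs hit their quotas exactly", {
    cfg <- simulationConfig(700, snpMafs = runif(10, 0.1, 0.5), seed = 13)
    ge <- simulateCohort(cfg, fixedCounts = c(350, 350))
    st <- caseStatus(ge)
    expect_equal(sum(st == 1L), 350L)
    expect_equal(sum(st == 0L), 350L)
    expect_equal(ncol(dosage(ge)), 700L)
    # deterministic too
    ge2 <- simulateCohort(cfg, fixedCounts = c(350, 350))
    expect_identical(dosage(ge), dosage(ge2))
})

test_that("age and sex covariates can confound when asked to", {
    cfg <- simulationConfig(4000, snpMafs = c(s = 0.3), sexEffect = 1.5,
                            seed = 14)
    ge <- simulateCohort(cfg)
    cd <- SummarizedExperiment::colData(ge)
    bySex <- tapply(cd$status, cd$sex, mean)
    expect_gt(bySex["1"], bySex["0"])
})
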