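test_that("binary-predictor Wald fit equals the 2x2 cross-product OR", {
    d <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
    y <- rep(c(1, 0), c(100, 100))
    w <- waldTest(d, y)
    expect_equal(w$oddsRatio, 27 / 7, tolerance = 1e-6)
    # CI bounds are exp(beta -/+ 1.959964 se)
    expect_equal(w$ciLow, exp(w$beta - qnorm(0.975) * w$se))
    expect_equal(w$ciHigh, exp(w$beta + qnorm(0.975) * w$se))
    expect_equal(w$p, 2 * pnorm(-abs(w$beta / w$se)))
})

test_that("the IRLS fit agrees with glm on random cohorts", {
    set.seed(21)
    for (i in 1:20) {
        n <- 300
        d <- rbinom(n, 2, runif(1, 0.1, 0.5))
        d[sample(n, 15)] <- NA
        age <- rnorm(n, 69, 7); sex <- rbinom(n, 1, 0.45)
        y <- rbinom(n, 1, plogis(-0.1 + 0.25 * ifelse(is.na(d), 0.6, d)))
        w <- waldTest(d, y, cbind(age = age, sex = sex))
        ref <- glmWald(d, y, cbind(age = age, sex = sex))
        # agreement is limited by glm's own deviance-based stopping rule
        expect_equal(w$beta, ref$beta, tolerance = 1e-4)
        expect_equal(w$se, ref$se, tolerance = 1e-4)
        expect_equal(w$p, ref$p, tolerance = 1e-4)
    }
})

test_that("constant (zero-information) covariates do not change the fit", {
    set.seed(22)
    n <- 400
    d <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(0.2 * d))
    plain <- waldTest(d, y)
    withZero <- waldTest(d, y, matrix(0, n, 2))
    expect_equal(plain$beta, withZero$beta)
    expect_equal(plain$se, withZero$se)
})

test_that("degenerate inputs error or flag rather than report a p-value", {
    d <- rbinom(100, 2, 0.3)
    expect_error(waldTest(d, rep(1L, 100)), "cases and 2 controls")
    expect_error(waldTest(rep(1, 100), rbinom(100, 1, 0.5)),
                 "monomorphic")
    # complete separation: dosage perfectly predicts status
    y <- as.integer(d > 0)
    ge <- GenotypeExperiment(matrix(d, nrow = 1,
                                    dimnames = list("sep", NULL)))
    scan <- associationScan(ge, status = y, useCovariates = FALSE)
    expect_true(scan$flagged[1])
    expect_true(is.na(scan$p[1]))
})

test_that("scan output preserves SNP order and flags monomorphic SNPs", {
    set.seed(23)
    d <- rbind(a = rbinom(200, 2, 0.4), mono = rep(1, 200),
               b = rbinom(200, 2, 0.2))
    ge <- GenotypeExperiment(d)
    y <- rbinom(200, 1, 0.5)
    scan <- associationScan(ge, status = y, useCovariates = FALSE)
    expect_equal(scan$snp, c("a", "mono", "b"))
    expect_equal(scan$flagReason[2], "monomorphic")
    expect_false(any(scan$flagged[c(1, 3)]))
    # empty scan
    e <- associationScan(ge[integer(0), ], status = y)
    expect_equal(nrow(e), 0L)
})

test_that("subject-id mismatches are rejected", {
    ge <- GenotypeExperiment(matrix(rbinom(40, 2, 0.4), nrow = 2))
    y <- setNames(rbinom(20, 1, 0.5), paste0("other", 1:20))
    expect_error(associationScan(ge, status = y), "subject ids")
})

test_that("a planted OR = 2 SNP is recovered by the scan", {
    set.seed(24)
    hits <- 0; ors <- numeric(50)
    for (i in 1:50) {
        cfg <- simulationConfig(2000, snpMafs = c(s1 = 0.3),
                                effectMap = c(s1 = log(2)), seed = 100 + i)
        ge <- simulateCohort(cfg)
        scan <- associationScan(ge, useCovariates = FALSE)
        hits <- hits + (scan$p[1] < 0.05)
        ors[i] <- scan$oddsRatio[1]
    }
    expect_gte(hits / 50, 0.8)                 # high power at n = 2000
    expect_gt(median(ors), 1.7); expect_lt(median(ors), 2.3)
})

test_that("null scans give uniform p-values (pipeline calibration)", {
    set.seed(25)
    cfg <- simulationConfig(300, snpMafs = runif(5000, 0.05, 0.5),
                            seed = 31)
    ge <- simulateCohort(cfg)
    scan <- associationScan(ge)
    p <- scan$p[!scan$flagged]
    expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("genomic control matches its definition and is idempotent", {
    chimed <- qchisq(0.5, 1)
    # all statistics at the null median: lambda exactly 1, p unchanged
    p0 <- rep(pchisq(chimed, 1, lower.tail = FALSE), 11)
    gc0 <- genomicControl(p0)
    expect_equal(gc0$lambda, 1.0)
    expect_equal(gc0$adjustedP, p0)
    # uniformly doubled chi-square spectrum: lambda = 2, statistics halved
    set.seed(26)
    chi <- qchisq(runif(1001), 1)
    p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
    gc2 <- genomicControl(p2)
    expect_equal(gc2$lambda, 2 * median(chi) / chimed, tolerance = 1e-12)
    expect_equal(qchisq(gc2$adjustedP, 1, lower.tail = FALSE),
                 2 * chi / gc2$lambda, tolerance = 1e-9)
    # after one adjustment the re-estimated lambda is exactly 1
    expect_equal(genomicControl(gc2$adjustedP)$lambda, 1.0,
                 tolerance = 1e-12)
    # lambda <= 1 leaves p untouched
    pLow <- pchisq(0.5 * chi, 1, lower.tail = FALSE)
    expect_equal(genomicControl(pLow)$adjustedP, pLow)
    expect_error(genomicControl(numeric(0)), "empty")
    expect_error(genomicControl(c(0.5, 0)), "0, 1")
})

test_that("95% CI covers the generating OR at nominal rate", {
    set.seed(27)
    beta <- log(1.5)
    cover <- vapply(1:300, function(i) {
        n <- 600
        d <- rbinom(n, 2, 0.3)
        y <- rbinom(n, 1, plogis(-0.3 + beta * d))
        w <- waldTest(d, y)
        w$ciLow <= exp(beta) && exp(beta) <= w$ciHigh
    }, logical(1))
    expect_gt(mean(cover), 0.92)
    expect_lt(mean(cover), 0.98)
})
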