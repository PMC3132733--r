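test_that("gene statistics take the best SNP with deterministic ties", {
    scan <- S4Vectors::DataFrame(
        snp = c("s1", "s2", "s3", "s4", "s5", "s6"),
        p = c(0.5, 0.01, 0.2, 0.03, 0.03, NA))
    map <- c(s1 = "g1", s2 = "g1", s3 = "g1",
             s4 = "g2", s5 = "g2", s6 = "g3")
    gs <- geneStatistics(scan, map)
    expect_equal(gs$pMin[gs$geneId == "g1"], 0.01)
    expect_equal(gs$r[gs$geneId == "g1"], 2.0)
    # tie at 0.03: lexicographically smaller SNP id wins
    expect_equal(gs$bestSnp[gs$geneId == "g2"], "s4")
    # gene whose only SNP is flagged (p = NA) is omitted
    expect_false("g3" %in% gs$geneId)
    # empty scan -> empty statistics
    expect_equal(nrow(geneStatistics(scan[0, ], map)), 0L)
})

test_that("ranking is decreasing with gene-id tie-break", {
    st <- S4Vectors::DataFrame(geneId = c("a", "b", "c"),
                               bestSnp = NA_character_,
                               pMin = c(0.1, 0.001, 0.01),
                               r = c(1, 3, 2))
    expect_equal(geneIds(rankGenes(st)), c("b", "c", "a"))
    tied <- S4Vectors::DataFrame(geneId = c("z", "m", "a"),
                                 bestSnp = NA_character_,
                                 pMin = 0.1, r = c(1, 1, 1))
    expect_equal(geneIds(rankGenes(tied)), c("a", "m", "z"))
    expect_error(rankGenes(rbind(st, st)), "duplicate")
})

test_that("hand-worked running sums are reproduced exactly", {
    # single member at the top: +3/3 then two misses of 1/2 each
    e1 <- enrichmentScore(makeRanked(c(3, 2, 1), c("g1", "g2", "g3")),
                          "g1")
    expect_equal(e1$es, 1.0)
    expect_equal(unname(e1$runningSum), c(1, 0.5, 0))
    expect_equal(e1$leadingEdge, "g1")

    # members at ranks 1 and 3 of 4: peak 2/3 at position 1
    e2 <- enrichmentScore(makeRanked(4:1, paste0("g", 1:4)),
                          c("g1", "g3"))
    expect_equal(e2$es, 2 / 3)
    expect_equal(unname(e2$runningSum), c(2/3, 1/6, 1/2, 0))
    expect_equal(e2$leadingEdge, "g1")
    expect_equal(e2$peakIndex, 1L)

    # unweighted (p = 0) classic KS: -1/2, +1, -1/2
    e3 <- enrichmentScore(makeRanked(c(3, 2, 1), paste0("g", 1:3)),
                          "g2", weightP = 0)
    expect_equal(e3$es, 0.5)
    expect_equal(unname(e3$runningSum), c(-0.5, 0.5, 0))
})

test_that("enrichment score equals the brute-force loop on random instances", {
    set.seed(31)
    for (i in 1:300) {
        inst <- randomEsInstance(50)
        wp <- sample(c(0, 0.5, 1, 2), 1)
        rl <- makeRanked(inst$r)
        got <- enrichmentScore(rl, geneIds(rl)[inst$hit], weightP = wp)
        ref <- bruteEnrichmentScore(inst$r, inst$hit, wp)
        expect_equal(got$es, ref$es, tolerance = 1e-12)
        expect_equal(unname(got$runningSum), ref$cum, tolerance = 1e-12)
        # closure: hits sum to 1 and misses to 1
        expect_lt(abs(got$runningSum[inst$N]), 1e-10)
        # range
        expect_gte(got$es, 0); expect_lte(got$es, 1 + 1e-12)
    }
})

test_that("enrichment score agrees with fgsea's GSEA statistic", {
    set.seed(32)
    for (i in 1:25) {
        N <- sample(10:40, 1)
        r <- sort(runif(N, 0.01, 5), decreasing = TRUE)
        ids <- sprintf("g%02d", seq_len(N))
        hitIdx <- sort(sample(seq_len(N - 1), sample(2:5, 1)))
        ours <- enrichmentScore(makeRanked(r, ids), ids[hitIdx])$es
        ref <- fgsea::calcGseaStat(setNames(r, ids), hitIdx,
                                   gseaParam = 1, returnAllExtremes = TRUE)
        # fgsea reports the signed max deviation; compare its positive arm
        expect_equal(ours, max(ref$tops), tolerance = 1e-10)
    }
})

test_that("es = 1 exactly iff the set fills the top ranks up to the peak", {
    rl <- makeRanked(c(5, 4, 3, 2, 1))
    expect_equal(enrichmentScore(rl, c("g01", "g02"))$es, 1.0)
    expect_lt(enrichmentScore(rl, c("g01", "g03"))$es, 1.0)
})

test_that("es is invariant to rescaling the statistics", {
    set.seed(33)
    inst <- randomEsInstance(30)
    rl1 <- makeRanked(inst$r)
    rl2 <- makeRanked(inst$r * 37.5)
    s <- geneIds(rl1)[inst$hit]
    expect_equal(enrichmentScore(rl1, s)$es, enrichmentScore(rl2, s)$es,
                 tolerance = 1e-12)
})

test_that("untestable sets are rejected", {
    rl <- makeRanked(c(3, 2, 1))
    expect_error(enrichmentScore(rl, "nope"), "untestable")
    expect_error(enrichmentScore(rl, c("g01", "g02", "g03")), "whole")
    # members absent from the list only shrink the effective set
    e <- enrichmentScore(rl, c("g01", "absent"))
    expect_equal(e$nS, 1L)
})

test_that("permutation results are deterministic and self-consistent", {
    set.seed(34)
    st <- simulateStudy(nSubjects = 150, nGenes = 25, setSizes = c(8, 8),
                        nCausal = 3, effectSize = log(2.5), seed = 17)
    ge <- applyQc(st$genotypes)$genotypes
    sets <- st$truth@geneSets
    t1 <- runPathwayAnalysis(ge, sets, st$truth@snpGeneMap, k = 40,
                             seed = 5)
    t2 <- runPathwayAnalysis(ge, sets, st$truth@snpGeneMap, k = 40,
                             seed = 5)
    expect_identical(as.data.frame(t1), as.data.frame(t2))

    r1 <- S4Vectors::metadata(t1)$results[[1]]
    # nominal p and NES follow their definitions
    expect_equal(r1@nominalP, mean(r1@permEs >= r1@es))
    expect_equal(r1@nes, r1@es / mean(r1@permEs[r1@permEs > 0]))
    expect_equal(length(r1@permEs), 40L)

    # the single-set interface matches the multi-set driver
    single <- permutationTest(ge, sets[1], st$truth@snpGeneMap, k = 40,
                              seed = 5)
    expect_equal(single@es, r1@es)
    expect_equal(single@nominalP, r1@nominalP)
    expect_equal(single@permEs, r1@permEs)
})

test_that("NES scales as observed ES over the permutation mean", {
    res <- methods::new("EnrichmentResult", setName = "s", es = 0.44,
        nes = 0.44 / 0.25, nominalP = 0, runningSum = numeric(3),
        leadingEdge = "g", permEs = rep(0.25, 10), nS = 1L, nGenes = 3L,
        weightP = 1, k = 10L, seed = 1L)
    expect_equal(res@nes, res@es / mean(res@permEs))
    # observed 1.76x the permutation mean -> NES 1.76
    expect_equal(0.44 / 0.25, 1.76)
})

test_that("an observed score below every permuted score gives p = 1", {
    set.seed(35)
    st <- simulateStudy(nSubjects = 120, nGenes = 20, setSizes = 6,
                        seed = 23)
    ge <- applyQc(st$genotypes)$genotypes
    res <- permutationTest(ge, st$truth@geneSets[1],
                           st$truth@snpGeneMap, k = 30, seed = 2)
    if (all(res@permEs >= res@es))
        expect_equal(res@nominalP, 1.0)
    expect_gte(res@nominalP, mean(res@permEs > res@es))
})

test_that("planted pathway signal yields small p and recovers the truth", {
    set.seed(36)
    st <- simulateStudy(nSubjects = 800, nGenes = 60, setSizes = c(15, 15),
                        nCausal = 6, effectSize = log(2), seed = 41)
    ge <- applyQc(st$genotypes)$genotypes
    res <- runPathwayAnalysis(ge, st$truth@geneSets,
                              st$truth@snpGeneMap, k = 100, seed = 3)
    enriched <- S4Vectors::metadata(res)$results[[st$truth@enrichedSetName]]
    expect_lte(enriched@nominalP, 0.05)
    expect_gte(length(intersect(enriched@leadingEdge, st$causalGenes)), 4L)
})

test_that("the fast gene-relabelling mode approximates the null", {
    set.seed(37)
    st <- simulateStudy(nSubjects = 150, nGenes = 40, setSizes = 10,
                        seed = 29)
    ge <- applyQc(st$genotypes)$genotypes
    res <- runPathwayAnalysis(ge, st$truth@geneSets,
                              st$truth@snpGeneMap, k = 100, seed = 4,
                              mode = "gene")
    expect_true(res$nominalP >= 0 && res$nominalP <= 1)
})
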