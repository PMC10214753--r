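mkProf <- function(pos, ref, alt) {
    data.frame(pos = pos, ref = ref, alt = alt, kind = "SNV", hp = 1L)
}
noVar <- data.frame(pos = integer(), ref = character(), alt = character(),
                    kind = character(), hp = integer())

test_that("pooled allele frequencies count reads equally and suppress below threshold", {
    ## every read carries the alternate -> frequency 1.0
    af <- pooledAlleleFrequencies(replicate(10, mkProf(4L, "A", "G"),
                                            simplify = FALSE))
    expect_equal(af$frequency, 1.0)
    expect_equal(af$pos, 5L)          # 1-based export

    ## 40 alt / 100 reads -> 0.4
    profs <- c(replicate(40, mkProf(4L, "A", "G"), simplify = FALSE),
               replicate(60, noVar, simplify = FALSE))
    af2 <- pooledAlleleFrequencies(profs)
    expect_equal(af2$altCount, 40L)
    expect_equal(af2$depth, 100L)
    expect_equal(af2$frequency, 0.4)

    ## 8 alt / 16000 reads = 0.0005 < 0.005 -> suppressed
    profs3 <- c(replicate(8, mkProf(4L, "A", "G"), simplify = FALSE),
                replicate(15992, noVar, simplify = FALSE))
    expect_equal(nrow(pooledAlleleFrequencies(profs3)), 0L)

    ## multi-allelic sites split into biallelic rows
    profs4 <- c(replicate(30, mkProf(4L, "A", "G"), simplify = FALSE),
                replicate(20, mkProf(4L, "A", "T"), simplify = FALSE),
                replicate(50, noVar, simplify = FALSE))
    af4 <- pooledAlleleFrequencies(profs4)
    expect_equal(nrow(af4), 2L)
    expect_setequal(af4$frequency, c(0.3, 0.2))
})

test_that("raising the suppression threshold never adds sites", {
    set.seed(31)
    profs <- lapply(1:400, function(i) {
        if (runif(1) < 0.5) noVar
        else mkProf(sample(0:50, 1), "A", sample(c("C", "G", "T"), 1))
    })
    thresholds <- c(0.001, 0.005, 0.02, 0.1, 0.5)
    counts <- vapply(thresholds, function(t)
        nrow(pooledAlleleFrequencies(profs, minAltFraction = t)),
        integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("TSR haplotype frequency is the sum over carrier clusters", {
    guide <- as.character(miniRef()$guide)
    profs <- hapProfiles()
    corrected <- c(rep(profs["T1"], 2), rep(profs["T2"], 1),
                   rep(profs["W1"], 17))
    cl <- annotateClusters(formClusters(unname(corrected),
                                        sprintf("r%02d", 1:20), guide),
                           miniRef()$model)
    expect_equal(tsrFrequencyFromClusters(cl, "Ile1781.1Leu_T"), 0.1)
    expect_equal(tsrFrequencyFromClusters(cl, "Gly2096.2Ala_C"), 0)
})

test_that("Pearson correlation matches the closed-form textbook computation", {
    expect_equal(correlateFrequencies(1:5, 1:5)$r, 1)
    expect_equal(correlateFrequencies(1:5, -(1:5))$r, -1)

    x <- c(0.12, 0.55, 0.31, 0.90, 0.44)
    y <- c(0.10, 0.48, 0.40, 0.85, 0.41)
    res <- correlateFrequencies(x, y)
    rOracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tOracle <- rOracle * sqrt(3 / (1 - rOracle^2))
    pOracle <- 2 * stats::pt(-abs(tOracle), df = 3)
    expect_equal(res$r, rOracle, tolerance = 1e-12)
    expect_equal(res$p, pOracle, tolerance = 1e-12)

    z <- correlateFrequencies(c(1, 1, 1), c(1, 2, 3))
    expect_true(z$undefined)
})

test_that("recovery benchmarking counts correct, unidentified and additional TSR pairs", {
    guide <- as.character(miniRef()$guide)
    haps <- miniHaps()
    profs <- hapProfiles()

    ## individuals carry W1, W2, T1; pool recovers W1, W2, W3, T2
    ind <- data.frame(individual = 1:4,
                      hap1 = c("W1", "W1", "W2", "T1"),
                      hap2 = c("W1", "W2", "T1", "W2"))
    corrected <- c(rep(profs["W1"], 10), rep(profs["W2"], 6),
                   rep(profs["W3"], 3), rep(profs["T2"], 5))
    cl <- annotateClusters(formClusters(unname(corrected),
                                        sprintf("r%02d", 1:24), guide),
                           miniRef()$model)
    bm <- benchmarkRecovery(ind, haps, cl, miniRef()$model)
    expect_equal(bm$report$nPoolHaplotypes, 4L)
    expect_equal(bm$report$nIndividualHaplotypes, 3L)
    expect_equal(bm$report$nCorrectPairs, 2L)           # W1, W2
    expect_equal(bm$report$nCorrectTsrPairs, 0L)
    expect_equal(bm$report$nUnidentifiedTsr, 1L)        # T1 missing in pool
    expect_equal(bm$report$nAdditionalTsr, 1L)          # T2 extra in pool
    expect_lte(bm$report$nCorrectPairs,
               min(bm$report$nPoolHaplotypes,
                   bm$report$nIndividualHaplotypes))

    ## identical sets: everything pairs, nothing extra
    ind2 <- data.frame(individual = 1:2, hap1 = c("W1", "W2"),
                       hap2 = c("W1", "T1"))
    corrected2 <- c(rep(profs["W1"], 8), rep(profs["W2"], 4),
                    rep(profs["T1"], 4))
    cl2 <- annotateClusters(formClusters(unname(corrected2),
                                         sprintf("r%02d", 1:16), guide),
                            miniRef()$model)
    bm2 <- benchmarkRecovery(ind2, haps, cl2, miniRef()$model)
    expect_equal(bm2$report$nCorrectPairs, 3L)
    expect_equal(bm2$report$nUnidentifiedTsr, 0L)
    expect_equal(bm2$report$nAdditionalTsr, 0L)

    ## disjoint sets: zero correct pairs
    ind3 <- data.frame(individual = 1, hap1 = "W4", hap2 = "W4")
    bm3 <- benchmarkRecovery(ind3, haps, cl2, miniRef()$model)
    expect_equal(bm3$report$nCorrectPairs, 0L)
})

test_that("the pairing invariant holds on randomized benchmark inputs", {
    guide <- as.character(miniRef()$guide)
    haps <- miniHaps()
    profs <- hapProfiles()
    set.seed(47)
    for (i in 1:15) {
        ids <- names(haps)
        ind <- data.frame(individual = 1:6,
                          hap1 = sample(ids, 6, TRUE),
                          hap2 = sample(ids, 6, TRUE))
        poolIds <- sample(ids, sample(2:6, 1))
        corrected <- unname(unlist(lapply(poolIds, function(h)
            rep(profs[h], sample(2:5, 1))), recursive = FALSE))
        cl <- annotateClusters(
            formClusters(corrected,
                         sprintf("r%03d", seq_along(corrected)), guide),
            miniRef()$model)
        bm <- benchmarkRecovery(ind, haps, cl, miniRef()$model)
        expect_lte(bm$report$nCorrectPairs,
                   min(bm$report$nPoolHaplotypes,
                       bm$report$nIndividualHaplotypes))
        expect_lte(bm$report$nCorrectTsrPairs, bm$report$nCorrectPairs)
    }
})

test_that("recovery stratifies by carrier count", {
    ind <- data.frame(individual = 1:6,
                      hap1 = c("A", "A", "A", "A", "B", "C"),
                      hap2 = c("A", "B", "B", "D", "D", "C"))
    ## carriers: A 4, B 3, C 1, D 2
    rec <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE)
    tab <- recoveryByCarrierCount(ind, rec)
    expect_equal(tab$rate[tab$carriers == ">=4"], 1.0)
    expect_equal(tab$rate[tab$carriers == "2-3"], 0.5)   # B yes, D no
    expect_equal(tab$rate[tab$carriers == "1"], 0.0)

    allRec <- recoveryByCarrierCount(ind, c(A = TRUE, B = TRUE, C = TRUE,
                                            D = TRUE))
    expect_true(all(allRec$rate == 1.0))
    noneRec <- recoveryByCarrierCount(ind, c(A = FALSE, B = FALSE,
                                             C = FALSE, D = FALSE))
    expect_true(all(noneRec$rate == 0.0))
})
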