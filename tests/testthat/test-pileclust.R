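test_that("pool-design parameter derivation reproduces both published designs", {
    p <- derivePoolParameters(200, 16000)
    expect_equal(p@pileSize, 50L)                      # 40 * 1.25
    expect_equal(p@minClusterReadCount, 20L)           # ceil(40 / 2)
    expect_equal(p@minClusterFrequency, 0.00125)
    expect_equal(p@maxAlignmentsPerRead, 16000L)

    p2 <- derivePoolParameters(150, 5300)
    expect_equal(p2@minClusterReadCount, 9L)           # ceil(17.67 / 2)
    expect_equal(signif(p2@minClusterFrequency, 2), 0.0017)
    expect_equal(p2@pileSize, 22L)                     # round(17.67 * 1.25)

    p3 <- derivePoolParameters(1, 2)
    expect_equal(p3@minClusterReadCount, 1L)
    expect_equal(p3@minClusterFrequency, 0.5)
})

test_that("piles take the top-identity reads with deterministic tie-breaking", {
    ## two haplotypes one variant apart, 10 reads each, error-free
    n <- 20L
    profs <- c(replicate(10, data.frame(pos = 5L, ref = "A", alt = "C",
                                        kind = "SNV", hp = 1L),
                         simplify = FALSE),
               replicate(10, data.frame(pos = integer(), ref = character(),
                                        alt = character(),
                                        kind = character(), hp = integer()),
                         simplify = FALSE))
    ids <- sprintf("r%02d", seq_len(n))
    idm <- identityMatrix(profs, guideLength = 1000)

    params <- clusterParams(pileSize = 10, minClusterReadCount = 1,
                            minClusterFrequency = 0.01)
    pile <- buildPile(1L, idm, ids, params)
    expect_length(pile$members, 10L)
    expect_setequal(pile$members, 1:10)                 # haplotype-pure

    ## pile of size 1 is just the focal read
    p1 <- clusterParams(pileSize = 1, minClusterReadCount = 1,
                        minClusterFrequency = 0.01)
    expect_equal(buildPile(3L, idm, ids, p1)$members, 3L)

    ## pile covering the pool returns the whole pool
    pAll <- clusterParams(pileSize = 50, minClusterReadCount = 1,
                          minClusterFrequency = 0.01)
    expect_setequal(buildPile(1L, idm, ids, pAll)$members, seq_len(n))

    ## ties broken by lexicographic read id
    pile2 <- buildPile(1L, idm, ids, params)
    expect_equal(pile2$members[-1], 2:10)               # r02..r10 before r11+
})

test_that("error correction masks low-frequency variants and never adds pile variants", {
    params <- clusterParams(pileSize = 10, minVarFrequency = 0.4,
                            minClusterReadCount = 1,
                            minClusterFrequency = 0.01)
    focal <- data.frame(pos = c(5L, 9L), ref = c("A", "G"),
                        alt = c("C", "T"), kind = "SNV", hp = c(1L, 1L))
    ## variant at 5 in 5/10 members, variant at 9 in 2/10
    freqs <- c("5:A>C" = 0.5, "9:G>T" = 0.2)
    corr <- errorCorrect(focal, freqs, params)
    expect_equal(corr$pos, 5L)

    ## idempotence: correcting a pile of identical reads changes nothing
    freqs2 <- c("5:A>C" = 1.0)
    expect_identical(errorCorrect(corr, freqs2, params), corr)

    ## homopolymer masking removes long-run variants regardless of frequency
    pHp <- clusterParams(pileSize = 10, minVarFrequency = 0.4,
                         minClusterReadCount = 1, minClusterFrequency = 0.01,
                         homopolymerMaskLength = 6L)
    hpFocal <- data.frame(pos = c(5L, 9L), ref = c("A", "GA"),
                          alt = c("C", "G"), kind = c("SNV", "del"),
                          hp = c(1L, 7L))
    corrHp <- errorCorrect(hpFocal, c("5:A>C" = 1, "9:GA>G" = 1), pHp)
    expect_equal(corrHp$pos, 5L)
})

test_that("cluster formation groups identical profiles with exact frequencies", {
    empty <- data.frame(pos = integer(), ref = character(),
                        alt = character(), kind = character(),
                        hp = integer())
    v <- data.frame(pos = 7L, ref = "A", alt = "T", kind = "SNV", hp = 1L)
    guide <- substr(as.character(miniRef()$guide), 1, 200)
    stopifnot(substr(guide, 8, 8) == substr(guide, 8, 8))

    ## all reads corrected to the empty profile -> one cluster at 1.0
    cl <- formClusters(replicate(12, empty, simplify = FALSE),
                       sprintf("r%02d", 1:12), guide)
    expect_equal(nClusters(cl), 1L)
    expect_equal(clusterMeta(cl)$frequency, 1.0)
    expect_equal(as.character(consensusSeqs(cl))[[1]], guide)

    ## 30 + 10 reads in two classes -> frequencies 0.75 / 0.25
    v$ref <- substr(guide, 8, 8)
    v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
    profs <- c(replicate(30, empty, simplify = FALSE),
               replicate(10, v, simplify = FALSE))
    cl2 <- formClusters(profs, sprintf("r%02d", 1:40), guide)
    expect_equal(nClusters(cl2), 2L)
    expect_equal(clusterMeta(cl2)$frequency, c(0.75, 0.25))
    ## conservation: read counts sum to the number of corrected reads
    expect_equal(sum(clusterMeta(cl2)$readCount), 40L)
})

test_that("cluster filters enforce read-count and frequency thresholds", {
    empty <- data.frame(pos = integer(), ref = character(),
                        alt = character(), kind = character(),
                        hp = integer())
    v <- data.frame(pos = 7L, ref = "A", alt = "T", kind = "SNV", hp = 1L)
    guide <- paste(rep("ACGTA", 40), collapse = "")
    v$ref <- substr(guide, 8, 8); v$alt <- "C"
    profs <- c(replicate(20, empty, simplify = FALSE),
               replicate(19, v, simplify = FALSE))
    cl <- formClusters(profs, sprintf("r%02d", 1:39), guide,
                       totalReads = 16000L)
    params <- clusterParams(pileSize = 50, minClusterReadCount = 20,
                            minClusterFrequency = 0.00125)
    kept <- filterClusters(cl, params)
    expect_equal(nClusters(kept), 1L)                   # 20/16000 = 0.00125
    expect_equal(clusterMeta(kept)$readCount, 20L)
    removed <- attr(kept, "removed")
    expect_equal(removed$readCount, 19L)
    expect_match(removed$reason, "count")

    ## empty input passes through
    none <- formClusters(list(), character(), guide)
    expect_equal(nClusters(filterClusters(none, params)), 0L)
})

test_that("noise-free two-haplotype pools resolve single-variant differences exactly", {
    haps <- miniHaps()[c("W1", "T1")]                  # differ by one SNV
    spec <- poolSpec("res", 20, c(W1 = 0.5, T1 = 0.5), 60, seed = 41)
    reads <- simulatePoolReads(spec, haps,
                               readSimParams(substitutionRate = 0,
                                             homopolymerIndelRate = 0))
    params <- derivePoolParameters(20, length(reads))
    cl <- clusterPool(reads, miniRef()$guide, params)
    expect_equal(nClusters(cl), 2L)
    expect_setequal(unname(as.character(consensusSeqs(cl))),
                    unname(as.character(haps)))
})

test_that("default-error pools recover planted haplotypes after pile correction", {
    haps <- miniHaps()[1:4]
    spec <- poolSpec("err", 50, c(W1 = 0.4, W2 = 0.3, W3 = 0.2, W4 = 0.1),
                     500, seed = 43)
    reads <- simulatePoolReads(spec, haps)
    params <- derivePoolParameters(50, length(reads))   # depth 5, pile 6
    cl <- clusterPool(reads, miniRef()$guide, params)
    expect_setequal(unname(as.character(consensusSeqs(cl))),
                    unname(as.character(haps)))
    ## frequencies track the pool composition
    idx <- match(as.character(haps), as.character(consensusSeqs(cl)))
    expect_lt(max(abs(clusterMeta(cl)$frequency[idx] -
                      c(0.4, 0.3, 0.2, 0.1))), 0.1)
})
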