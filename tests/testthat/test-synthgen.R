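test_that("default geometry yields the full-size amplicon with TSR codons in the penultimate exon", {
    ref <- defaultRef()
    cfg <- geneModelConfig("default")
    expLen <- cfg$upstream + sum(cfg$exonLengths) + sum(cfg$intronLengths) +
        cfg$downstream
    expect_equal(ampliconLength(ref$model), expLen)
    expect_equal(ampliconLength(ref$model), 13249L)
    expect_equal(cfg$upstream, 585L)
    expect_equal(cfg$downstream, 364L)
    expect_equal(nExons(ref$model), 32L)
    expect_equal(Biostrings::nchar(ref$guide), 13249L)

    ## all seven codons inside the penultimate exon
    ex <- exons(ref$model)
    pen <- ex[length(ex) - 1L]
    cod <- tsrCodons(ref$model)
    expect_setequal(names(cod),
                    c("1781", "1999", "2027", "2041", "2078", "2088", "2096"))
    expect_true(all(IRanges::start(cod) >= IRanges::start(pen)))
    expect_true(all(IRanges::start(cod) + 3L <=
                    IRanges::start(pen) + IRanges::width(pen)))
})

test_that("the guide CDS translates without internal stops and carries canonical wild-type residues", {
    for (ref in list(miniRef(), defaultRef())) {
        guide <- as.character(ref$guide)
        ex <- exons(ref$model)
        cds <- paste(substring(guide, IRanges::start(ex) + 1L,
                               IRanges::start(ex) + IRanges::width(ex)),
                     collapse = "")
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
        expect_false(grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
        expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
        ## wild-type amino acids at the mapped TSR codons
        sites <- tsrSites()
        cod <- tsrCodons(ref$model)
        for (nm in names(cod)) {
            codonSeq <- substring(guide, IRanges::start(cod[nm]) + 1L,
                                  IRanges::start(cod[nm]) + 3L)
            aa1 <- unname(Biostrings::GENETIC_CODE[codonSeq])
            expect_equal(aa1, sites$wtAA[sites$codon == as.integer(nm)])
        }
    }
})

test_that("reference construction is seed-deterministic and rejects impossible geometry", {
    a <- buildReference(geneModelConfig("mini", seed = 42))
    b <- buildReference(geneModelConfig("mini", seed = 42))
    expect_identical(as.character(a$guide), as.character(b$guide))
    expect_identical(a$model, b$model)
    c <- buildReference(geneModelConfig("mini", seed = 43))
    expect_false(identical(as.character(a$guide), as.character(c$guide)))

    bad <- geneModelConfig("mini")
    bad$tsrMap <- c("2096" = 10L)      # codon 10 sits in the first exon
    expect_error(buildReference(bad), "geometry error")
})

test_that("TSR haplotypes differ from their wild-type parent by exactly one mutation", {
    haps <- miniHaps()
    mc <- S4Vectors::mcols(haps)
    expect_equal(sum(mc$isTsr), 2L)
    expect_equal(mc$tsrAllele[mc$id == "T1"], "Ile1781.1Leu_T")
    expect_equal(mc$parentId[mc$id == "T1"], "W1")

    ## the mutated codon reads TTA in the child
    cod <- tsrCodons(miniRef()$model)["1781"]
    t1 <- as.character(haps[["T1"]])
    w1 <- as.character(haps[["W1"]])
    expect_equal(substring(t1, IRanges::start(cod) + 1L,
                           IRanges::start(cod) + 3L), "TTA")
    expect_equal(substring(w1, IRanges::start(cod) + 1L,
                           IRanges::start(cod) + 3L), "ATA")

    ## full pairwise alignment oracle: distance parent -> child is 1
    expect_equal(alignmentDistance(haps[["W1"]], haps[["T1"]]), 1L)
    expect_equal(alignmentDistance(haps[["W2"]], haps[["T2"]]), 1L)

    ## all haplotypes pairwise distinct
    expect_equal(anyDuplicated(as.character(haps)), 0L)

    ## synonymous specs are rejected: ATA -> ATC is still Ile
    expect_error(
        spawnHaplotypes(miniRef()$guide, miniRef()$model, 1,
                        data.frame(parent = 1L, codon = 1781L,
                                   codonPos = 3L, alt = "C"), seed = 1),
        "synonymous")
})

test_that("a single wild-type request returns one haplotype", {
    one <- spawnHaplotypes(miniRef()$guide, miniRef()$model, 1, NULL,
                           seed = 7)
    expect_length(one, 1L)
    expect_equal(names(one), "W1")
})

test_that("error-free reads reproduce their source haplotypes and match requested frequencies", {
    haps <- miniHaps()[1:2]
    spec <- poolSpec("chk", 100,
                     c(W1 = 0.5, W2 = 0.5), 10000, seed = 21)
    reads <- simulatePoolReads(spec, haps,
                               readSimParams(substitutionRate = 0,
                                             homopolymerIndelRate = 0,
                                             orientationMix = 0))
    src <- sub(".* hap=(\\S+) rc=.*", "\\1", names(reads))
    expect_true(all(as.character(reads) == as.character(haps[src])))

    ## source counts within 4 sigma of binomial expectation
    n1 <- sum(src == "W1")
    expect_lt(abs(n1 - 5000), 4 * sqrt(10000 * 0.25))
    ## chi-square goodness of fit not rejected at alpha = 0.001
    expect_gt(stats::chisq.test(table(src), p = c(0.5, 0.5))$p.value, 0.001)
})

test_that("orientation mix reverse-complements about half the reads and flags them", {
    haps <- miniHaps()[1]
    spec <- poolSpec("ori", 10, c(W1 = 1), 2000, seed = 31)
    reads <- simulatePoolReads(spec, haps,
                               readSimParams(substitutionRate = 0,
                                             homopolymerIndelRate = 0,
                                             orientationMix = 0.5))
    rc <- sub(".* rc=(\\d)$", "\\1", names(reads)) == "1"
    expect_lt(abs(sum(rc) - 1000), 4 * sqrt(2000 * 0.25))
    w1 <- as.character(haps[["W1"]])
    w1rc <- as.character(Biostrings::reverseComplement(haps[["W1"]]))
    expect_true(all(as.character(reads[rc]) == w1rc))
    expect_true(all(as.character(reads[!rc]) == w1))
})

test_that("simulated reads are seed-deterministic and meet the accuracy floor", {
    haps <- miniHaps()
    freqs <- stats::setNames(rep(0.1, 10), names(haps))
    spec <- poolSpec("det", 100, freqs, 300, seed = 77)
    a <- simulatePoolReads(spec, haps)
    b <- simulatePoolReads(spec, haps)
    expect_identical(as.character(a), as.character(b))
    expect_identical(as.character(S4Vectors::mcols(a)$quality),
                     as.character(S4Vectors::mcols(b)$quality))

    ## mean identity to the source haplotype stays above the q30 floor
    src <- sub(".* hap=(\\S+) rc=.*", "\\1", names(a))
    rc <- sub(".* rc=(\\d)$", "\\1", names(a)) == "1"
    ids <- vapply(seq_len(200), function(i) {
        r <- a[[i]]
        if (rc[i]) r <- Biostrings::reverseComplement(r)
        d <- alignmentDistance(r, haps[[src[i]]])
        1 - d / Biostrings::nchar(haps[[src[i]]])
    }, numeric(1))
    expect_gte(mean(ids), 0.999)
})

test_that("FASTQ output round-trips through disk byte-identically", {
    haps <- miniHaps()[1:3]
    spec <- poolSpec("io", 10, c(W1 = 0.5, W2 = 0.3, W3 = 0.2), 50,
                     seed = 5)
    reads <- simulatePoolReads(spec, haps)
    f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
    writeReadsFastq(reads, f1)
    back <- readReadsFastq(f1)
    expect_identical(names(back), names(reads))
    expect_identical(unname(as.character(back)),
                     unname(as.character(reads)))
    writeReadsFastq(back, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("diploid individuals are two draws from the pool frequencies", {
    spec <- poolSpec("ind", 24, c(A = 0.6, B = 0.4), 100, seed = 1)
    expect_equal(nrow(sampleIndividuals(spec, 0)), 0L)

    mono <- poolSpec("mono", 24, c(A = 1), 100, seed = 1)
    ind <- sampleIndividuals(mono, 24, seed = 2)
    expect_true(all(ind$hap1 == "A" & ind$hap2 == "A"))

    ind2 <- sampleIndividuals(spec, 24, seed = 3)
    expect_lte(length(unique(c(ind2$hap1, ind2$hap2))), 48L)
    expect_identical(ind2, sampleIndividuals(spec, 24, seed = 3))
})

test_that("template copy arithmetic matches the molarity equation", {
    expect_equal(round(estimateTemplateCopies(50, 3.56e9)), 13012)
    expect_equal(estimateTemplateCopies(0, 3.56e9), 0)
    expect_error(estimateTemplateCopies(50, 0), "positive")

    copies <- estimateTemplateCopies(50, 3.56e9)
    expect_equal(round(copies / 400, 1), 32.5)
    expect_equal(round(copies / 300, 1), 43.4)
    expect_equal(round(copiesPerHaploidGenome(50, 3.56e9, 400), 1), 32.5)

    ## linear in mass, inverse-linear in genome size
    expect_equal(estimateTemplateCopies(100, 3.56e9), 2 * copies)
    expect_equal(estimateTemplateCopies(50, 2 * 3.56e9), copies / 2)
})

test_that("pool manifest and gene model exports are well formed", {
    spec <- poolSpec("pX", 10, c(W1 = 0.7, W2 = 0.3), 100, seed = 1)
    mf <- tempfile(fileext = ".tsv")
    writePoolManifest(list(spec), mf, seed = 1)
    lines <- readLines(mf)
    expect_match(lines[1], "^# pilepool")
    tab <- utils::read.delim(mf, comment.char = "#")
    expect_equal(tab$haplotype_id, c("W1", "W2"))
    expect_equal(sum(tab$frequency), 1)

    pre <- tempfile()
    writeGeneModel(miniRef()$model, pre, seed = 1)
    bed <- utils::read.delim(paste0(pre, ".bed"), header = FALSE,
                             comment.char = "#")
    expect_equal(nrow(bed), nExons(miniRef()$model))
    side <- jsonlite::read_json(paste0(pre, ".codons.json"))
    expect_equal(side$amplicon_length, 2000L)
    expect_true("1781" %in% names(side$tsr_codons))
})
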