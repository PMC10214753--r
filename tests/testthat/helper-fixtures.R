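## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}

miniRef <- function() memo("miniRef", function()
    buildReference(geneModelConfig("mini", seed = 3)))

defaultRef <- function() memo("defaultRef", function()
    buildReference(geneModelConfig("default", seed = 3)))

## 8 wild types + 2 TSR children (T1 from W1 at codon 1781.1 A>T,
## T2 from W2 at codon 1781.2 T>C)
miniHaps <- function() memo("miniHaps", function()
    spawnHaplotypes(miniRef()$guide, miniRef()$model, nWildtype = 8,
                    tsrSpec = data.frame(parent = c(1L, 2L),
                                         codon = 1781L,
                                         codonPos = c(1L, 2L),
                                         alt = c("T", "C")),
                    seed = 5))

hapProfiles <- function(haps = miniHaps()) S4Vectors::metadata(haps)$profiles

## a pool whose haplotype frequencies are the realized frequencies of 200
## sampled diploid individuals, so carrier counts are known exactly
realizedPool <- function(poolId, nIndividuals, reads, baseFreqs, seedInd,
                         seedPool) {
    spec0 <- poolSpec(poolId, nIndividuals, baseFreqs, reads,
                      seed = seedPool)
    ind <- sampleIndividuals(spec0, nIndividuals, seed = seedInd)
    realized <- table(factor(c(ind$hap1, ind$hap2),
                             levels = names(baseFreqs)))
    realized <- realized[realized > 0]
    spec <- poolSpec(poolId, nIndividuals,
                     stats::setNames(as.numeric(realized) / sum(realized),
                                     names(realized)),
                     reads, seed = seedPool)
    list(spec = spec, individuals = ind)
}

## reads with explicit sequence and uniform quality
mkReads <- function(seqs, phred = 40L) {
    x <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(x))) names(x) <- sprintf("r%03d", seq_along(x))
    S4Vectors::mcols(x)$quality <- Biostrings::BStringSet(
        vapply(nchar(seqs), function(n) strrep(intToUtf8(phred + 33L), n),
               character(1)))
    x
}

## brute-force edit distance between two sequences via full (unbanded)
## global alignment: mismatches plus gapped columns
alignmentDistance <- function(a, b) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                    mismatch = -4,
                                                    baseOnly = TRUE)
    pw <- Biostrings::pairwiseAlignment(as.character(a), as.character(b),
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 4, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(pw)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(pw)), "")[[1]]
    sum(pa != sa)
}
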