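#' @importFrom Biostrings BStringSet writeXStringSet readDNAStringSet
#' @importFrom stats rpois rbinom runif
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

## canonical wild-type codons at the seven ACCase TSR sites, chosen so that
## the substitutions reported in blackgrass (Ile1781Leu via A>T at codon
## position 1, Ile2041Asn via T>A at position 2, ...) are single-base
sensibleWtCodons <- c(
    "1781" = "ATA",  # Ile
    "1999" = "TGG",  # Trp
    "2027" = "TGG",  # Trp
    "2041" = "ATT",  # Ile
    "2078" = "GAT",  # Asp
    "2088" = "TGT",  # Cys
    "2096" = "GGA"   # Gly
)

#' Geometry configuration for a synthetic reference amplicon
#'
#' Two built-in profiles: `"default"` reproduces the full-size amplicon
#' geometry (585 bp upstream flank, a 32-exon / 31-intron gene of 12.3 kb
#' with all seven TSR codons in the penultimate exon, 364 bp downstream;
#' 13,249 bp in total), and `"mini"` is a 2 kb, 4-exon gene with a single
#' TSR codon (1781) for fast experiments. The `tsrMap` assigns field-
#' convention codon numbers to CDS codon indices; in the default profile
#' the mapping is literal.
#'
#' @param profile `"mini"` or `"default"`
#' @param seed integer seed used by [buildReference()]
#' @param strand `"+"` or `"-"`
#' @return a config list (`upstream`, `downstream`, `exonLengths`,
#'   `intronLengths`, `tsrMap`, `strand`, `seed`)
#' @export
geneModelConfig <- function(profile = c("mini", "default"), seed = 1L,
                            strand = "+") {
    profile <- match.arg(profile)
    if (profile == "default") {
        list(upstream = 585L, downstream = 364L,
             exonLengths = c(rep(173L, 29L), 183L, 1500L, 236L),
             intronLengths = c(rep(173L, 30L), 174L),
             tsrMap = stats::setNames(
                 as.integer(names(sensibleWtCodons)), names(sensibleWtCodons)),
             strand = strand, seed = as.integer(seed))
    } else {
        list(upstream = 100L, downstream = 100L,
             exonLengths = c(210L, 240L, 300L, 150L),
             intronLengths = c(300L, 300L, 300L),
             tsrMap = c("1781" = 200L),
             strand = strand, seed = as.integer(seed))
    }
}

randomDna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## map a 0-based CDS coordinate to a 0-based gene-orientation amplicon
## coordinate given exon starts/lengths
cdsToAmplicon <- function(cdsPos0, exonStarts0, exonLengths) {
    cum <- cumsum(exonLengths)
    ei <- findInterval(cdsPos0, c(0, cum), rightmost.closed = FALSE)
    exonStarts0[ei] + (cdsPos0 - c(0, cum)[ei])
}

#' Build a seeded synthetic reference amplicon and its gene model
#'
#' Draws a random DNA amplicon whose CDS translates without internal stop
#' codons and whose TSR codons carry the canonical wild-type amino acids
#' (Ile1781, Trp1999, Trp2027, Ile2041, Asp2078, Cys2088, Gly2096). The
#' same config (including seed) always yields the identical sequence and
#' model.
#'
#' @param config a list from [geneModelConfig()]
#' @return list with `guide` ([Biostrings::DNAString]) and `model`
#'   ([GeneModel-class])
#' @export
buildReference <- function(config = geneModelConfig()) {
    set.seed(config$seed)
    nEx <- length(config$exonLengths)
    if (length(config$intronLengths) != nEx - 1L)
        stop("need exactly one fewer intron than exons")
    cdsLen <- sum(config$exonLengths)
    if (cdsLen %% 3L != 0L)
        stop("geometry error: exon lengths must sum to a multiple of 3")
    nCodons <- cdsLen %/% 3L

    codons <- sample(setdiff(mkAllCodons(), STOP_CODONS), nCodons,
                     replace = TRUE)
    codons[nCodons] <- "TAA"              # terminal stop
    for (nm in names(config$tsrMap)) {
        idx <- config$tsrMap[[nm]]
        if (idx < 1L || idx >= nCodons)
            stop("geometry error: CDS cannot host mapped codon ", nm)
        codons[idx] <- sensibleWtCodons[[nm]]
    }
    cds <- paste(codons, collapse = "")

    ## assemble gene-orientation amplicon
    cumEx <- cumsum(config$exonLengths)
    exonSeqs <- substring(cds, c(1L, cumEx[-nEx] + 1L), cumEx)
    pieces <- character(2L * nEx - 1L)
    pieces[seq(1L, by = 2L, length.out = nEx)] <- exonSeqs
    pieces[seq(2L, by = 2L, length.out = nEx - 1L)] <-
        vapply(config$intronLengths, randomDna, character(1))
    amplicon <- paste0(randomDna(config$upstream),
                       paste(pieces, collapse = ""),
                       randomDna(config$downstream))
    L <- nchar(amplicon)

    ## exon starts in gene-orientation amplicon coordinates (0-based)
    geneLens <- integer(2L * nEx - 1L)
    geneLens[seq(1L, by = 2L, length.out = nEx)] <- config$exonLengths
    geneLens[seq(2L, by = 2L, length.out = nEx - 1L)] <- config$intronLengths
    pieceStarts <- config$upstream + c(0L, cumsum(geneLens))[seq_along(geneLens)]
    exonStarts0 <- pieceStarts[seq(1L, by = 2L, length.out = nEx)]

    ## TSR codon intervals, checked against the penultimate exon
    penStart <- exonStarts0[nEx - 1L]
    penEnd <- penStart + config$exonLengths[nEx - 1L]
    codStarts <- vapply(names(config$tsrMap), function(nm) {
        s <- cdsToAmplicon(3L * (config$tsrMap[[nm]] - 1L),
                           exonStarts0, config$exonLengths)
        e <- cdsToAmplicon(3L * config$tsrMap[[nm]] - 1L,
                           exonStarts0, config$exonLengths)
        if (e != s + 2L)
            stop("geometry error: codon ", nm, " split across an exon junction")
        if (s < penStart || s + 3L > penEnd)
            stop("geometry error: codon ", nm, " not in the penultimate exon")
        as.integer(s)
    }, integer(1))

    exonsIR <- IRanges(start = exonStarts0, width = config$exonLengths)
    codIR <- IRanges(start = as.integer(codStarts), width = 3L)
    names(codIR) <- names(config$tsrMap)
    up <- config$upstream; down <- config$downstream

    if (config$strand == "-") {
        amplicon <- as.character(reverseComplement(DNAString(amplicon)))
        flip <- function(ir) {
            out <- IRanges(start = L - (start(ir) + width(ir)), width = width(ir))
            names(out) <- names(ir)
            out
        }
        exonsIR <- rev(flip(exonsIR))
        codIR <- flip(codIR)
        tmp <- up; up <- down; down <- tmp
    }

    model <- new("GeneModel",
        ampliconLength = L, upstreamLength = as.integer(up),
        downstreamLength = as.integer(down), exons = exonsIR,
        strand = config$strand, tsrCodons = codIR)
    list(guide = DNAString(amplicon), model = model)
}

mkAllCodons <- function() {
    g <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
    paste0(g[[3]], g[[2]], g[[1]])
}

#' Spawn a haplotype set around a guide sequence
#'
#' Wild-type haplotypes carry random SNVs outside the TSR codons; each TSR
#' haplotype equals its wild-type parent plus exactly the one specified TSR
#' codon change, so parent/child pairs differ by a single mutation across
#' the whole amplicon.
#'
#' @param guide guide sequence
#' @param model a [GeneModel-class]
#' @param nWildtype number of wild-type haplotypes
#' @param tsrSpec `NULL`, or a data frame with columns `parent` (wild-type
#'   index), `codon` (TSR codon number), `codonPos` (1--3) and `alt`
#'   (alternate base in CDS orientation); synonymous changes are rejected
#' @param seed integer seed
#' @param meanVariants Poisson mean of background SNVs per wild-type
#'   haplotype (at least one is always planted)
#' @return [Biostrings::DNAStringSet] named by haplotype id, with `mcols`
#'   columns `id`, `isTsr`, `tsrAllele`, `parentId`, and the variant
#'   profiles in `metadata(x)$profiles`
#' @export
spawnHaplotypes <- function(guide, model, nWildtype, tsrSpec = NULL,
                            seed = 1L, meanVariants = 8) {
    set.seed(seed)
    guide <- as.character(guide)
    L <- nchar(guide)
    gch <- strsplit(guide, "", fixed = TRUE)[[1]]
    ghp <- homopolymerRuns(guide)
    forbidden <- unlist(lapply(seq_along(tsrCodons(model)), function(i) {
        iv <- tsrCodons(model)[i]
        seq(start(iv), start(iv) + 2L)
    }))
    allowed <- setdiff(seq_len(L) - 1L, forbidden)

    profiles <- list()
    seen <- character()
    for (i in seq_len(nWildtype)) {
        repeat {
            nv <- max(1L, rpois(1L, meanVariants))
            pos0 <- sort(sample(allowed, nv))
            alt <- vapply(pos0, function(p)
                sample(setdiff(BASES, gch[p + 1L]), 1L), character(1))
            prof <- data.frame(pos = pos0, ref = gch[pos0 + 1L], alt = alt,
                               kind = "SNV", hp = ghp[pos0 + 1L],
                               stringsAsFactors = FALSE)
            key <- paste(profileKeys(prof), collapse = ";")
            if (!key %in% seen) break
        }
        seen <- c(seen, key)
        profiles[[paste0("W", i)]] <- prof
    }

    if (!is.null(tsrSpec) && nrow(tsrSpec) > 0L) {
        for (i in seq_len(nrow(tsrSpec))) {
            sp <- tsrSpec[i, ]
            ann <- codonChangeAnnotation(model, guide, sp$codon,
                                         sp$codonPos, sp$alt)
            if (ann$synonymous)
                stop("TSR spec entry ", i, " (codon ", sp$codon,
                     " position ", sp$codonPos, " alt ", sp$alt,
                     ") is synonymous: ", ann$wtAA, " -> ", ann$newAA)
            parent <- profiles[[paste0("W", sp$parent)]]
            if (is.null(parent))
                stop("TSR spec entry ", i, ": no wild-type parent W", sp$parent)
            v <- data.frame(pos = ann$pos, ref = ann$refBase,
                            alt = ann$altBase, kind = "SNV",
                            hp = ghp[ann$pos + 1L], stringsAsFactors = FALSE)
            prof <- rbind(parent, v)
            prof <- prof[order(prof$pos), , drop = FALSE]
            rownames(prof) <- NULL
            key <- paste(profileKeys(prof), collapse = ";")
            if (key %in% seen)
                stop("TSR spec entry ", i, " duplicates an existing haplotype")
            seen <- c(seen, key)
            profiles[[paste0("T", i)]] <- prof
        }
    }

    ids <- names(profiles)
    seqs <- DNAStringSet(vapply(profiles, function(p) applyProfile(guide, p),
                                character(1)))
    names(seqs) <- ids
    nT <- if (is.null(tsrSpec)) 0L else nrow(tsrSpec)
    isTsr <- grepl("^T", ids)
    allele <- rep("", length(ids))
    parentId <- rep(NA_character_, length(ids))
    if (nT > 0L) {
        for (i in seq_len(nT)) {
            ann <- codonChangeAnnotation(model, guide, tsrSpec$codon[i],
                                         tsrSpec$codonPos[i], tsrSpec$alt[i])
            allele[ids == paste0("T", i)] <- ann$name
            parentId[ids == paste0("T", i)] <- paste0("W", tsrSpec$parent[i])
        }
    }
    S4Vectors::mcols(seqs) <- DataFrame(id = ids, isTsr = isTsr,
                                        tsrAllele = allele,
                                        parentId = parentId)
    metadata(seqs)$profiles <- profiles
    seqs
}

#' Specify a pool of diploid individuals
#'
#' @param poolId label
#' @param nIndividuals diploid individuals in the pool
#' @param haplotypeFrequencies named proportions summing to 1
#' @param readsRequested reads to simulate for the pool
#' @param seed integer seed
#' @return a `PoolSpec` (list)
#' @export
poolSpec <- function(poolId, nIndividuals, haplotypeFrequencies,
                     readsRequested, seed = 1L) {
    if (nIndividuals <= 0) stop("nIndividuals must be positive")
    if (is.null(names(haplotypeFrequencies)))
        stop("haplotypeFrequencies must be named by haplotype id")
    if (abs(sum(haplotypeFrequencies) - 1) > 1e-9)
        stop("haplotype frequencies must sum to 1")
    structure(list(poolId = poolId, nIndividuals = as.integer(nIndividuals),
                   haplotypeFrequencies = haplotypeFrequencies,
                   readsRequested = as.integer(readsRequested),
                   seed = as.integer(seed)),
              class = "PoolSpec")
}

#' HiFi-like read simulation parameters
#'
#' Defaults give ~q30 reads: substitutions at 5e-4 per base and
#' single-base indels at 3e-4 per homopolymer run of at least
#' `minHomopolymerLength` bases, matching the error profile of
#' quality-filtered circular-consensus reads, whose residual errors
#' concentrate in homopolymer contexts.
#'
#' @param substitutionRate per-base substitution probability
#' @param homopolymerIndelRate per-run indel probability
#' @param minHomopolymerLength shortest run subject to indel errors
#' @param minPredictedAccuracy expected per-read accuracy floor at defaults
#' @param orientationMix proportion of reads emitted reverse-complemented
#' @param seed integer seed (combined with the pool seed)
#' @return a `ReadSimParams` (list)
#' @export
readSimParams <- function(substitutionRate = 5e-4,
                          homopolymerIndelRate = 3e-4,
                          minHomopolymerLength = 4L,
                          minPredictedAccuracy = 0.999,
                          orientationMix = 0.5, seed = 1L) {
    structure(list(substitutionRate = substitutionRate,
                   homopolymerIndelRate = homopolymerIndelRate,
                   minHomopolymerLength = as.integer(minHomopolymerLength),
                   minPredictedAccuracy = minPredictedAccuracy,
                   orientationMix = orientationMix, seed = as.integer(seed)),
              class = "ReadSimParams")
}

## Phred qualities drawn per base; the mixture mean error (~4e-4)
## corresponds to a predicted accuracy of ~0.9996
QUAL_LEVELS <- c(30L, 33L, 37L, 40L)
QUAL_PROBS <- c(0.15, 0.35, 0.30, 0.20)

#' Simulate HiFi-like reads for a pool
#'
#' Each read is drawn from a haplotype with probability equal to its pool
#' frequency, full-length (amplicon reads are full-length by construction),
#' with substitution errors and homopolymer-biased single-base indels
#' injected at the configured rates, Sanger-scaled per-base qualities, and
#' a configurable share of reverse-complement reads. The true source
#' haplotype and orientation are recorded in the read header (`hap=`,
#' `rc=`) for test oracles only; the analysis pipeline never reads them.
#'
#' @param pool a [poolSpec()]
#' @param haplotypes haplotype sequences from [spawnHaplotypes()]
#' @param params a [readSimParams()]
#' @return [Biostrings::DNAStringSet] with qualities in
#'   `mcols(x)$quality` ([Biostrings::BStringSet])
#' @export
simulatePoolReads <- function(pool, haplotypes, params = readSimParams()) {
    freqs <- pool$haplotypeFrequencies
    miss <- setdiff(names(freqs), names(haplotypes))
    if (length(miss))
        stop("pool references unknown haplotypes: ", paste(miss, collapse = ", "))
    set.seed((pool$seed * 10007L + params$seed) %% 2147483647L)

    hapChars <- lapply(names(freqs), function(h)
        strsplit(as.character(haplotypes[[h]]), "", fixed = TRUE)[[1]])
    names(hapChars) <- names(freqs)
    hapRuns <- lapply(hapChars, function(ch) {
        r <- rle(ch)
        ends <- cumsum(r$lengths)
        keep <- r$lengths >= params$minHomopolymerLength
        data.frame(start = (ends - r$lengths + 1L)[keep],
                   base = r$values[keep])
    })

    n <- pool$readsRequested
    src <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    seqs <- character(n); quals <- character(n); rc <- logical(n)
    for (i in seq_len(n)) {
        ch <- hapChars[[src[i]]]
        len <- length(ch)
        nsub <- rbinom(1L, len, params$substitutionRate)
        if (nsub > 0L) {
            at <- sample.int(len, nsub)
            ch[at] <- vapply(ch[at], function(b)
                sample(setdiff(BASES, b), 1L), character(1))
        }
        runs <- hapRuns[[src[i]]]
        counts <- NULL
        if (nrow(runs) > 0L) {
            hit <- which(runif(nrow(runs)) < params$homopolymerIndelRate)
            if (length(hit)) {
                counts <- rep.int(1L, len)
                ## delete or duplicate one base of the run
                counts[runs$start[hit]] <- ifelse(runif(length(hit)) < 0.5, 0L, 2L)
            }
        }
        if (!is.null(counts)) ch <- rep.int(ch, counts)
        q <- sample(QUAL_LEVELS, length(ch), replace = TRUE, prob = QUAL_PROBS)
        s <- paste(ch, collapse = "")
        rc[i] <- runif(1L) < params$orientationMix
        if (rc[i]) {
            s <- as.character(reverseComplement(DNAString(s)))
            q <- rev(q)
        }
        seqs[i] <- s
        quals[i] <- intToUtf8(q + 33L)
    }
    out <- DNAStringSet(seqs)
    names(out) <- sprintf("%s_r%05d hap=%s rc=%d", pool$poolId,
                          seq_len(n), src, as.integer(rc))
    S4Vectors::mcols(out)$quality <- BStringSet(quals)
    out
}

#' Draw diploid individuals from a pool's haplotype frequencies
#'
#' Emulates the individual-sequencing arm of the benchmark: each individual
#' is two haplotype draws with replacement.
#'
#' @param pool a [poolSpec()]
#' @param n number of individuals
#' @param seed integer seed
#' @return data frame with columns `individual`, `hap1`, `hap2`
#' @export
sampleIndividuals <- function(pool, n, seed = 1L) {
    set.seed(seed)
    if (n == 0L)
        return(data.frame(individual = integer(), hap1 = character(),
                          hap2 = character(), stringsAsFactors = FALSE))
    freqs <- pool$haplotypeFrequencies
    draws <- matrix(sample(names(freqs), 2L * n, replace = TRUE, prob = freqs),
                    ncol = 2L)
    data.frame(individual = seq_len(n), hap1 = draws[, 1], hap2 = draws[, 2],
               stringsAsFactors = FALSE)
}

#' PCR template copies from input DNA mass
#'
#' `copies = mass_ng * 6.022e23 / (genome_bp * 1e9 * 650)`, the standard
#' molarity arithmetic for double-stranded DNA at 650 g/mol per base pair.
#'
#' @param massNg input DNA mass in nanograms
#' @param haploidGenomeBp haploid genome size in base pairs
#' @return expected number of template copies (real-valued)
#' @export
estimateTemplateCopies <- function(massNg, haploidGenomeBp) {
    if (any(haploidGenomeBp <= 0)) stop("genome size must be positive")
    if (any(massNg < 0)) stop("DNA mass must be non-negative")
    massNg * 6.022e23 / (haploidGenomeBp * 1e9 * 650)
}

#' @describeIn estimateTemplateCopies copies available per haploid genome
#'   when the template is shared by `nHaplotypes` haploid genomes (e.g.
#'   2x the number of diploid individuals in the pool)
#' @param nHaplotypes number of haploid genomes sharing the template
#' @export
copiesPerHaploidGenome <- function(massNg, haploidGenomeBp, nHaplotypes) {
    if (any(nHaplotypes <= 0)) stop("haplotype count must be positive")
    estimateTemplateCopies(massNg, haploidGenomeBp) / nHaplotypes
}

#' Read/write FASTQ with per-base qualities
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()] keeping qualities in `mcols(x)$quality`.
#'
#' @param reads DNAStringSet with `mcols(x)$quality`
#' @param path file path
#' @return `readReadsFastq` returns the reads; `writeReadsFastq` the path,
#'   invisibly
#' @export
writeReadsFastq <- function(reads, path) {
    writeXStringSet(reads, path, format = "fastq",
                    qualities = S4Vectors::mcols(reads)$quality)
    invisible(path)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(path) {
    x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    q <- S4Vectors::mcols(x)$qualities
    S4Vectors::mcols(x) <- NULL
    S4Vectors::mcols(x)$quality <- q
    x
}

#' Export pool composition and gene model
#'
#' `writePoolManifest` writes a provenance-headed TSV (pool_id,
#' n_individuals, haplotype_id, frequency); `writeGeneModel` writes the
#' exon layout as BED (0-based half-open) plus a JSON sidecar with the TSR
#' codon map.
#'
#' @param pools list of [poolSpec()] objects
#' @param path output path
#' @param seed seed recorded in the provenance header
#' @export
writePoolManifest <- function(pools, path, seed = NA) {
    rows <- do.call(rbind, lapply(pools, function(p)
        data.frame(pool_id = p$poolId, n_individuals = p$nIndividuals,
                   haplotype_id = names(p$haplotypeFrequencies),
                   frequency = unname(p$haplotypeFrequencies),
                   stringsAsFactors = FALSE)))
    writeLines(provenanceHeader(seed), path)
    suppressWarnings(utils::write.table(rows, path, sep = "\t",
        quote = FALSE, row.names = FALSE, append = TRUE))
    invisible(path)
}

#' @rdname writePoolManifest
#' @param model a [GeneModel-class]
#' @param prefix output path prefix (writes `<prefix>.bed` and
#'   `<prefix>.codons.json`)
#' @export
writeGeneModel <- function(model, prefix, seed = NA) {
    ex <- exons(model)
    bed <- data.frame(chrom = "amplicon", start = start(ex),
                      end = start(ex) + width(ex),
                      name = sprintf("exon%02d", seq_along(ex)),
                      score = 0L, strand = geneStrand(model))
    bedPath <- paste0(prefix, ".bed")
    writeLines(provenanceHeader(seed), bedPath)
    suppressWarnings(utils::write.table(bed, bedPath, sep = "\t",
        quote = FALSE, row.names = FALSE, col.names = FALSE, append = TRUE))
    cod <- tsrCodons(model)
    sidecar <- list(
        amplicon_length = ampliconLength(model),
        upstream_length = model@upstreamLength,
        downstream_length = model@downstreamLength,
        strand = geneStrand(model),
        tsr_codons = stats::setNames(lapply(seq_along(cod), function(i)
            list(start = start(cod)[i], end = start(cod)[i] + 3L)),
            names(cod)))
    jsonlite::write_json(sidecar, paste0(prefix, ".codons.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(prefix)
}

provenanceHeader <- function(seed = NA, extra = NULL) {
    c(sprintf("# pilepool %s | %s | seed=%s",
              as.character(utils::packageVersion("pilepool")),
              format(Sys.time(), "%Y-%m-%d"), as.character(seed)),
      extra)
}
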