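#' @importFrom Matrix sparseMatrix tcrossprod colSums
NULL

#' Derive clustering parameters from pool design
#'
#' The pool-design rule: with `totalReads` normalized reads over
#' `nIndividuals` diploids, the expected depth per haplotype is
#' `totalReads / (2 * nIndividuals)`. The minimum cluster read count is
#' half that depth (rounded up), the minimum cluster frequency is the
#' corresponding read fraction, and the pile is set a quarter larger than
#' the expected haplotype read count (`pileFactor` 1.25) to reduce
#' spurious cluster formation while keeping piles mostly within-haplotype.
#' For 200 individuals at 16,000 reads this yields depth 40, read count
#' 20, frequency 0.00125 and pile size 50.
#'
#' @param nIndividuals diploid individuals in the pool
#' @param totalReads normalized reads in the pool
#' @param pileFactor pile size as a multiple of the expected haplotype
#'   depth (default 1.25)
#' @param minVarFrequency within-pile variant frequency cutoff
#' @param homopolymerMaskLength optional homopolymer masking length
#' @return a [ClusterParams-class]
#' @export
derivePoolParameters <- function(nIndividuals, totalReads,
                                 pileFactor = 1.25, minVarFrequency = 0.4,
                                 homopolymerMaskLength = NULL) {
    stopifnot(nIndividuals > 0, totalReads > 0)
    depth <- totalReads / (2 * nIndividuals)
    minCount <- as.integer(ceiling(depth / 2))
    clusterParams(
        pileSize = max(1L, as.integer(round(depth * pileFactor))),
        minVarFrequency = minVarFrequency,
        minClusterReadCount = minCount,
        minClusterFrequency = minCount / totalReads,
        maxAlignmentsPerRead = as.integer(totalReads),
        maxReadsPerGuide = as.integer(totalReads),
        homopolymerMaskLength = homopolymerMaskLength)
}

## Sparse read x variant incidence over profile keys. Returns the matrix,
## the key universe and per-read variant counts.
profileIncidence <- function(profiles) {
    keys <- lapply(profiles, profileKeys)
    uni <- unique(unlist(keys, use.names = FALSE))
    sizes <- lengths(keys)
    if (length(uni) == 0L) {
        m <- sparseMatrix(i = integer(), j = integer(),
                          dims = c(length(profiles), 0L))
    } else {
        m <- sparseMatrix(i = rep.int(seq_along(keys), sizes),
                          j = match(unlist(keys, use.names = FALSE), uni),
                          x = 1, dims = c(length(profiles), length(uni)))
    }
    list(m = m, keys = uni, sizes = sizes, keyList = keys)
}

#' Identity matrix over the reads of a pool
#'
#' All-pairs read identity from guide-anchored profiles:
#' `1 - |symmetric difference| / guideLength`, computed with a sparse
#' incidence product. Memory is quadratic in the number of reads.
#'
#' @param profiles list of variant-profile data frames
#' @param guideLength guide length
#' @return dense numeric matrix of identities
#' @export
identityMatrix <- function(profiles, guideLength) {
    inc <- profileIncidence(profiles)
    inter <- as.matrix(tcrossprod(inc$m))
    symdiff <- outer(inc$sizes, inc$sizes, "+") - 2 * inter
    1 - symdiff / guideLength
}

#' Build the pile of a focal read
#'
#' The pile is the focal read plus the `pileSize - 1` reads of highest
#' profile identity to it (capped at `maxAlignmentsPerRead`), ties broken
#' by lexicographic read id for determinism.
#'
#' @param focal index of the focal read
#' @param idMat identity matrix from [identityMatrix()]
#' @param readIds read identifiers
#' @param params a [ClusterParams-class]
#' @return list with `focal`, `members` (indices, focal first, then by
#'   decreasing identity) and `identity`
#' @export
buildPile <- function(focal, idMat, readIds, params) {
    n <- min(params@pileSize, params@maxAlignmentsPerRead, ncol(idMat))
    others <- setdiff(seq_len(ncol(idMat)), focal)
    idv <- idMat[focal, others]
    ord <- others[order(-idv, readIds[others])]
    members <- c(focal, utils::head(ord, n - 1L))
    list(focal = focal, members = members,
         identity = idMat[focal, members])
}

#' Error-correct a focal read against its pile
#'
#' Each variant of the focal read is kept iff its frequency among the pile
#' members reaches `minVarFrequency`; below that it is reverted to the
#' guide allele. Correction only masks: variants common in the pile but
#' absent from the focal read are never introduced. When
#' `homopolymerMaskLength` is set, variants inside guide homopolymer runs
#' longer than that are always masked.
#'
#' @param focalProfile the focal read's variant profile
#' @param pileFreqs named numeric: within-pile frequency of each focal
#'   variant key (see [clusterPool()] for the assembled pipeline)
#' @param params a [ClusterParams-class]
#' @return the corrected variant profile (a subset of the focal rows)
#' @export
errorCorrect <- function(focalProfile, pileFreqs, params) {
    if (is.null(focalProfile) || nrow(focalProfile) == 0L)
        return(focalProfile)
    keys <- profileKeys(focalProfile)
    keep <- pileFreqs[keys] >= params@minVarFrequency
    keep[is.na(keep)] <- FALSE
    if (!is.null(params@homopolymerMaskLength))
        keep <- keep & focalProfile$hp <= params@homopolymerMaskLength
    out <- focalProfile[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Group corrected reads into haplotype clusters
#'
#' Reads with identical corrected profiles form one cluster; the cluster
#' consensus is the guide with the shared profile applied (members are
#' profile-identical by construction, so no second-round consensus is
#' needed). Frequencies are fractions of `totalReads`.
#'
#' @param corrected list of corrected variant profiles
#' @param readIds read identifiers, parallel to `corrected`
#' @param guide the guide sequence
#' @param totalReads frequency denominator (default: number of corrected
#'   reads)
#' @return an unfiltered [HaplotypeClusterSet-class]
#' @export
formClusters <- function(corrected, readIds, guide,
                         totalReads = length(corrected)) {
    guide <- as.character(guide)
    sig <- vapply(corrected, function(p)
        paste(profileKeys(p), collapse = ";"), character(1))
    groups <- split(seq_along(sig), sig)
    ## order clusters by decreasing size, then signature, for stable ids
    ord <- order(-lengths(groups), names(groups))
    groups <- groups[ord]
    n <- length(groups)
    ids <- sprintf("cluster%03d", seq_len(n))
    profiles <- lapply(groups, function(g) corrected[[g[1]]])
    names(profiles) <- ids
    members <- lapply(groups, function(g) sort(readIds[g]))
    names(members) <- ids
    counts <- lengths(groups)
    cons <- DNAStringSet(vapply(profiles, function(p)
        applyProfile(guide, p), character(1)))
    names(cons) <- ids
    meta <- DataFrame(clusterId = ids, readCount = as.integer(counts),
                      frequency = as.numeric(counts) / totalReads,
                      nVariants = vapply(profiles, nrow, integer(1)))
    rownames(meta) <- NULL
    new("HaplotypeClusterSet", consensus = cons, meta = meta,
        profiles = profiles, members = members,
        totalReads = as.integer(totalReads), guide = guide)
}

#' Filter clusters by read count and frequency
#'
#' Keeps clusters with `readCount >= minClusterReadCount` and
#' `frequency >= minClusterFrequency`; removed clusters are listed (with
#' the failed criterion) in the `"removed"` attribute.
#'
#' @param x a [HaplotypeClusterSet-class]
#' @param params a [ClusterParams-class]
#' @return the filtered `HaplotypeClusterSet`
#' @export
filterClusters <- function(x, params) {
    meta <- clusterMeta(x)
    lowCount <- meta$readCount < params@minClusterReadCount
    lowFreq <- meta$frequency < params@minClusterFrequency
    keep <- !(lowCount | lowFreq)
    removed <- data.frame(
        clusterId = meta$clusterId[!keep],
        readCount = meta$readCount[!keep],
        frequency = meta$frequency[!keep],
        reason = ifelse(lowCount[!keep],
                        ifelse(lowFreq[!keep], "count+frequency", "count"),
                        "frequency"),
        stringsAsFactors = FALSE)
    out <- new("HaplotypeClusterSet",
               consensus = x@consensus[keep],
               meta = meta[keep, , drop = FALSE],
               profiles = x@profiles[keep],
               members = x@members[keep],
               totalReads = x@totalReads, guide = x@guide)
    attr(out, "removed") <- removed
    out
}

#' Cluster a pool of reads into haplotypes
#'
#' The full reference-aided clustering pass for one pool: align reads to
#' the guide and profile their variants, drop off-target reads, build the
#' pile of each focal read from the top-identity alignments, error-correct
#' each focal read against its pile's variant frequencies, group identical
#' corrected profiles into clusters, and apply the cluster-level read
#' count and frequency filters.
#'
#' @param reads DNAStringSet (orientation may be mixed)
#' @param guide the guide sequence
#' @param params a [ClusterParams-class], e.g. from
#'   [derivePoolParameters()]
#' @param band alignment band half-width
#' @return a filtered, unannotated [HaplotypeClusterSet-class]; attributes
#'   `"removed"` (cluster filter log) and `"offTarget"` (excluded read
#'   ids)
#' @export
clusterPool <- function(reads, guide, params, band = 24L) {
    if (length(reads) > params@maxReadsPerGuide)
        reads <- reads[seq_len(params@maxReadsPerGuide)]
    aln <- alignToGuide(reads, guide, band = band)
    clusterFromAlignment(aln, guide, params)
}

## Clustering pass over an existing alignToGuide() result; lets callers
## that also need the per-read profiles (e.g. pooled allele-frequency
## calling) align only once.
clusterFromAlignment <- function(aln, guide, params) {
    keep <- aln$onTarget
    profiles <- aln$profiles[keep]
    readIds <- aln$readIds[keep]
    total <- length(profiles)
    if (total == 0L) stop("no on-target reads to cluster")

    inc <- profileIncidence(profiles)
    inter <- as.matrix(tcrossprod(inc$m))
    symdiff <- outer(inc$sizes, inc$sizes, "+") - 2 * inter
    idMat <- 1 - symdiff / aln$guideLength

    corrected <- vector("list", total)
    for (i in seq_len(total)) {
        pile <- buildPile(i, idMat, readIds, params)
        cols <- match(inc$keyList[[i]], inc$keys)
        freqs <- if (length(cols))
            colSums(inc$m[pile$members, cols, drop = FALSE]) /
                length(pile$members)
        else numeric()
        names(freqs) <- inc$keyList[[i]]
        corrected[[i]] <- errorCorrect(profiles[[i]], freqs, params)
    }

    clusters <- formClusters(corrected, readIds, guide, totalReads = total)
    out <- filterClusters(clusters, params)
    attr(out, "offTarget") <- aln$readIds[!keep]
    out
}

#' Cluster export helpers
#'
#' `writeClusterFasta` writes consensus sequences with headers encoding
#' pool id, cluster id, read count and frequency;
#' `clusterTable` returns (and optionally writes) the cluster metadata as
#' a TSV with a provenance header.
#'
#' @param x a [HaplotypeClusterSet-class]
#' @param path output path
#' @param poolId pool label for the headers
#' @param seed seed recorded in the provenance header
#' @export
writeClusterFasta <- function(x, path, poolId = "pool") {
    cons <- consensusSeqs(x)
    meta <- clusterMeta(x)
    names(cons) <- sprintf("%s|%s|reads=%d|freq=%.6f", poolId,
                           meta$clusterId, meta$readCount, meta$frequency)
    writeXStringSet(cons, path)
    invisible(path)
}

#' @rdname writeClusterFasta
#' @export
clusterTable <- function(x, path = NULL, poolId = "pool", seed = NA) {
    meta <- clusterMeta(x)
    df <- data.frame(pool_id = poolId, cluster_id = meta$clusterId,
                     read_count = meta$readCount,
                     frequency = meta$frequency,
                     n_variants = meta$nVariants,
                     tsr_alleles = if (is.null(meta$tsrAlleles)) ""
                                   else meta$tsrAlleles,
                     stringsAsFactors = FALSE)
    if (!is.null(path)) {
        writeLines(provenanceHeader(seed), path)
        suppressWarnings(utils::write.table(df, path, sep = "\t",
            quote = FALSE, row.names = FALSE, append = TRUE))
    }
    df
}
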