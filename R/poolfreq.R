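#' @importFrom stats cor.test
NULL

#' Pooled SNP allele frequencies from read profiles
#'
#' Per-site alternate allele counts over all on-target reads of a pool,
#' with reads counted equally (no depth weighting) and full-length
#' amplicon reads so the depth at every site equals the read count. Sites
#' below `minAltFraction` are suppressed. Each `(pos, ref, alt)` row is
#' biallelic by construction; a multi-allelic site appears as multiple
#' rows.
#'
#' @param profiles list of variant-profile data frames (on-target reads),
#'   e.g. from [alignToGuide()]
#' @param minAltFraction suppression threshold (default 0.005, the pooled
#'   continuous calling convention)
#' @return data frame with columns `pos` (1-based), `ref`, `alt`, `kind`,
#'   `altCount`, `depth`, `frequency`
#' @export
pooledAlleleFrequencies <- function(profiles, minAltFraction = 0.005) {
    profiles <- profiles[!vapply(profiles, function(p)
        length(p) == 1L && is.na(p), logical(1))]
    depth <- length(profiles)
    if (depth == 0L)
        return(data.frame(pos = integer(), ref = character(),
                          alt = character(), kind = character(),
                          altCount = integer(), depth = integer(),
                          frequency = numeric(), stringsAsFactors = FALSE))
    all <- do.call(rbind, profiles[vapply(profiles, nrow, integer(1)) > 0])
    if (is.null(all) || nrow(all) == 0L) {
        out <- data.frame(pos = integer(), ref = character(),
                          alt = character(), kind = character(),
                          altCount = integer(), depth = integer(),
                          frequency = numeric(), stringsAsFactors = FALSE)
        return(out)
    }
    key <- sprintf("%d:%s>%s", all$pos, all$ref, all$alt)
    counts <- table(key)
    first <- all[!duplicated(key), , drop = FALSE]
    firstKey <- sprintf("%d:%s>%s", first$pos, first$ref, first$alt)
    out <- data.frame(pos = first$pos + 1L, ref = first$ref,
                      alt = first$alt, kind = first$kind,
                      altCount = as.integer(counts[firstKey]),
                      depth = depth, stringsAsFactors = FALSE)
    out$frequency <- out$altCount / out$depth
    out <- out[out$frequency >= minAltFraction, , drop = FALSE]
    out <- out[order(out$pos, out$ref, out$alt), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summed pool frequency of a TSR allele across carrier clusters
#'
#' The haplotype-level frequency of a TSR allele: the sum of frequencies
#' of all clusters annotated with that allele. On error-free data this
#' equals the pooled SNP allele frequency at the underlying site.
#'
#' @param x an annotated [HaplotypeClusterSet-class]
#' @param allele a TSR allele name (e.g. `"Ile1781.1Leu_T"`)
#' @return numeric frequency
#' @export
tsrFrequencyFromClusters <- function(x, allele) {
    meta <- clusterMeta(x)
    if (is.null(meta$tsrAlleles))
        stop("clusters are not annotated; run annotateClusters() first")
    carriers <- vapply(strsplit(meta$tsrAlleles, ",", fixed = TRUE),
                       function(a) allele %in% a, logical(1))
    sum(meta$frequency[carriers])
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the p-value from the t-distribution on
#' `n - 2` degrees of freedom. Zero-variance input is reported as
#' undefined rather than an error.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`
#' @return list with `r`, `p`, `n`, and `undefined` flag
#' @export
correlateFrequencies <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(r = NA_real_, p = NA_real_, n = length(x),
                    undefined = TRUE))
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
         undefined = FALSE)
}

#' Benchmark individual-versus-pool haplotype recovery
#'
#' Compares the unique haplotypes observed among individually genotyped
#' plants with the clusters recovered from the pool. A "correct pair" is
#' an exact sequence match between a unique individual haplotype and a
#' pool cluster consensus. TSR pairs are counted among TSR-annotated
#' haplotypes; individual TSR haplotypes without a pool match are
#' "unidentified", pool TSR clusters without an individual match are
#' "additional". Frequency pairs for matched haplotypes are returned for
#' correlation.
#'
#' @param individuals data frame from [sampleIndividuals()]
#' @param haplotypes haplotype sequences (for looking up individual
#'   haplotype ids), as from [spawnHaplotypes()]
#' @param x an annotated pool [HaplotypeClusterSet-class]
#' @param model a [GeneModel-class]
#' @return list with `report` (one-row data frame: `nPoolHaplotypes`,
#'   `nIndividualHaplotypes`, `nCorrectPairs`, `nCorrectTsrPairs`,
#'   `nUnidentifiedTsr`, `nAdditionalTsr`) and `frequencyPairs`
#'   (haplotype, individual frequency, pool frequency, matched flag)
#' @export
benchmarkRecovery <- function(individuals, haplotypes, x, model) {
    meta <- clusterMeta(x)
    if (is.null(meta$tsrAlleles))
        stop("clusters are not annotated; run annotateClusters() first")
    drawn <- c(individuals$hap1, individuals$hap2)
    indIds <- sort(unique(drawn))
    indSeqs <- as.character(haplotypes[indIds])
    indFreq <- as.numeric(table(factor(drawn, levels = indIds))) /
        length(drawn)
    indTsr <- S4Vectors::mcols(haplotypes)$isTsr[
        match(indIds, S4Vectors::mcols(haplotypes)$id)]

    poolSeqs <- as.character(consensusSeqs(x))
    poolTsr <- meta$tsrAlleles != ""

    matchIdx <- match(indSeqs, poolSeqs)
    matched <- !is.na(matchIdx)
    nCorrect <- sum(matched)
    nCorrectTsr <- sum(matched & indTsr)
    nUnidentifiedTsr <- sum(!matched & indTsr)
    nAdditionalTsr <- sum(poolTsr & !(poolSeqs %in% indSeqs))

    report <- data.frame(
        nPoolHaplotypes = length(poolSeqs),
        nIndividualHaplotypes = length(indIds),
        nCorrectPairs = nCorrect,
        nCorrectTsrPairs = nCorrectTsr,
        nUnidentifiedTsr = nUnidentifiedTsr,
        nAdditionalTsr = nAdditionalTsr)
    stopifnot(report$nCorrectPairs <=
                  min(report$nPoolHaplotypes, report$nIndividualHaplotypes))
    freqPairs <- data.frame(
        haplotype = indIds,
        individualFrequency = indFreq,
        poolFrequency = ifelse(matched, meta$frequency[matchIdx], 0),
        matched = matched, isTsr = indTsr,
        stringsAsFactors = FALSE)
    list(report = report, frequencyPairs = freqPairs)
}

#' Recovery rate stratified by carrier count
#'
#' For each haplotype among the genotyped individuals, counts its carrier
#' individuals and reports the fraction recovered in the pool within the
#' strata 1, 2--3 and >= 4 carriers.
#'
#' @param individuals data frame from [sampleIndividuals()]
#' @param recovered logical named by haplotype id (or a
#'   `frequencyPairs` data frame from [benchmarkRecovery()])
#' @return data frame with columns `carriers`, `nHaplotypes`,
#'   `nRecovered`, `rate`
#' @export
recoveryByCarrierCount <- function(individuals, recovered) {
    if (is.data.frame(recovered))
        recovered <- stats::setNames(recovered$matched, recovered$haplotype)
    perHap <- lapply(split(rbind(
        data.frame(hap = individuals$hap1, ind = individuals$individual),
        data.frame(hap = individuals$hap2, ind = individuals$individual)),
        ~hap), function(d) length(unique(d$ind)))
    carriers <- unlist(perHap)
    stratum <- cut(carriers, breaks = c(0, 1, 3, Inf),
                   labels = c("1", "2-3", ">=4"))
    rec <- recovered[names(carriers)]
    rec[is.na(rec)] <- FALSE
    agg <- lapply(split(rec, stratum), function(r)
        c(n = length(r), nRec = sum(r)))
    data.frame(carriers = names(agg),
               nHaplotypes = vapply(agg, `[[`, numeric(1), "n"),
               nRecovered = vapply(agg, `[[`, numeric(1), "nRec"),
               rate = vapply(agg, function(a)
                   if (a["n"] == 0) NA_real_ else a["nRec"] / a["n"],
                   numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
}
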