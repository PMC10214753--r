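#' @importFrom stats rbinom qt sd
NULL

## Deterministic part of one generation: the expected next-generation
## allele frequency under viability selection with genotype fitnesses
## w_AA = 1+s (carrier homozygote), w_Aa = 1+h*s, w_aa = 1.
expectedFrequency <- function(p, s, h) {
    q <- 1 - p
    wAA <- 1 + s; wAa <- 1 + h * s
    wbar <- p^2 * wAA + 2 * p * q * wAa + q^2
    if (wbar <= 0) stop("mean fitness is non-positive")
    p * (p * wAA + q * wAa) / wbar
}

#' One Wright-Fisher generation
#'
#' Applies selection deterministically (genotype fitnesses `1 + s`,
#' `1 + h * s`, `1`) and then binomial sampling of `2N` allele copies:
#' the exact marginal allele-count process of a diploid Wright-Fisher
#' population at a single biallelic locus.
#'
#' @param alleleCount current allele copies, in `0..2N`
#' @param params a [wfParams()]
#' @return next generation's allele count
#' @export
wfStep <- function(alleleCount, params) {
    twoN <- 2L * params@N
    stopifnot(alleleCount >= 0L, alleleCount <= twoN)
    if (alleleCount == 0L) return(0L)
    if (alleleCount == twoN && params@s == 0) return(twoN)
    pstar <- expectedFrequency(alleleCount / twoN, params@s, params@h)
    rbinom(1L, twoN, pstar)
}

#' Simulate allele trajectories to loss or fixation
#'
#' Runs `replicates` independent trajectories from
#' `round(p0 * 2N)` copies until the allele count first hits 0 (lost) or
#' `2N` (fixed), or the generation cap (censored). The initial state is
#' generation 0. Replicate `i` uses seed `seed + i - 1`.
#'
#' @param params a [wfParams()]
#' @return data frame with columns `replicate`, `generations`, `fate`
#' @export
simulateToLoss <- function(params) {
    twoN <- 2L * params@N
    start <- as.integer(round(params@p0 * twoN))
    out <- data.frame(replicate = seq_len(params@replicates),
                      generations = NA_integer_, fate = NA_character_,
                      stringsAsFactors = FALSE)
    for (r in seq_len(params@replicates)) {
        set.seed((params@seed + r - 1L) %% 2147483647L)
        count <- start
        gen <- 0L
        fate <- NULL
        repeat {
            if (count == 0L) { fate <- "lost"; break }
            if (count == twoN) { fate <- "fixed"; break }
            if (gen >= params@maxGenerations) { fate <- "censored"; break }
            count <- wfStep(count, params)
            gen <- gen + 1L
        }
        out$generations[r] <- gen
        out$fate[r] <- fate
    }
    out
}

#' Summarize time-to-loss outcomes
#'
#' Mean generations to loss over the lost replicates with a t-based 0.95
#' confidence interval; fixed and censored replicates are counted
#' separately and excluded from the mean. With no lost replicates the
#' mean is reported as undefined.
#'
#' @param outcomes data frame from [simulateToLoss()]
#' @param level confidence level (default 0.95)
#' @return one-row data frame: `nLost`, `nFixed`, `nCensored`,
#'   `meanGenerations`, `ciLow`, `ciHigh`
#' @export
summarizeLoss <- function(outcomes, level = 0.95) {
    stopifnot(nrow(outcomes) >= 1L)
    lost <- outcomes$generations[outcomes$fate == "lost"]
    nLost <- length(lost)
    if (nLost == 0L) {
        m <- NA_real_; lo <- NA_real_; hi <- NA_real_
    } else {
        m <- mean(lost)
        if (nLost == 1L || sd(lost) == 0) {
            lo <- m; hi <- m
        } else {
            half <- qt(1 - (1 - level) / 2, df = nLost - 1L) *
                sd(lost) / sqrt(nLost)
            lo <- m - half; hi <- m + half
        }
    }
    data.frame(nLost = nLost,
               nFixed = sum(outcomes$fate == "fixed"),
               nCensored = sum(outcomes$fate == "censored"),
               meanGenerations = m, ciLow = lo, ciHigh = hi)
}

#' Sweep a grid of selection, dominance and starting frequency
#'
#' One [simulateToLoss()] + [summarizeLoss()] row per `(s, h, p0)`
#' combination. The default grid covers s from 0 to -0.4, codominant
#' (0.5) and recessive-leaning (0.25) dominance, and starting frequencies
#' 0.05, 0.1, 0.4 and 0.7, with 400 replicates per combination.
#'
#' @param s,h,p0 grid values
#' @param N diploid population size
#' @param replicates replicates per combination
#' @param maxGenerations censoring cap
#' @param seed base seed; combination `i` offsets it by
#'   `(i - 1) * replicates`
#' @return data frame with one summary row per combination
#' @export
persistenceSweep <- function(s = c(0, -0.1, -0.2, -0.3, -0.4),
                             h = c(0.5, 0.25),
                             p0 = c(0.05, 0.1, 0.4, 0.7),
                             N = 42000L, replicates = 400L,
                             maxGenerations = 100000L, seed = 1L) {
    grid <- expand.grid(s = s, h = h, p0 = p0, KEEP.OUT.ATTRS = FALSE)
    stopifnot(nrow(grid) >= 1L)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        p <- wfParams(N = N, s = grid$s[i], h = grid$h[i], p0 = grid$p0[i],
                      replicates = replicates,
                      maxGenerations = maxGenerations,
                      seed = (seed + (i - 1L) * replicates) %% 2147483647L)
        cbind(grid[i, , drop = FALSE], replicates = replicates,
              summarizeLoss(simulateToLoss(p)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Deterministic (infinite-population) time to quasi-loss
#'
#' Iterates the expected-frequency recursion from `p0` until the
#' frequency falls below `1 / (2N)`, the deterministic analogue of loss
#' in a population of `N` diploids; an independent check of the
#' stochastic means under strong selection. Requires `s < 0` (under
#' neutrality the recursion never declines).
#'
#' @param params a [wfParams()]
#' @return number of generations until `p < 1/(2N)`
#' @export
deterministicRecursion <- function(params) {
    if (params@s >= 0)
        stop("deterministic recursion requires s < 0")
    thresh <- 1 / (2 * params@N)
    p <- params@p0
    gen <- 0L
    while (p >= thresh) {
        p <- expectedFrequency(p, params@s, params@h)
        gen <- gen + 1L
        if (gen > 10000000L) stop("recursion failed to reach loss")
    }
    gen
}

#' Write a persistence summary as TSV
#'
#' @param summary data frame from [persistenceSweep()]
#' @param path output path
#' @param seed seed recorded in the provenance header
#' @export
writePersistenceTable <- function(summary, path, seed = NA) {
    writeLines(provenanceHeader(seed), path)
    suppressWarnings(utils::write.table(summary, path, sep = "\t",
        quote = FALSE, row.names = FALSE, append = TRUE))
    invisible(path)
}
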