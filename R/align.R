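#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @useDynLib pilepool, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Precomputed per-guide data reused across many read alignments.
guideIndex <- function(guide, k = 13L) {
    guide <- as.character(guide)
    chars <- strsplit(guide, "", fixed = TRUE)[[1]]
    n <- length(chars)
    starts <- seq_len(n - k + 1L)
    kmers <- substring(guide, starts, starts + k - 1L)
    list(seq = guide, chars = chars, hp = homopolymerRuns(guide),
         k = k, kmers = unique(kmers), length = n)
}

## Shared-k-mer vote between a read and the guide, both orientations.
orientReads <- function(seqs, gidx, sampleEvery = 17L) {
    vapply(seqs, function(s) {
        n <- nchar(s)
        if (n < gidx$k) return(NA)
        starts <- seq(1L, n - gidx$k + 1L, by = sampleEvery)
        fwd <- sum(substring(s, starts, starts + gidx$k - 1L) %in% gidx$kmers)
        rcs <- as.character(reverseComplement(DNAString(s)))
        rev <- sum(substring(rcs, starts, starts + gidx$k - 1L) %in% gidx$kmers)
        rev > fwd
    }, logical(1), USE.NAMES = FALSE)
}

#' Align reads to the guide and express them as variant profiles
#'
#' The reference-aided front end of the clustering workflow: read
#' orientation is detected by a shared k-mer vote against the guide, each
#' read is globally aligned with affine gap penalties (banded dynamic
#' programming), and the alignment is reduced to a normalized,
#' left-aligned variant profile with per-variant homopolymer context.
#' Reads with alignment identity below `minIdentity` are flagged off-target
#' and carry an `NA` profile; downstream clustering excludes them.
#'
#' @param reads a named character vector or [Biostrings::DNAStringSet]
#' @param guide guide sequence (character or `DNAString`)
#' @param minIdentity alignment-column identity below which a read is
#'   called off-target (default 0.5)
#' @param band band half-width of the alignment (default 24; widened
#'   automatically by the read/guide length difference)
#' @return a list with elements `profiles` (list of variant-profile data
#'   frames, `NA` for off-target reads), `identity`, `reverse` (logical,
#'   read was reverse-complemented), `onTarget` (logical), and `readIds`
#' @export
alignToGuide <- function(reads, guide, minIdentity = 0.5, band = 24L) {
    seqs <- as.character(reads)
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
    gidx <- guideIndex(guide)

    rev <- orientReads(seqs, gidx)
    rev[is.na(rev)] <- FALSE
    if (any(rev))
        seqs[rev] <- as.character(reverseComplement(DNAStringSet(seqs[rev])))

    profiles <- vector("list", length(seqs))
    identity <- numeric(length(seqs))
    for (i in seq_along(seqs)) {
        aln <- banded_align_cpp(seqs[i], gidx$seq, band = band)
        pa <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
        sa <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
        identity[i] <- sum(pa == sa) / length(pa)
        profiles[[i]] <- if (identity[i] >= minIdentity)
            profileFromAlignment(aln$pattern, aln$subject, gidx$chars, gidx$hp)
        else NA
    }
    onTarget <- identity >= minIdentity
    list(profiles = profiles, identity = identity, reverse = rev,
         onTarget = onTarget, readIds = ids, guideLength = gidx$length)
}
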