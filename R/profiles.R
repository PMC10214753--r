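#' @importFrom stats setNames
NULL

## A variant profile expresses one read or haplotype as its differences from
## the guide: a data.frame with columns
##   pos  - 0-based guide coordinate (for indels: the anchor base)
##   ref  - guide allele (anchor included for indels, VCF style)
##   alt  - alternate allele
##   kind - "SNV", "ins" or "del"
##   hp   - homopolymer run length in the guide at the site
## Rows are sorted by pos; an unmutated read has a 0-row profile.

emptyProfile <- function() {
    data.frame(pos = integer(), ref = character(), alt = character(),
               kind = character(), hp = integer(), stringsAsFactors = FALSE)
}

#' Variant keys of a profile
#'
#' One string per variant (`pos:ref>alt`, 0-based), used for profile
#' comparison and clustering.
#'
#' @param profile a variant-profile data frame
#' @return character vector of keys
#' @export
profileKeys <- function(profile) {
    if (is.null(profile) || nrow(profile) == 0L) return(character())
    sprintf("%d:%s>%s", profile$pos, profile$ref, profile$alt)
}

#' Number of differing variants between two profiles
#'
#' The size of the symmetric difference of the two variant sets; exact for
#' profiles called against the same guide.
#'
#' @param a,b variant-profile data frames
#' @return integer distance
#' @export
profileDistance <- function(a, b) {
    ka <- profileKeys(a); kb <- profileKeys(b)
    length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Alignment-free read-to-read identity from guide-anchored profiles
#'
#' `1 - |symmetric difference of variant sets| / guideLength`. At the
#' divergences of high-fidelity amplicon reads (>99% identity to the guide)
#' this ranks read pairs identically to direct pairwise alignment.
#'
#' @param a,b variant-profile data frames over the same guide
#' @param guideLength guide length in bases
#' @return identity in `[0, 1]`
#' @export
pairwiseIdentity <- function(a, b, guideLength) {
    1 - profileDistance(a, b) / guideLength
}

#' Apply a variant profile to the guide sequence
#'
#' Reconstructs the haplotype sequence a profile describes. Inverse of
#' variant calling: `callVariants(applyProfile(guide, p), guide)` returns
#' `p` for normalized profiles.
#'
#' @param guide guide sequence (character or [Biostrings::DNAString])
#' @param profile a variant-profile data frame
#' @return character sequence
#' @export
applyProfile <- function(guide, profile) {
    guide <- as.character(guide)
    if (is.null(profile) || nrow(profile) == 0L) return(guide)
    ch <- strsplit(guide, "", fixed = TRUE)[[1]]
    out <- as.list(ch)
    profile <- profile[order(profile$pos), , drop = FALSE]
    for (i in seq_len(nrow(profile))) {
        p1 <- profile$pos[i] + 1L          # 1-based index of ref start
        ref <- profile$ref[i]; alt <- profile$alt[i]
        stopifnot(substr(guide, p1, p1 + nchar(ref) - 1L) == ref)
        out[[p1]] <- alt
        if (nchar(ref) > 1L)
            for (j in seq(p1 + 1L, p1 + nchar(ref) - 1L)) out[[j]] <- ""
    }
    paste(unlist(out), collapse = "")
}

## Per-position homopolymer run length of a sequence, as an integer vector.
homopolymerRuns <- function(seq) {
    ch <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
    r <- rle(ch)
    rep.int(r$lengths, r$lengths)
}

## Left-align an indel: shift start left while the base entering the event
## window equals the base leaving it (standard VCF normalization). pos is
## the 0-based anchor, ref/alt anchored strings.
leftAlignIndel <- function(guideChars, pos, ref, alt) {
    longer <- if (nchar(ref) > nchar(alt)) ref else alt
    allele <- substr(longer, 2L, nchar(longer))     # inserted/deleted bases
    alen <- nchar(allele)
    while (pos > 0L) {
        lastBase <- substr(allele, alen, alen)
        anchorBase <- guideChars[pos + 1L]          # base at 0-based pos
        if (anchorBase != lastBase) break
        allele <- paste0(anchorBase, substr(allele, 1L, alen - 1L))
        pos <- pos - 1L
    }
    anchor <- guideChars[pos + 1L]
    if (nchar(ref) > nchar(alt)) {
        list(pos = pos, ref = paste0(anchor, allele), alt = anchor)
    } else {
        list(pos = pos, ref = anchor, alt = paste0(anchor, allele))
    }
}

## Extract a normalized variant profile from a gapped alignment
## (pattern = read, subject = guide). guideChars/guideHp are precomputed
## from the guide for speed.
profileFromAlignment <- function(patternAln, subjectAln, guideChars, guideHp) {
    pa <- strsplit(patternAln, "", fixed = TRUE)[[1]]
    sa <- strsplit(subjectAln, "", fixed = TRUE)[[1]]
    gcol <- cumsum(sa != "-")           # 1-based guide position per column
    state <- ifelse(pa == "-", "D", ifelse(sa == "-", "I", "M"))

    out <- list()
    ## substitutions
    snv <- which(state == "M" & pa != sa)
    if (length(snv)) {
        pos0 <- gcol[snv] - 1L
        out[[length(out) + 1L]] <- data.frame(
            pos = pos0, ref = sa[snv], alt = pa[snv], kind = "SNV",
            hp = guideHp[pos0 + 1L], stringsAsFactors = FALSE)
    }
    ## indel runs
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values != "M")) {
        cols <- starts[i]:ends[i]
        if (r$values[i] == "D") {                 # gap in read: deletion
            delBases <- paste(sa[cols], collapse = "")
            anchor0 <- gcol[starts[i]] - 2L       # 0-based base before event
            if (anchor0 < 0L) next                # terminal event, skip
            v <- leftAlignIndel(guideChars, anchor0,
                                paste0(guideChars[anchor0 + 1L], delBases),
                                guideChars[anchor0 + 1L])
            kind <- "del"
        } else {                                  # gap in guide: insertion
            insBases <- paste(pa[cols], collapse = "")
            anchor0 <- gcol[starts[i]] - 1L       # 0-based guide base before gap
            if (anchor0 < 0L) next
            v <- leftAlignIndel(guideChars, anchor0,
                                guideChars[anchor0 + 1L],
                                paste0(guideChars[anchor0 + 1L], insBases))
            kind <- "ins"
        }
        hpPos <- min(v$pos + 2L, length(guideHp))  # first affected base
        out[[length(out) + 1L]] <- data.frame(
            pos = v$pos, ref = v$ref, alt = v$alt, kind = kind,
            hp = guideHp[hpPos], stringsAsFactors = FALSE)
    }
    if (!length(out)) return(emptyProfile())
    prof <- do.call(rbind, out)
    prof <- prof[order(prof$pos, prof$ref, prof$alt), , drop = FALSE]
    rownames(prof) <- NULL
    prof
}
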