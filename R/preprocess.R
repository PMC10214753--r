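#' @importFrom Biostrings subseq quality PhredQuality
NULL

#' Predicted read accuracy from per-base qualities
#'
#' One minus the mean per-base error probability implied by the Phred
#' scores, the "predicted accuracy" convention of consensus reads (q30
#' corresponds to 0.999).
#'
#' @param reads DNAStringSet with qualities in `mcols(x)$quality`
#' @return numeric vector of per-read predicted accuracies
#' @export
predictedAccuracy <- function(reads) {
    q <- S4Vectors::mcols(reads)$quality
    if (is.null(q)) stop("reads carry no qualities in mcols(reads)$quality")
    errs <- lapply(as.character(q), function(s)
        10^(-(utf8ToInt(s) - 33L) / 10))
    vapply(errs, function(e) 1 - mean(e), numeric(1))
}

#' Filter reads by predicted accuracy
#'
#' Keeps exactly the reads whose predicted accuracy reaches the threshold
#' (default q30 = 0.999); the removal count is attached as the
#' `"report"` attribute.
#'
#' @param reads DNAStringSet with qualities in `mcols(x)$quality`
#' @param minAccuracy threshold in (0, 1]
#' @return filtered reads
#' @export
filterByAccuracy <- function(reads, minAccuracy = 0.999) {
    stopifnot(minAccuracy > 0, minAccuracy <= 1)
    if (length(reads) == 0L) {
        attr(reads, "report") <- data.frame(input = 0L, kept = 0L,
                                            removed = 0L)
        return(reads)
    }
    keep <- predictedAccuracy(reads) >= minAccuracy
    out <- reads[keep]
    attr(out, "report") <- data.frame(input = length(reads),
                                      kept = sum(keep),
                                      removed = sum(!keep))
    out
}

hammingDist <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Assign pooled reads to pools by terminal dual barcodes
#'
#' A simplified dual-barcode matcher: a read is assigned to a pool iff its
#' 5' end matches the pool's forward barcode and its 3' end the reverse
#' complement of the pool's reverse barcode, each within `maxMismatch`
#' (both read orientations are checked). Assigned reads are trimmed of
#' their barcodes (and re-oriented to barcode-forward); unassigned reads
#' are returned separately. Barcode pairs closer than `2 * maxMismatch`
#' in Hamming distance are rejected at configuration time.
#'
#' @param reads DNAStringSet with qualities in `mcols(x)$quality`
#' @param barcodes data frame with columns `pool_id`, `bc5`, `bc3`
#' @param maxMismatch maximum mismatches tolerated per barcode (default 1)
#' @return list with `pools` (named list of trimmed read sets),
#'   `unassigned`, and a per-pool count `report`
#' @export
demultiplex <- function(reads, barcodes, maxMismatch = 1L) {
    stopifnot(all(c("pool_id", "bc5", "bc3") %in% names(barcodes)))
    nb <- nrow(barcodes)
    if (nb > 1L) {
        for (i in seq_len(nb - 1L)) for (j in seq(i + 1L, nb)) {
            d5 <- hammingDist(barcodes$bc5[i], barcodes$bc5[j])
            d3 <- hammingDist(barcodes$bc3[i], barcodes$bc3[j])
            if (min(d5, d3) <= 2L * maxMismatch)
                stop("barcode collision between pools ", barcodes$pool_id[i],
                     " and ", barcodes$pool_id[j],
                     ": pairs must differ at > 2*maxMismatch positions")
        }
    }
    quals <- S4Vectors::mcols(reads)$quality
    seqs <- as.character(reads)
    qstr <- as.character(quals)
    ids <- names(reads)
    rc3 <- vapply(barcodes$bc3, function(b)
        as.character(reverseComplement(DNAString(b))), character(1))

    assign <- rep(NA_integer_, length(seqs))
    flipped <- logical(length(seqs))
    for (i in seq_along(seqs)) {
        s <- seqs[i]
        srev <- NULL
        for (b in seq_len(nb)) {
            n5 <- nchar(barcodes$bc5[b]); n3 <- nchar(barcodes$bc3[b])
            if (nchar(s) < n5 + n3) next
            if (hammingDist(substr(s, 1L, n5), barcodes$bc5[b]) <= maxMismatch &&
                hammingDist(substr(s, nchar(s) - n3 + 1L, nchar(s)),
                            rc3[b]) <= maxMismatch) {
                assign[i] <- b; break
            }
            if (is.null(srev))
                srev <- as.character(reverseComplement(DNAString(s)))
            if (hammingDist(substr(srev, 1L, n5), barcodes$bc5[b]) <= maxMismatch &&
                hammingDist(substr(srev, nchar(srev) - n3 + 1L, nchar(srev)),
                            rc3[b]) <= maxMismatch) {
                assign[i] <- b; flipped[i] <- TRUE; break
            }
        }
    }

    pools <- stats::setNames(vector("list", nb), barcodes$pool_id)
    for (b in seq_len(nb)) {
        idx <- which(assign == b)
        n5 <- nchar(barcodes$bc5[b]); n3 <- nchar(barcodes$bc3[b])
        s <- seqs[idx]; q <- qstr[idx]
        fl <- flipped[idx]
        if (any(fl)) {
            s[fl] <- as.character(reverseComplement(DNAStringSet(s[fl])))
            q[fl] <- vapply(q[fl], function(x)
                intToUtf8(rev(utf8ToInt(x))), character(1))
        }
        len <- nchar(s)
        s <- substr(s, n5 + 1L, len - n3)
        q <- substr(q, n5 + 1L, len - n3)
        out <- DNAStringSet(s)
        names(out) <- ids[idx]
        S4Vectors::mcols(out)$quality <- BStringSet(q)
        pools[[b]] <- out
    }
    un <- reads[is.na(assign)]
    list(pools = pools, unassigned = un,
         report = data.frame(pool_id = c(barcodes$pool_id, "unassigned"),
                             reads = c(vapply(pools, length, integer(1)),
                                       length(un))))
}

#' Attach pool barcodes to simulated reads
#'
#' The inverse of [demultiplex()], used when simulating a multiplexed run:
#' prepends `bc5` and appends the reverse complement of `bc3`, with maximal
#' qualities on the barcode bases.
#'
#' @param reads DNAStringSet with qualities in `mcols(x)$quality`
#' @param bc5,bc3 barcode sequences
#' @return barcoded reads
#' @export
attachBarcodes <- function(reads, bc5, bc3) {
    rc3 <- as.character(reverseComplement(DNAString(bc3)))
    s <- paste0(bc5, as.character(reads), rc3)
    q <- paste0(strrep("I", nchar(bc5)),
                as.character(S4Vectors::mcols(reads)$quality),
                strrep("I", nchar(bc3)))
    out <- DNAStringSet(s)
    names(out) <- names(reads)
    S4Vectors::mcols(out)$quality <- BStringSet(q)
    out
}

#' Normalize pools to a common read depth
#'
#' Subsamples each pool without replacement to exactly `targetReads`
#' (default: the smallest pool size) so haplotype frequencies are
#' comparable across pools. Pools with fewer reads than the target are
#' excluded, not truncated, and listed in the report.
#'
#' @param pools named list of read sets (DNAStringSet with qualities)
#' @param targetReads target read count per pool; `NULL` uses the minimum
#'   pool size
#' @param seed integer seed for the subsampling
#' @return list with `pools` (normalized, excluded pools dropped) and
#'   `report` (per-pool input size, action, output size)
#' @export
normalizePools <- function(pools, targetReads = NULL, seed = 1L) {
    sizes <- vapply(pools, length, integer(1))
    if (is.null(targetReads)) targetReads <- min(sizes)
    stopifnot(targetReads > 0)
    set.seed(seed)
    out <- list()
    action <- character(length(pools))
    for (i in seq_along(pools)) {
        if (sizes[i] < targetReads) {
            action[i] <- "excluded"
        } else if (sizes[i] == targetReads) {
            action[i] <- "unchanged"
            out[[names(pools)[i]]] <- pools[[i]]
        } else {
            action[i] <- "subsampled"
            keep <- sort(sample.int(sizes[i], targetReads))
            out[[names(pools)[i]]] <- pools[[i]][keep]
        }
    }
    list(pools = out,
         report = data.frame(pool_id = names(pools), input = sizes,
                             target = targetReads, action = action,
                             output = ifelse(action == "excluded", 0L,
                                             as.integer(targetReads)),
                             stringsAsFactors = FALSE))
}
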