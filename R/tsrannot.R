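#' @importFrom Biostrings GENETIC_CODE AMINO_ACID_CODE
NULL

#' Known ACCase target-site resistance codons
#'
#' The seven codons of the plastidic acetyl-CoA carboxylase at which
#' amino-acid substitutions confer resistance to ACCase-inhibiting
#' herbicides, all in the penultimate exon, with their wild-type residues.
#'
#' @return data frame with columns `codon` and `wtAA` (one-letter)
#' @export
tsrSites <- function() {
    data.frame(codon = c(1781L, 1999L, 2027L, 2041L, 2078L, 2088L, 2096L),
               wtAA = c("I", "W", "W", "I", "D", "C", "G"),
               stringsAsFactors = FALSE)
}

aaThree <- function(aa1) {
    ifelse(aa1 == "*", "Ter", unname(AMINO_ACID_CODE[aa1]))
}
aaOne <- function(aa3) {
    ifelse(aa3 == "Ter", "*",
           names(AMINO_ACID_CODE)[match(aa3, AMINO_ACID_CODE)])
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Format / parse TSR allele names
#'
#' Allele names follow the convention
#' `{wild-type AA}{codon}.{codon position}{new AA}_{alternate base}`,
#' e.g. `Ile1781.1Leu_T`: an A-to-T change at the first position of codon
#' 1781 replacing isoleucine with leucine. The alternate base is given in
#' CDS orientation. `parseTsrAllele` is the exact inverse.
#'
#' @param wtAA,newAA three-letter amino acid codes (`Ter` for stop)
#' @param codon TSR codon number
#' @param codonPos position within the codon (1--3)
#' @param altBase alternate base (CDS orientation)
#' @return `formatTsrAllele`: the allele name; `parseTsrAllele`: a list
#'   with fields `wtAA`, `codon`, `codonPos`, `newAA`, `altBase`
#' @export
formatTsrAllele <- function(wtAA, codon, codonPos, newAA, altBase) {
    sprintf("%s%d.%d%s_%s", wtAA, as.integer(codon), as.integer(codonPos),
            newAA, altBase)
}

#' @rdname formatTsrAllele
#' @param name an allele name
#' @export
parseTsrAllele <- function(name) {
    m <- regmatches(name, regexec(
        "^([A-Z][a-z]{2})(\\d+)\\.([123])([A-Z][a-z]{2})_([ACGT])$", name))[[1]]
    if (length(m) != 6L) stop("not a valid TSR allele name: ", name)
    list(wtAA = m[2], codon = as.integer(m[3]), codonPos = as.integer(m[4]),
         newAA = m[5], altBase = m[6])
}

## Annotation of a single-base change at a named TSR codon. codonPos and
## altBase are in CDS orientation; returns amplicon-coordinate fields used
## by the haplotype generator as well as the allele name.
codonChangeAnnotation <- function(model, guide, codonNumber, codonPos,
                                  altBase) {
    guide <- as.character(guide)
    iv <- tsrCodons(model)[as.character(codonNumber)]
    if (length(iv) == 0L || is.na(start(iv)))
        stop("gene model has no codon ", codonNumber)
    s0 <- start(iv)
    ampCodon <- substr(guide, s0 + 1L, s0 + 3L)
    if (geneStrand(model) == "+") {
        codonSeq <- ampCodon
        ampPos0 <- s0 + codonPos - 1L
        ampAlt <- altBase
    } else {
        codonSeq <- as.character(reverseComplement(DNAString(ampCodon)))
        ampPos0 <- s0 + (3L - codonPos)
        ampAlt <- unname(COMPLEMENT[altBase])
    }
    refBase <- substr(codonSeq, codonPos, codonPos)
    if (refBase == altBase)
        stop("alternate base equals the wild-type base at codon ",
             codonNumber, " position ", codonPos)
    newCodon <- codonSeq
    substr(newCodon, codonPos, codonPos) <- altBase
    wtAA <- unname(GENETIC_CODE[codonSeq])
    newAA <- unname(GENETIC_CODE[newCodon])
    list(name = formatTsrAllele(aaThree(wtAA), codonNumber, codonPos,
                                aaThree(newAA), altBase),
         codon = as.integer(codonNumber), codonPos = as.integer(codonPos),
         wtAA = wtAA, newAA = newAA, synonymous = wtAA == newAA,
         pos = ampPos0, refBase = substr(guide, ampPos0 + 1L, ampPos0 + 1L),
         altBase = ampAlt, cdsAlt = altBase)
}

#' Call variants on a consensus sequence against the guide
#'
#' Same alignment and normalization rules as [alignToGuide()], for a single
#' sequence; used to re-profile cluster consensus sequences and individual
#' haplotypes.
#'
#' @param consensus a sequence (character or `DNAString`)
#' @param guide the guide sequence
#' @param band alignment band half-width
#' @return a variant-profile data frame
#' @export
callVariants <- function(consensus, guide, band = 24L) {
    res <- alignToGuide(stats::setNames(as.character(consensus), "consensus"),
                        guide, band = band)
    if (!res$onTarget[1]) stop("consensus is off-target against the guide")
    res$profiles[[1]]
}

#' Annotate TSR codon changes in a variant profile
#'
#' Maps each variant through the gene model: SNVs inside a TSR codon are
#' translated (strand-aware) and reported as TSR annotations when the amino
#' acid changes; synonymous codon changes are reported separately and never
#' counted as TSR. Frameshift indels inside the CDS are flagged disruptive
#' rather than named.
#'
#' @param profile a variant-profile data frame
#' @param model a [GeneModel-class]
#' @param guide the guide sequence
#' @return list with data frames `tsr` (columns `alleleName`, `codon`,
#'   `codonPos`, `altBase`, `wtAA`, `newAA`, `spectrum`, `uncharacterized`),
#'   `synonymous`, and `disruptive` (frameshift indels in the CDS)
#' @export
annotateTsr <- function(profile, model, guide) {
    guide <- as.character(guide)
    cod <- tsrCodons(model)
    emptyAnn <- data.frame(alleleName = character(), codon = integer(),
                           codonPos = integer(), altBase = character(),
                           wtAA = character(), newAA = character(),
                           spectrum = character(), uncharacterized = logical(),
                           stringsAsFactors = FALSE)
    out <- list(tsr = emptyAnn, synonymous = emptyAnn,
                disruptive = emptyProfile())
    if (is.null(profile) || !is.data.frame(profile) || nrow(profile) == 0L)
        return(out)

    ex <- exons(model)
    inCds <- function(pos0) any(pos0 >= start(ex) & pos0 < start(ex) + width(ex))

    for (i in seq_len(nrow(profile))) {
        v <- profile[i, ]
        if (v$kind != "SNV") {
            netLen <- nchar(v$alt) - nchar(v$ref)
            if (inCds(v$pos + 1L) && netLen %% 3L != 0L)
                out$disruptive <- rbind(out$disruptive, v)
            next
        }
        hit <- which(v$pos >= start(cod) & v$pos < start(cod) + 3L)
        if (length(hit) != 1L) next
        s0 <- start(cod)[hit]
        codonNumber <- as.integer(names(cod)[hit])
        if (geneStrand(model) == "+") {
            codonPos <- v$pos - s0 + 1L
            cdsAlt <- v$alt
        } else {
            codonPos <- s0 + 3L - v$pos      # amplicon offset 0,1,2 -> 3,2,1
            cdsAlt <- unname(COMPLEMENT[v$alt])
        }
        ann <- codonChangeAnnotation(model, guide, codonNumber, codonPos,
                                     cdsAlt)
        spec <- resistanceSpectrum(ann)
        row <- data.frame(alleleName = ann$name, codon = ann$codon,
                          codonPos = ann$codonPos, altBase = ann$cdsAlt,
                          wtAA = ann$wtAA, newAA = ann$newAA,
                          spectrum = paste(spec$classes, collapse = ","),
                          uncharacterized = spec$uncharacterized,
                          stringsAsFactors = FALSE)
        if (ann$synonymous) out$synonymous <- rbind(out$synonymous, row)
        else out$tsr <- rbind(out$tsr, row)
    }
    out
}

#' Herbicide classes a TSR substitution confers resistance to
#'
#' Lookup of the published cross-resistance spectra: Ile1781Leu and
#' Asp2078Gly confer resistance to all three classes of ACCase inhibitors;
#' Trp2027Cys and Ile2041Asn to FOPs and DENs; any substitution of Gly2096
#' to FOPs only. Substitutions without a characterized spectrum return an
#' empty set flagged `uncharacterized`.
#'
#' @param annotation an annotation list from [codonChangeAnnotation] /
#'   a row of [annotateTsr()] output, or a TSR allele name string
#' @return list with `classes` (subset of `c("FOPs","DIMs","DENs")`) and
#'   `uncharacterized` flag
#' @export
resistanceSpectrum <- function(annotation) {
    if (is.character(annotation) && length(annotation) == 1L) {
        p <- parseTsrAllele(annotation)
        annotation <- list(codon = p$codon, wtAA = aaOne(p$wtAA),
                           newAA = aaOne(p$newAA), synonymous = FALSE)
    }
    key <- paste0(aaThree(annotation$wtAA), annotation$codon,
                  aaThree(annotation$newAA))
    known <- list(
        "Ile1781Leu" = c("FOPs", "DIMs", "DENs"),
        "Asp2078Gly" = c("FOPs", "DIMs", "DENs"),
        "Trp2027Cys" = c("FOPs", "DENs"),
        "Ile2041Asn" = c("FOPs", "DENs"))
    if (key %in% names(known))
        return(list(classes = known[[key]], uncharacterized = FALSE))
    if (annotation$codon == 2096L && annotation$wtAA != annotation$newAA)
        return(list(classes = "FOPs", uncharacterized = FALSE))
    list(classes = character(), uncharacterized = TRUE)
}

#' Annotate the clusters of a pool with TSR alleles
#'
#' Runs [annotateTsr()] on every cluster profile and records the allele
#' names in the cluster metadata (`tsrAlleles`, comma-joined; empty string
#' for wild-type clusters) together with the full annotation tables.
#'
#' @param x a [HaplotypeClusterSet-class]
#' @param model a [GeneModel-class]
#' @return the annotated `HaplotypeClusterSet`
#' @export
annotateClusters <- function(x, model) {
    anns <- lapply(clusterProfiles(x), annotateTsr, model = model,
                   guide = x@guide)
    x@meta$tsrAlleles <- vapply(anns, function(a)
        paste(a$tsr$alleleName, collapse = ","), character(1))
    x@meta$annotations <- S4Vectors::SimpleList(anns)
    x
}

#' Nearest wild-type haplotype for each TSR cluster
#'
#' For every TSR cluster in a pool, finds the wild-type cluster at minimal
#' profile distance. Pairs at distance 1 -- a TSR haplotype differing from
#' a co-occurring wild-type haplotype by the resistance mutation alone --
#' are flagged as putative in-field origins, and the report notes whether
#' the wild-type haplotype outnumbers its TSR derivative.
#'
#' @param x an annotated [HaplotypeClusterSet-class] (see
#'   [annotateClusters()])
#' @return data frame with columns `tsrCluster`, `wtCluster`, `distance`,
#'   `singleMutation`, `tsrFrequency`, `wtFrequency`, `wtMoreFrequent`;
#'   zero rows when the pool lacks TSR or wild-type clusters
#' @export
nearestWildtypePairs <- function(x) {
    meta <- clusterMeta(x)
    if (is.null(meta$tsrAlleles))
        stop("clusters are not annotated; run annotateClusters() first")
    empty <- data.frame(tsrCluster = character(), wtCluster = character(),
                        distance = integer(), singleMutation = logical(),
                        tsrFrequency = numeric(), wtFrequency = numeric(),
                        wtMoreFrequent = logical(), stringsAsFactors = FALSE)
    isTsr <- meta$tsrAlleles != ""
    if (!any(isTsr) || all(isTsr)) return(empty)
    profs <- clusterProfiles(x)
    ids <- meta$clusterId
    wtIdx <- which(!isTsr)
    rows <- lapply(which(isTsr), function(i) {
        d <- vapply(wtIdx, function(j)
            profileDistance(profs[[i]], profs[[j]]), integer(1))
        best <- wtIdx[order(d, ids[wtIdx])][1]
        data.frame(tsrCluster = ids[i], wtCluster = ids[best],
                   distance = min(d), singleMutation = min(d) == 1L,
                   tsrFrequency = meta$frequency[i],
                   wtFrequency = meta$frequency[best],
                   wtMoreFrequent = meta$frequency[best] > meta$frequency[i],
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Write a minimal VCF (v4.2) for a variant profile
#'
#' One record per variant, 1-based positions, anchored indels.
#'
#' @param profile a variant-profile data frame
#' @param path output path
#' @param chrom contig name
#' @param contigLength contig length for the header
#' @param seed seed recorded in the provenance line
#' @export
writeMinimalVcf <- function(profile, path, chrom = "amplicon",
                            contigLength = NA, seed = NA) {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##source=pilepool_%s",
                     as.character(utils::packageVersion("pilepool"))),
             sprintf("##pilepool_seed=%s", as.character(seed)),
             if (!is.na(contigLength))
                 sprintf("##contig=<ID=%s,length=%d>", chrom,
                         as.integer(contigLength))
             else sprintf("##contig=<ID=%s>", chrom),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- if (is.null(profile) || nrow(profile) == 0L) character() else
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s", chrom,
                profile$pos + 1L, profile$ref, profile$alt, profile$kind)
    writeLines(c(hdr, body), path)
    invisible(path)
}
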