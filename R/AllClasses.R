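#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges start end width
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Gene model of a long amplicon
#'
#' Describes where a multi-exon gene sits inside an amplicon: flanking
#' sequence lengths, exon intervals (0-based, half-open, in amplicon
#' coordinates) and the amplicon intervals of the target-site resistance
#' (TSR) codons. Codon numbers follow the cross-species convention for the
#' ACCase reference protein (1781--2096), supplied by the codon map rather
#' than derived from the literal CDS index, so reduced test geometries can
#' carry canonically numbered codons.
#'
#' @slot ampliconLength total amplicon length in bases
#' @slot upstreamLength bases before the gene in amplicon coordinates
#' @slot downstreamLength bases after the gene in amplicon coordinates
#' @slot exons [IRanges::IRanges] of exon intervals (0-based half-open:
#'   `start` is the 0-based start, `width` the exon length)
#' @slot strand `"+"` or `"-"`; on `"-"` the CDS reads off the reverse
#'   complement of the amplicon
#' @slot tsrCodons named [IRanges::IRanges]; names are codon numbers, each
#'   interval the 3-base amplicon footprint of that codon
#' @exportClass GeneModel
setClass("GeneModel",
    representation(
        ampliconLength = "integer",
        upstreamLength = "integer",
        downstreamLength = "integer",
        exons = "IRanges",
        strand = "character",
        tsrCodons = "IRanges"
    )
)

setValidity("GeneModel", function(object) {
    msg <- character()
    L <- object@ampliconLength
    up <- object@upstreamLength
    down <- object@downstreamLength
    ex <- object@exons
    if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(ex) < 2L)
        msg <- c(msg, "gene model needs at least two exons")
    st <- start(ex); en <- start(ex) + width(ex)
    if (any(diff(st) <= 0) || any(st[-1] < en[-length(ex)]))
        msg <- c(msg, "exons must be ordered and non-overlapping")
    if (min(st) < up || max(en) > L - down)
        msg <- c(msg, "exons must lie between the upstream and downstream flanks")
    if (sum(width(ex)) %% 3L != 0L)
        msg <- c(msg, "total CDS length must be a multiple of 3")
    if (length(object@tsrCodons) > 0L && length(ex) >= 2L) {
        ## penultimate exon in CDS order: next-to-last interval on "+",
        ## second interval in amplicon coordinates on "-"
        pen <- if (identical(object@strand, "-")) ex[2L]
               else ex[length(ex) - 1L]
        cs <- start(object@tsrCodons)
        ce <- cs + width(object@tsrCodons)
        if (any(width(object@tsrCodons) != 3L))
            msg <- c(msg, "TSR codon intervals must be 3 bases wide")
        if (any(cs < start(pen) | ce > start(pen) + width(pen)))
            msg <- c(msg, "every TSR codon must lie inside the penultimate exon")
        if (is.null(names(object@tsrCodons)))
            msg <- c(msg, "tsrCodons must be named by codon number")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneModel number of exons
#' @param object,x a `GeneModel`
#' @export
nExons <- function(x) length(x@exons)

#' @describeIn GeneModel exon intervals (0-based half-open)
#' @export
exons <- function(x) x@exons

#' @describeIn GeneModel named codon intervals
#' @export
tsrCodons <- function(x) x@tsrCodons

#' @describeIn GeneModel amplicon length in bases
#' @export
ampliconLength <- function(x) x@ampliconLength

#' @describeIn GeneModel gene strand
#' @export
geneStrand <- function(x) x@strand

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel:", object@ampliconLength, "bp amplicon,",
        length(object@exons), "exons on strand", object@strand, "\n")
    cat("  flanks:", object@upstreamLength, "bp upstream /",
        object@downstreamLength, "bp downstream; CDS",
        sum(width(object@exons)), "bp\n")
    cat("  TSR codons:", paste(names(object@tsrCodons), collapse = ", "), "\n")
})

#' Clustering parameters for pile-based haplotype reconstruction
#'
#' Mirrors the tunables of reference-aided amplicon clustering: the pile
#' size (top-n most similar reads used to error-correct each focal read),
#' the within-pile variant frequency cutoff, and the cluster-level read
#' count / frequency filters. `homopolymerMaskLength`, when set, masks any
#' variant sitting in a guide homopolymer run longer than the given length.
#'
#' @slot pileSize reads per pile
#' @slot minVarFrequency within-pile frequency below which a focal variant
#'   is corrected back to the guide allele (default 0.4)
#' @slot minClusterReadCount minimum supporting reads per retained cluster
#' @slot minClusterFrequency minimum fraction of normalized pool reads
#' @slot maxAlignmentsPerRead cap on alignments considered per focal read
#' @slot maxReadsPerGuide cap on reads clustered against the guide
#' @slot homopolymerMaskLength mask variants in runs longer than this, or
#'   `NULL` to disable (default)
#' @exportClass ClusterParams
setClass("ClusterParams",
    representation(
        pileSize = "integer",
        minVarFrequency = "numeric",
        minClusterReadCount = "integer",
        minClusterFrequency = "numeric",
        maxAlignmentsPerRead = "integer",
        maxReadsPerGuide = "integer",
        homopolymerMaskLength = "integerOrNULL"
    )
)

setValidity("ClusterParams", function(object) {
    msg <- character()
    if (object@pileSize < 1L) msg <- c(msg, "pileSize must be >= 1")
    if (object@minClusterReadCount < 1L)
        msg <- c(msg, "minClusterReadCount must be >= 1")
    if (object@minVarFrequency <= 0 || object@minVarFrequency >= 1)
        msg <- c(msg, "minVarFrequency must be in (0,1)")
    if (object@minClusterFrequency <= 0 || object@minClusterFrequency >= 1)
        msg <- c(msg, "minClusterFrequency must be in (0,1)")
    if (object@maxAlignmentsPerRead < 1L || object@maxReadsPerGuide < 1L)
        msg <- c(msg, "alignment caps must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct clustering parameters
#'
#' @param pileSize,minVarFrequency,minClusterReadCount,minClusterFrequency,maxAlignmentsPerRead,maxReadsPerGuide,homopolymerMaskLength
#'   see [ClusterParams-class]
#' @return a `ClusterParams` object
#' @seealso [derivePoolParameters()] for the pool-design rule that sets
#'   these from the number of individuals and the normalized read count.
#' @export
clusterParams <- function(pileSize = 50L, minVarFrequency = 0.4,
                          minClusterReadCount = 20L,
                          minClusterFrequency = 0.00125,
                          maxAlignmentsPerRead = 16000L,
                          maxReadsPerGuide = 16000L,
                          homopolymerMaskLength = NULL) {
    new("ClusterParams",
        pileSize = as.integer(pileSize),
        minVarFrequency = minVarFrequency,
        minClusterReadCount = as.integer(minClusterReadCount),
        minClusterFrequency = minClusterFrequency,
        maxAlignmentsPerRead = as.integer(maxAlignmentsPerRead),
        maxReadsPerGuide = as.integer(maxReadsPerGuide),
        homopolymerMaskLength = if (is.null(homopolymerMaskLength)) NULL
                                else as.integer(homopolymerMaskLength))
}

setMethod("show", "ClusterParams", function(object) {
    cat("ClusterParams: pile", object@pileSize,
        "| min var freq", object@minVarFrequency,
        "| min cluster reads", object@minClusterReadCount,
        "| min cluster freq", signif(object@minClusterFrequency, 3), "\n")
    if (!is.null(object@homopolymerMaskLength))
        cat("  masking variants in homopolymer runs >",
            object@homopolymerMaskLength, "bp\n")
})

#' Wright-Fisher simulation parameters
#'
#' Diploid single-locus model with genotype fitnesses `1 + s` (homozygous
#' carrier), `1 + h * s` (heterozygote) and `1` (non-carrier). Mutation and
#' recombination rates are recorded for provenance but play no role in the
#' marginal allele-count process of a pre-existing allele.
#'
#' @slot N diploid population size
#' @slot s selection coefficient (non-positive for a deleterious allele)
#' @slot h dominance coefficient of the carrier allele
#' @slot p0 initial allele frequency
#' @slot replicates number of independent replicates
#' @slot maxGenerations censoring cap
#' @slot seed integer seed
#' @slot mu,r recorded mutation / recombination rates (unused)
#' @exportClass WFParams
setClass("WFParams",
    representation(
        N = "integer", s = "numeric", h = "numeric", p0 = "numeric",
        replicates = "integer", maxGenerations = "integer",
        seed = "integer", mu = "numeric", r = "numeric"
    )
)

setValidity("WFParams", function(object) {
    msg <- character()
    if (object@N < 1L) msg <- c(msg, "N must be >= 1")
    if (object@p0 < 0 || object@p0 > 1) msg <- c(msg, "p0 must be in [0,1]")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (object@h < 0 || object@h > 1) msg <- c(msg, "h must be in [0,1]")
    if (object@s < -1) msg <- c(msg, "s must be >= -1")
    if (length(msg)) msg else TRUE
})

#' Construct Wright-Fisher parameters
#'
#' Defaults follow the field-population setting used throughout the package:
#' N = 42000 diploids, 400 replicates, mutation rate 3.0e-8 and
#' recombination rate 7.4e-9 recorded from grass literature values.
#'
#' @param N,s,h,p0,replicates,maxGenerations,seed,mu,r see [WFParams-class]
#' @return a `WFParams` object
#' @export
wfParams <- function(N = 42000L, s = -0.4, h = 0.5, p0 = 0.05,
                     replicates = 400L, maxGenerations = 100000L,
                     seed = 1L, mu = 3.0e-8, r = 7.4e-9) {
    new("WFParams", N = as.integer(N), s = s, h = h, p0 = p0,
        replicates = as.integer(replicates),
        maxGenerations = as.integer(maxGenerations),
        seed = as.integer(seed), mu = mu, r = r)
}

setMethod("show", "WFParams", function(object) {
    cat(sprintf(
        "WFParams: N=%d s=%g h=%g p0=%g | %d replicates, cap %d, seed %d\n",
        object@N, object@s, object@h, object@p0, object@replicates,
        object@maxGenerations, object@seed))
})

#' A set of haplotype clusters from one pool
#'
#' The result of pile-based clustering: one consensus sequence per distinct
#' corrected variant profile, with supporting read counts and pool
#' frequencies (fraction of the normalized pool reads). TSR annotations are
#' attached by [annotateClusters()].
#'
#' @slot consensus [Biostrings::DNAStringSet] of cluster consensus sequences
#' @slot meta [S4Vectors::DataFrame] with columns `clusterId`, `readCount`,
#'   `frequency`, `nVariants` and, after annotation, `tsrAlleles`
#' @slot profiles list of variant-profile data frames, one per cluster
#' @slot members list of member read id vectors
#' @slot totalReads the normalized pool read count used as the frequency
#'   denominator
#' @slot guide the guide sequence (character)
#' @exportClass HaplotypeClusterSet
setClass("HaplotypeClusterSet",
    representation(
        consensus = "DNAStringSet",
        meta = "DataFrame",
        profiles = "list",
        members = "list",
        totalReads = "integer",
        guide = "character"
    )
)

setValidity("HaplotypeClusterSet", function(object) {
    msg <- character()
    n <- length(object@consensus)
    if (nrow(object@meta) != n || length(object@profiles) != n ||
        length(object@members) != n)
        msg <- c(msg, "consensus, meta, profiles and members must be parallel")
    if (n > 0) {
        if (any(object@meta$readCount < 1L))
            msg <- c(msg, "clusters must have at least one supporting read")
        if (any(abs(object@meta$frequency -
                    object@meta$readCount / object@totalReads) > 1e-9))
            msg <- c(msg, "frequency must equal readCount / totalReads")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn HaplotypeClusterSet number of clusters
#' @param x,object a `HaplotypeClusterSet`
#' @export
nClusters <- function(x) length(x@consensus)

#' @describeIn HaplotypeClusterSet consensus sequences
#' @export
consensusSeqs <- function(x) x@consensus

#' @describeIn HaplotypeClusterSet per-cluster metadata
#' @export
clusterMeta <- function(x) x@meta

#' @describeIn HaplotypeClusterSet per-cluster variant profiles
#' @export
clusterProfiles <- function(x) x@profiles

#' @describeIn HaplotypeClusterSet member read ids per cluster
#' @export
clusterMembers <- function(x) x@members

setMethod("show", "HaplotypeClusterSet", function(object) {
    cat("HaplotypeClusterSet:", length(object@consensus), "clusters over",
        object@totalReads, "normalized reads\n")
    if (length(object@consensus)) {
        m <- object@meta
        cat(sprintf("  read counts %d..%d, frequencies %.4g..%.4g\n",
                    min(m$readCount), max(m$readCount),
                    min(m$frequency), max(m$frequency)))
        if (!is.null(m$tsrAlleles)) {
            tsr <- m$tsrAlleles[m$tsrAlleles != ""]
            cat("  TSR clusters:", length(tsr), "\n")
        }
    }
})
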