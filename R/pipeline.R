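#' Default pipeline configuration
#'
#' A small, fully specified end-to-end run on the mini reference profile:
#' two pools of diploid individuals drawing from a haplotype set with TSR
#' haplotypes one mutation away from their wild-type parents, dual
#' barcodes per pool, q30 filtering, depth normalization, pile-based
#' clustering with pool-derived parameters, TSR annotation, haplotype
#' versus allele-frequency comparison, and the individual-versus-pool
#' recovery benchmark.
#'
#' @param outputDir artifact directory
#' @param seed global seed; every stage derives its draws from it
#' @return a config list accepted by [runPipeline()]
#' @export
pipelineConfig <- function(outputDir = tempfile("pilepool_run_"),
                           seed = 1L) {
    list(
        outputDir = outputDir,
        seed = as.integer(seed),
        reference = list(profile = "mini", strand = "+"),
        haplotypes = list(nWildtype = 5L, meanVariants = 8,
                          tsrSpec = data.frame(
                              parent = c(1L, 2L),
                              codon = c(1781L, 1781L),
                              codonPos = c(1L, 2L),
                              alt = c("T", "C"))),
        pools = list(
            list(poolId = "poolA", nIndividuals = 200L, reads = 700L),
            list(poolId = "poolB", nIndividuals = 200L, reads = 600L)),
        readSim = list(),
        minAccuracy = 0.999,
        targetReads = NULL,
        pileFactor = 1.25,
        minVarFrequency = 0.4,
        homopolymerMaskLength = NULL,
        minAltFraction = 0.005,
        nIndividualsSequenced = 24L,
        persistence = NULL)
}

validatePipelineConfig <- function(config) {
    required <- c("outputDir", "seed", "reference", "haplotypes", "pools")
    for (f in required)
        if (is.null(config[[f]]))
            stop("pipeline config is missing required field '", f, "'")
    if (!length(config$pools))
        stop("pipeline config field 'pools' must list at least one pool")
    for (p in config$pools)
        for (f in c("poolId", "nIndividuals", "reads"))
            if (is.null(p[[f]]))
                stop("pipeline config field 'pools' entry is missing '",
                     f, "'")
    invisible(config)
}

## deterministic per-pool barcode pairs, pairwise-distant 10-mers
makeBarcodes <- function(poolIds, seed, width = 10L, maxMismatch = 1L) {
    set.seed(seed)
    bc <- data.frame(pool_id = poolIds, bc5 = NA_character_,
                     bc3 = NA_character_, stringsAsFactors = FALSE)
    draw <- function() paste(sample(BASES, width, replace = TRUE),
                             collapse = "")
    farEnough <- function(cand, have)
        all(vapply(have, function(h)
            hammingDist(cand, h) > 2L * maxMismatch, logical(1)))
    have <- character()
    for (i in seq_along(poolIds)) {
        repeat { b5 <- draw(); if (farEnough(b5, have)) break }
        have <- c(have, b5)
        repeat { b3 <- draw(); if (farEnough(b3, have)) break }
        have <- c(have, b3)
        bc$bc5[i] <- b5; bc$bc3[i] <- b3
    }
    bc
}

#' Run the full pooled-amplicon pipeline
#'
#' Executes simulate, preprocess, cluster, annotate, compare and
#' benchmark (plus, when configured, the persistence sweep) and writes
#' all artifacts and a JSON manifest with parameters, seeds and stage
#' status to `config$outputDir`. Reruns with the same config are
#' byte-identical for sequence outputs.
#'
#' @param config a list as produced by [pipelineConfig()], or a path to a
#'   YAML/JSON file with the same structure
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config = pipelineConfig()) {
    if (is.character(config)) {
        config <- if (grepl("\\.json$", config))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
        if (!is.null(config$haplotypes$tsrSpec))
            config$haplotypes$tsrSpec <-
                as.data.frame(config$haplotypes$tsrSpec)
    }
    validatePipelineConfig(config)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(config$outputDir, ...)
    manifest <- list(package = "pilepool",
                     version = as.character(utils::packageVersion("pilepool")),
                     seed = config$seed, stages = list())
    stageDone <- function(name, files) {
        manifest$stages[[name]] <<- list(status = "complete",
                                         outputs = unname(files))
    }
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    ## --- simulate ---------------------------------------------------
    runStage("simulate", {
        refCfg <- do.call(geneModelConfig, c(config$reference,
                                             list(seed = config$seed)))
        ref <- buildReference(refCfg)
        guide <- ref$guide; model <- ref$model
        haps <- spawnHaplotypes(guide, model,
                                nWildtype = config$haplotypes$nWildtype,
                                tsrSpec = config$haplotypes$tsrSpec,
                                seed = config$seed + 1L,
                                meanVariants = config$haplotypes$meanVariants)
        hapIds <- names(haps)
        pools <- lapply(seq_along(config$pools), function(i) {
            pc <- config$pools[[i]]
            set.seed(config$seed + 100L + i)
            w <- stats::rgamma(length(hapIds), shape = 1)
            poolSpec(pc$poolId, pc$nIndividuals,
                     stats::setNames(w / sum(w), hapIds),
                     pc$reads, seed = config$seed + 200L + i)
        })
        simPar <- do.call(readSimParams,
                          c(config$readSim, list(seed = config$seed)))
        barcodes <- makeBarcodes(vapply(pools, `[[`, character(1), "poolId"),
                                 seed = config$seed + 7L)
        mixed <- do.call(c, lapply(seq_along(pools), function(i) {
            r <- simulatePoolReads(pools[[i]], haps, simPar)
            attachBarcodes(r, barcodes$bc5[i], barcodes$bc3[i])
        }))
        writeXStringSet(DNAStringSet(stats::setNames(as.character(guide),
                                                     "guide")),
                        out("guide.fasta"))
        writeXStringSet(haps, out("haplotypes.fasta"))
        writeReadsFastq(mixed, out("multiplexed.fastq"))
        writePoolManifest(pools, out("pool_manifest.tsv"),
                          seed = config$seed)
        writeGeneModel(model, out("gene_model"), seed = config$seed)
        stageDone("simulate", c("guide.fasta", "haplotypes.fasta",
                                "multiplexed.fastq", "pool_manifest.tsv",
                                "gene_model.bed", "gene_model.codons.json"))
        list(guide = guide, model = model, haps = haps, pools = pools,
             barcodes = barcodes, mixed = mixed)
    }) -> sim

    ## --- preprocess -------------------------------------------------
    pre <- runStage("preprocess", {
        dm <- demultiplex(sim$mixed, sim$barcodes)
        filtered <- lapply(dm$pools, filterByAccuracy,
                           minAccuracy = config$minAccuracy)
        norm <- normalizePools(filtered, targetReads = config$targetReads,
                               seed = config$seed + 11L)
        writeLines(provenanceHeader(config$seed), out("demux_report.tsv"))
        suppressWarnings(utils::write.table(dm$report,
            out("demux_report.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, append = TRUE))
        writeLines(provenanceHeader(config$seed),
                   out("normalization_report.tsv"))
        suppressWarnings(utils::write.table(norm$report,
            out("normalization_report.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, append = TRUE))
        for (pid in names(norm$pools))
            writeReadsFastq(norm$pools[[pid]],
                            out(sprintf("%s.normalized.fastq", pid)))
        stageDone("preprocess", c("demux_report.tsv",
                                  "normalization_report.tsv",
                                  sprintf("%s.normalized.fastq",
                                          names(norm$pools))))
        norm
    })

    ## --- cluster + annotate ----------------------------------------
    poolN <- stats::setNames(
        vapply(config$pools, function(p) as.integer(p$nIndividuals),
               integer(1)),
        vapply(config$pools, `[[`, character(1), "poolId"))
    alnByPool <- list()
    clustersByPool <- list()
    runStage("cluster", {
        for (pid in names(pre$pools)) {
            reads <- pre$pools[[pid]]
            params <- derivePoolParameters(
                poolN[[pid]], length(reads),
                pileFactor = config$pileFactor,
                minVarFrequency = config$minVarFrequency,
                homopolymerMaskLength = config$homopolymerMaskLength)
            aln <- alignToGuide(reads, sim$guide)
            alnByPool[[pid]] <- aln
            cl <- clusterFromAlignment(aln, sim$guide, params)
            clustersByPool[[pid]] <- cl
            writeClusterFasta(cl, out(sprintf("%s.clusters.fasta", pid)),
                              poolId = pid)
        }
        stageDone("cluster", sprintf("%s.clusters.fasta", names(pre$pools)))
    })
    runStage("annotate", {
        for (pid in names(clustersByPool)) {
            clustersByPool[[pid]] <- annotateClusters(clustersByPool[[pid]],
                                                      sim$model)
            clusterTable(clustersByPool[[pid]],
                         out(sprintf("%s.clusters.tsv", pid)),
                         poolId = pid, seed = config$seed)
            writeMinimalVcf(
                do.call(rbind, clusterProfiles(clustersByPool[[pid]])),
                out(sprintf("%s.clusters.vcf", pid)),
                contigLength = ampliconLength(sim$model),
                seed = config$seed)
        }
        stageDone("annotate",
                  c(sprintf("%s.clusters.tsv", names(clustersByPool)),
                    sprintf("%s.clusters.vcf", names(clustersByPool))))
    })

    ## --- compare: haplotype-sum vs pooled SNP allele frequency ------
    cmp <- runStage("compare", {
        rows <- list()
        for (pid in names(clustersByPool)) {
            cl <- clustersByPool[[pid]]
            aln <- alnByPool[[pid]]
            af <- pooledAlleleFrequencies(aln$profiles[aln$onTarget],
                                          minAltFraction = config$minAltFraction)
            alleles <- setdiff(unique(unlist(
                strsplit(clusterMeta(cl)$tsrAlleles, ",", fixed = TRUE))), "")
            for (a in alleles) {
                hapFreq <- tsrFrequencyFromClusters(cl, a)
                ## locate the allele's site through any carrier profile
                carrier <- which(vapply(
                    strsplit(clusterMeta(cl)$tsrAlleles, ",", fixed = TRUE),
                    function(x) a %in% x, logical(1)))[1]
                ann <- clusterMeta(cl)$annotations[[carrier]]$tsr
                ann <- ann[ann$alleleName == a, ]
                cod <- tsrCodons(sim$model)[as.character(ann$codon)]
                pos0 <- if (geneStrand(sim$model) == "+")
                    start(cod) + ann$codonPos - 1L
                else start(cod) + (3L - ann$codonPos)
                hit <- af[af$pos == pos0 + 1L & af$kind == "SNV", ]
                snpFreq <- if (nrow(hit)) sum(hit$frequency) else 0
                rows[[length(rows) + 1L]] <- data.frame(
                    pool_id = pid, allele = a,
                    haplotype_frequency = hapFreq,
                    snp_frequency = snpFreq, stringsAsFactors = FALSE)
            }
        }
        tab <- if (length(rows)) do.call(rbind, rows) else
            data.frame(pool_id = character(), allele = character(),
                       haplotype_frequency = numeric(),
                       snp_frequency = numeric())
        writeLines(provenanceHeader(config$seed), out("tsr_comparison.tsv"))
        suppressWarnings(utils::write.table(tab, out("tsr_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
        stageDone("compare", "tsr_comparison.tsv")
        tab
    })

    ## --- benchmark: individuals versus pools ------------------------
    runStage("benchmark", {
        reports <- list()
        for (i in seq_along(sim$pools)) {
            pid <- sim$pools[[i]]$poolId
            if (is.null(clustersByPool[[pid]])) next
            ind <- sampleIndividuals(sim$pools[[i]],
                                     config$nIndividualsSequenced,
                                     seed = config$seed + 300L + i)
            bm <- benchmarkRecovery(ind, sim$haps, clustersByPool[[pid]],
                                    sim$model)
            reports[[pid]] <- cbind(pool_id = pid, bm$report)
        }
        tab <- do.call(rbind, reports)
        writeLines(provenanceHeader(config$seed), out("recovery_report.tsv"))
        suppressWarnings(utils::write.table(tab, out("recovery_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
        stageDone("benchmark", "recovery_report.tsv")
    })

    ## --- persist (optional) -----------------------------------------
    if (!is.null(config$persistence)) {
        runStage("persist", {
            ps <- do.call(persistenceSweep,
                          c(config$persistence,
                            list(seed = config$seed + 1000L)))
            writePersistenceTable(ps, out("persistence.tsv"),
                                  seed = config$seed)
            stageDone("persist", "persistence.tsv")
        })
    }

    manifest$parameters <- config[setdiff(names(config), "outputDir")]
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
    invisible(manifest)
}
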