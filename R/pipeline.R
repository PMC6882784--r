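## End-to-end orchestration: purity -> copy number -> allelic imbalance ->
## mutation QC -> prevalence/clustering -> phylogeny, per mouse and cohort.

#' Pipeline parameter set
#'
#' Collects every tunable threshold with its documented default; validates
#' ranges.
#'
#' @param focalSizeLimit focal event maximum span (bp).
#' @param focalMinProbes minimum probes per focal segment.
#' @param focalMergeGap same-class merge distance (bp).
#' @param segAlpha permutation level for accepting a split.
#' @param segPerm permutations per split test.
#' @param aiFdr FDR level for allelic-imbalance calls.
#' @param aiMinDp informative SNP depth.
#' @param prevTol multiplicity-deduction tolerance.
#' @param treeAlpha precedence-test level.
#' @param sumTol sum-rule tolerance.
#' @param lowVafCutoff region-exclusion VAF cutoff.
#' @return named list of validated parameters.
#' @export
pipelineParams <- function(focalSizeLimit = 4e6, focalMinProbes = 5L,
                           focalMergeGap = 1e5, segAlpha = 0.01,
                           segPerm = 100L, aiFdr = 0.05, aiMinDp = 20L,
                           prevTol = 0.05, treeAlpha = 0.05, sumTol = 0.10,
                           lowVafCutoff = 0.02) {
    stopifnot(focalSizeLimit > 0, focalMinProbes >= 1,
              segAlpha > 0, segAlpha < 1, aiFdr > 0, aiFdr < 1,
              sumTol >= 0, lowVafCutoff >= 0, lowVafCutoff < 1)
    as.list(environment())
}

#' Cohort configuration
#'
#' Validates a configuration (typically parsed from YAML) describing the
#' cohort inputs and thresholds.
#'
#' @param mice named list; each element a list of file paths (`mutations`,
#'   `probes`, `snps`, `ct_standards`, `ct_sample`).
#' @param genes path to the gene BED file.
#' @param params list from [pipelineParams()] (defaults applied).
#' @param seed master seed.
#' @return validated config list.
#' @export
cohortConfig <- function(mice, genes, params = pipelineParams(),
                         seed = 1L) {
    stopifnot(length(mice) >= 1L)
    for (m in names(mice)) {
        for (f in unlist(mice[[m]]))
            if (!file.exists(f))
                stop("missing input for mouse ", m, ": ", f)
    }
    if (!file.exists(genes))
        stop("missing gene BED: ", genes)
    params <- do.call(pipelineParams, params)
    list(mice = mice, genes = genes, params = params,
         seed = as.integer(seed))
}

#' Read a YAML cohort configuration
#'
#' @param path YAML file with keys `mice`, `genes`, optional `params`,
#'   `seed`; relative paths resolve against the file's directory.
#' @return validated config list (see [cohortConfig()]).
#' @export
readCohortConfig <- function(path) {
    y <- yaml::read_yaml(path)
    base <- dirname(path)
    resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
    mice <- lapply(y$mice, function(m) lapply(m, resolve))
    cohortConfig(mice, resolve(y$genes), y$params %||% list(),
                 y$seed %||% 1L)
}

## load one mouse's input files into the in-memory layout runMouse expects
.loadMouseInputs <- function(paths) {
    list(mutations = readMutationTable(paths$mutations),
         probes = readProbeTrack(paths$probes),
         snps = readSnpCounts(paths$snps),
         ctStandards = readCtStandards(paths$ct_standards),
         ctSample = read.table(paths$ct_sample, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

.asMouseInputs <- function(mouse) {
    if (is(mouse, "SimulatedMouse"))
        return(list(mouseId = mouse@mouseId, mutations = mouse@mutations,
                    probes = mouse@probes, snps = mouse@snps,
                    ctStandards = mouse@ctStandards,
                    ctSample = mouse@ctSample))
    mouse
}

## copy number at mutation positions from called segments of one region
.lookupCn <- function(segments, chrom, pos) {
    cnt <- rep(NA_integer_, length(pos))
    for (i in seq_along(pos)) {
        hit <- segments$chrom == chrom[i] & segments$start <= pos[i] &
            segments$end > pos[i]
        if (any(hit)) cnt[i] <- segments$cnt[which(hit)[1L]]
    }
    cnt
}

#' Run the full pipeline for one mouse
#'
#' Executes purity estimation, per-region segmentation and copy-number
#' calling, allelic-imbalance calibration and testing, mutation validation
#' and heterogeneity categorization, prevalence estimation and clustering,
#' and subclone-tree enumeration. Regions that fail a stage (no copy-number
#' profile, all-low VAF, calibration lacking power) degrade gracefully and
#' are recorded in the report's `exclusions`.
#'
#' @param mouse a [SimulatedMouse-class], an input list (see
#'   `.loadMouseInputs`), or a named list of file paths.
#' @param genes gene table (data.frame `chrom`, `start`, `end`, `name`) or a
#'   BED path.
#' @param params list from [pipelineParams()].
#' @param seed seed for the stochastic stages (segmentation permutations,
#'   threshold calibration).
#' @param outDir optional directory for stage artifacts (TSV/SEG/Newick/
#'   DOT/JSON).
#' @return report list with elements `purity`, `segments`, `focalEvents`,
#'   `largeScale`, `geneAlteredFraction`, `aiGenes`, `mutations`,
#'   `heterogeneity`, `clusters`, `trees`, `topology`, `exclusions`,
#'   `params`.
#' @export
runMouse <- function(mouse, genes, params = pipelineParams(), seed = 1L,
                     outDir = NULL) {
    inputs <- if (is.list(mouse) && !is.null(mouse$mutations) &&
                  is.character(mouse$mutations))
        .loadMouseInputs(mouse) else .asMouseInputs(mouse)
    if (is.character(genes)) genes <- readGenesBed(genes)
    mouseId <- inputs$mouseId %||% "mouse"
    exclusions <- list()
    regions <- sort(unique(inputs$mutations$region))

    ## 1. purity
    curve <- fitStandardCurve(inputs$ctStandards)
    purity <- vapply(regions, function(rg) {
        ct <- inputs$ctSample$ct[inputs$ctSample$region == rg]
        if (!length(ct)) return(NA_real_)
        estimatePurity(ct, curve)
    }, numeric(1))

    ## 2. copy number per region
    segByRegion <- list()
    focal <- list()
    large <- list()
    gaf <- c()
    for (rg in regions) {
        probes <- inputs$probes[inputs$probes$region == rg, , drop = FALSE]
        if (!nrow(probes) || is.na(purity[[rg]]) || purity[[rg]] <= 0) {
            exclusions[[length(exclusions) + 1L]] <-
                list(region = rg, stage = "copy_number",
                     reason = "no probe track or unusable purity")
            next
        }
        seg <- segmentTrack(probes, alpha = params$segAlpha,
                            nPerm = params$segPerm,
                            seed = subSeed(seed, match(rg, regions)))
        seg <- mergeUndo(seg)
        seg <- annotateCopyNumber(seg, purity[[rg]])
        segByRegion[[rg]] <- seg
        ev <- callFocalEvents(seg, genes,
                              sizeLimit = params$focalSizeLimit,
                              minProbes = params$focalMinProbes,
                              mergeGap = params$focalMergeGap)
        if (nrow(ev)) ev$region <- rg
        focal[[rg]] <- ev
        ls <- callLargeScale(seg)
        ls$region <- rg
        large[[rg]] <- ls
        gaf[rg] <- geneAlterationFraction(seg, genes)
    }
    focalAll <- do.call(rbind, focal[vapply(focal, nrow, 1L) > 0])
    if (is.null(focalAll))
        focalAll <- data.frame(class = character(0), chrom = character(0),
                               start = numeric(0), end = numeric(0),
                               nProbes = integer(0), genes = character(0),
                               region = character(0))
    focalMatched <- matchFocalEvents(focalAll,
                                     regions = names(segByRegion))

    ## 3. allelic imbalance per region
    aiByRegion <- list()
    for (rg in names(segByRegion)) {
        snps <- inputs$snps[inputs$snps$region == rg, , drop = FALSE]
        if (!nrow(snps)) next
        snps2 <- .mafCols(snps)
        inf <- snps2[snps2$t_dp >= params$aiMinDp &
                     snps2$n_dp >= params$aiMinDp, , drop = FALSE]
        coverage <- max(1, round(median(inf$t_dp)))
        cal <- calibrateMafThreshold(purity[[rg]], coverage,
                                     sample = paste0(mouseId, "_", rg),
                                     seed = subSeed(seed, 100L +
                                                    match(rg, regions)))
        if (lackingPower(cal)) {
            exclusions[[length(exclusions) + 1L]] <-
                list(region = rg, stage = "allelic_imbalance",
                     reason = "lacking power for imbalance analysis")
            aiByRegion[[rg]] <- NA
            next
        }
        tab <- testAllelicImbalance(genes, snps, cal,
                                    minDp = params$aiMinDp,
                                    fdrLevel = params$aiFdr)
        aiByRegion[[rg]] <- tab$gene[!is.na(tab$ai) & tab$ai]
    }
    aiGenes <- tryCatch(aiUnion(aiByRegion), error = function(e) character(0))

    ## 4. mutation QC
    muts <- inputs$mutations
    validated <- validationFilter(muts)
    muts$validated <- validated[muts$id]
    vmuts <- muts[muts$validated, , drop = FALSE]
    somaticAll <- if (is.null(vmuts$knockin)) vmuts else
        vmuts[!vmuts$knockin, , drop = FALSE]
    analyzed <- excludeLowVafRegions(
        somaticAll, regionsWithCn = names(segByRegion),
        maxVaf = params$lowVafCutoff)
    for (rg in setdiff(regions, analyzed))
        exclusions[[length(exclusions) + 1L]] <-
            list(region = rg, stage = "prevalence",
                 reason = "low VAF across all mutations or no copy-number profile")
    het <- categorizeHeterogeneity(vmuts, analyzedRegions = analyzed)

    ## 5. prevalence + clustering
    somatic <- somaticAll[somaticAll$region %in% analyzed, , drop = FALSE]
    somatic$cnt <- NA_integer_
    for (rg in analyzed) {
        i <- somatic$region == rg
        somatic$cnt[i] <- .lookupCn(segByRegion[[rg]], somatic$chrom[i],
                                    somatic$pos[i])
    }
    prev <- estimatePrevalence(somatic, purity, regions = analyzed,
                               tol = params$prevTol)
    clustering <- clusterByPrevalence(prev$matrix)

    ## 6. phylogeny
    trees <- list()
    topology <- NA_character_
    synchronous <- NA
    if (nrow(clusterCenters(clustering)) <= 8L) {
        trees <- enumerateTrees(clusterCenters(clustering),
                                clusterSds(clustering),
                                alpha = params$treeAlpha,
                                sumTol = params$sumTol)
        topo <- unique(vapply(trees, topologyClass, character(1)))
        if (length(topo) == 1L) topology <- topo
        sp <- unique(vapply(trees, function(t) t@synchronousPrimary,
                            logical(1)))
        if (length(sp) == 1L) synchronous <- sp
    }

    report <- list(mouseId = mouseId, purity = as.list(purity),
                   segments = segByRegion, focalEvents = focalMatched,
                   largeScale = do.call(rbind, large),
                   geneAlteredFraction = as.list(gaf), aiGenes = aiGenes,
                   mutations = muts, heterogeneity = het,
                   clusters = list(centers = clusterCenters(clustering),
                                   sds = clusterSds(clustering),
                                   assignments =
                                       clusterAssignments(clustering),
                                   method = clustering@method),
                   trees = trees, topology = topology,
                   synchronousPrimary = synchronous,
                   analyzedRegions = analyzed, exclusions = exclusions,
                   params = params, seed = seed)
    if (!is.null(outDir))
        .writeMouseArtifacts(report, outDir)
    report
}

.writeMouseArtifacts <- function(report, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (rg in names(report$segments))
        writeSeg(report$segments[[rg]],
                 file.path(outDir, sprintf("segments_%s.seg", rg)),
                 sample = paste0(report$mouseId, "_", rg))
    writeMutationTable(report$mutations,
                       file.path(outDir, "mutations_qc.tsv"))
    write.table(report$heterogeneity,
                file.path(outDir, "heterogeneity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(report$focalEvents))
        write.table(report$focalEvents,
                    file.path(outDir, "focal_events.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    centers <- report$clusters$centers
    clTab <- data.frame(cluster = rownames(centers), centers,
                        check.names = FALSE)
    write.table(clTab, file.path(outDir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(report$trees)) {
        writeLines(vapply(report$trees, subcloneNewick, character(1)),
                   file.path(outDir, "trees.nwk"))
        writeTreeDot(report$trees[[1L]], file.path(outDir, "tree1.dot"))
    }
    json <- report
    json$segments <- lapply(json$segments, function(s) s)
    json$trees <- lapply(report$trees, function(t)
        list(parents = as.list(t@parents), cost = t@cost,
             topology = t@topology,
             synchronousPrimary = t@synchronousPrimary))
    json$clusters$centers <- apply(centers, 1, as.list)
    json$clusters$sds <- apply(report$clusters$sds, 1, as.list)
    jsonlite::write_json(json, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10,
                         force = TRUE)
    invisible(outDir)
}

#' Run the pipeline over a cohort
#'
#' Per-mouse runs never abort the cohort: failures are recorded and the
#' summary aggregates whatever completed. The summary reports the per-mouse
#' validated mutation burden, heterogeneity fractions, focal-event recurrence
#' across mice (same 50% overlap/union matching as within-mouse), the
#' linear/branched tally, and gene allelic-imbalance enrichment.
#'
#' @param cohort named list of mice ([SimulatedMouse-class] objects or input
#'   path lists), or a config from [cohortConfig()]/[readCohortConfig()].
#' @param genes gene table or BED path (ignored when `cohort` is a config).
#' @param params list from [pipelineParams()].
#' @param seed master seed; per-mouse sub-seeds derive from it.
#' @param outDir optional artifact directory (one subdirectory per mouse).
#' @return list with `reports` (per mouse) and `summary`.
#' @export
runCohort <- function(cohort, genes = NULL, params = pipelineParams(),
                      seed = 1L, outDir = NULL) {
    if (!is.null(cohort$mice) && !is.null(cohort$genes)) {
        genes <- cohort$genes
        params <- cohort$params
        seed <- cohort$seed
        cohort <- cohort$mice
    }
    if (length(cohort) < 1L)
        stop("empty cohort")
    if (is.character(genes)) genes <- readGenesBed(genes)
    mouseIds <- names(cohort) %||% sprintf("M%02d", seq_along(cohort))
    reports <- list()
    failures <- list()
    for (i in seq_along(cohort)) {
        id <- mouseIds[i]
        res <- tryCatch(
            runMouse(cohort[[i]], genes, params,
                     seed = subSeed(seed, 500L + i),
                     outDir = if (!is.null(outDir))
                         file.path(outDir, id) else NULL),
            error = function(e) e)
        if (inherits(res, "error")) {
            failures[[id]] <- conditionMessage(res)
        } else {
            res$mouseId <- id
            reports[[id]] <- res
        }
    }
    summary <- .summarizeCohort(reports, failures)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(summary,
                             file.path(outDir, "cohort_summary.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = 10,
                             force = TRUE)
    }
    list(reports = reports, summary = summary)
}

.summarizeCohort <- function(reports, failures = list()) {
    burden <- vapply(reports, function(r) {
        m <- r$mutations
        keep <- m$validated
        if (!is.null(m$knockin)) keep <- keep & !m$knockin
        v <- m[keep, , drop = FALSE]
        length(unique(v$id))
    }, numeric(1))
    hetFrac <- lapply(reports, function(r) {
        h <- r$heterogeneity
        h <- h[h$category != "absent", , drop = FALSE]
        if (!nrow(h)) return(c(ubiquitous = NA_real_,
                               `partially shared` = NA_real_,
                               private = NA_real_))
        tab <- table(factor(h$category,
                            levels = c("ubiquitous", "partially shared",
                                       "private")))
        setNames(as.vector(tab) / nrow(h), names(tab))
    })
    ## focal recurrence across mice: per-mouse unique events (union span per
    ## within-mouse event id), matched across mice at 50% overlap/union
    perMouse <- lapply(names(reports), function(id) {
        ev <- reports[[id]]$focalEvents
        if (!nrow(ev)) return(NULL)
        agg <- do.call(rbind, lapply(split(ev, ev$eventId), function(e)
            data.frame(class = e$class[1L], chrom = e$chrom[1L],
                       start = min(e$start), end = max(e$end),
                       nProbes = max(e$nProbes),
                       genes = paste(unique(unlist(
                           strsplit(e$genes, ","))), collapse = ","),
                       region = id, stringsAsFactors = FALSE)))
        agg
    })
    pooled <- do.call(rbind, perMouse)
    recurrence <- NULL
    if (!is.null(pooled) && nrow(pooled)) {
        m <- matchFocalEvents(pooled, regions = names(reports))
        recurrence <- do.call(rbind, lapply(split(m, m$eventId), function(e)
            data.frame(class = e$class[1L], chrom = e$chrom[1L],
                       start = min(e$start), end = max(e$end),
                       nMice = length(unique(e$region)),
                       genes = paste(unique(unlist(
                           strsplit(e$genes, ","))), collapse = ","),
                       stringsAsFactors = FALSE)))
        rownames(recurrence) <- NULL
    }
    topo <- vapply(reports, function(r) r$topology %||% NA_character_,
                   character(1))
    aiAll <- sort(unique(unlist(lapply(reports, function(r) r$aiGenes))))
    aiMat <- NULL
    aiEnrich <- NULL
    if (length(aiAll)) {
        aiMat <- vapply(reports, function(r) aiAll %in% r$aiGenes,
                        logical(length(aiAll)))
        aiMat <- matrix(aiMat, nrow = length(aiAll),
                        dimnames = list(aiAll, names(reports)))
        aiEnrich <- aiEnrichment(aiMat)
    }
    list(nMice = length(reports),
         mutationBurden = as.list(burden),
         burdenMean = mean(burden), burdenSd = sd(burden),
         heterogeneity = hetFrac,
         geneAlteredFraction = lapply(reports, function(r)
             mean(unlist(r$geneAlteredFraction))),
         focalRecurrence = recurrence,
         topologyTally = as.list(table(topo[!is.na(topo)])),
         synchronousPrimaries = names(reports)[vapply(reports, function(r)
             isTRUE(r$synchronousPrimary), logical(1))],
         aiEnrichment = aiEnrich,
         failures = failures)
}
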