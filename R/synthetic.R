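## Synthetic multi-region cohort generator.
##
## Emulates the processed data of a 12-mouse, 3-regions-per-tumor study:
## binomial amplicon read counts over a truth subclone hierarchy, probe-level
## aCGH log ratios under the purity mixing model, germline het-SNP allele
## counts with one-copy-loss imbalance, and a qPCR purity dilution series.

#' Default synthetic genome
#'
#' A compact all-autosome genome used by the simulator; real coordinates are
#' not needed because every downstream rule is interval arithmetic.
#'
#' @param nChrom number of autosomes.
#' @param chromLength length of each chromosome in bp.
#' @return data.frame with columns `chrom`, `length`.
#' @export
defaultGenome <- function(nChrom = 4L, chromLength = 5e7) {
    data.frame(chrom = paste0("chr", seq_len(nChrom)),
               length = rep(chromLength, nChrom),
               stringsAsFactors = FALSE)
}

#' Simulate gene coordinates
#'
#' Non-overlapping gene spans placed uniformly along the genome.
#'
#' @param genome data.frame from [defaultGenome()].
#' @param nGenes total number of genes.
#' @param geneWidth gene span in bp.
#' @param seed RNG seed.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`
#'   (0-based half-open coordinates).
#' @export
simulateGenes <- function(genome, nGenes = 200L, geneWidth = 2e4,
                          seed = NULL) {
    withSeed(seed, {
        per <- diff(round(seq(0, nGenes, length.out = nrow(genome) + 1)))
        out <- lapply(seq_len(nrow(genome)), function(i) {
            n <- per[i]
            if (n == 0) return(NULL)
            ## evenly spaced slots with jitter keep genes non-overlapping
            slot <- genome$length[i] / n
            jitter <- runif(n, 0, max(slot - geneWidth, 1))
            start <- floor((seq_len(n) - 1) * slot + jitter)
            data.frame(chrom = genome$chrom[i], start = start,
                       end = start + geneWidth,
                       name = sprintf("%s_g%03d", genome$chrom[i],
                                      seq_len(n)),
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, out)
    })
}

## ---- truth trees -----------------------------------------------------------

## descending per-region prevalences for a chain of n non-root clusters,
## each step at least `margin` below its parent
.chainPrevalence <- function(n, margin) {
    floorPrev <- 0.03
    slack <- 1 - floorPrev - n * margin
    if (slack < 0)
        stop("margin too large for ", n, " nested clusters")
    extra <- runif(n)
    extra <- extra / sum(extra) * slack * runif(1, 0.2, 1)
    1 - cumsum(margin + extra)
}

#' Simulate a ground-truth subclone tree
#'
#' Generates a rooted hierarchy of mutation clusters with per-region cancer
#' cell prevalences obeying the sum rule (children sum to at most the parent
#' in every region). The root is the knock-in transgene cluster at prevalence
#' 1 everywhere. Cluster prevalence vectors are pairwise separated by at least
#' `margin` (sup norm) so downstream clustering can recover them.
#'
#' @param nClusters total number of clusters including the root (2-7 observed
#'   per mouse in this study design).
#' @param topology `"linear"`, `"branched"` or `"two_primary"`. Two synchronous
#'   primaries need at least 3 clusters (root + one founder per primary) and
#'   2 regions.
#' @param nRegions number of tumor regions.
#' @param margin minimum prevalence separation between clusters.
#' @param seed RNG seed.
#' @return A [TruthTree-class].
#' @examples
#' simulateTree(3, "branched", nRegions = 3, seed = 1)
#' @export
simulateTree <- function(nClusters, topology = c("linear", "branched",
                                                 "two_primary"),
                         nRegions = 3L, margin = 0.15, seed = NULL) {
    topology <- match.arg(topology)
    stopifnot(nClusters >= 2L, nRegions >= 1L)
    if (topology == "two_primary" && nClusters < 3L)
        stop("two_primary needs at least 3 clusters (root + 2 lineages)")
    if (topology == "two_primary" && nRegions < 2L)
        stop("two_primary needs at least 2 regions for disjoint support")
    if (topology == "branched" && nClusters < 3L)
        stop("a branched tree needs at least 3 clusters")
    withSeed(seed, .simulateTreeImpl(nClusters, topology, nRegions, margin))
}

.simulateTreeImpl <- function(K, topology, R, margin) {
    ids <- paste0("C", seq_len(K) - 1L)
    regions <- paste0("T", seq_len(R))
    for (try in seq_len(300L)) {
        parents <- setNames(rep(NA_character_, K), ids)
        P <- matrix(0, K, R, dimnames = list(ids, regions))
        P[1L, ] <- 1
        if (topology == "linear") {
            parents[-1L] <- ids[-K]
            for (r in seq_len(R))
                P[-1L, r] <- .chainPrevalence(K - 1L, margin)
        } else if (topology == "branched") {
            ## random parent among earlier clusters; force >= 1 branch point
            pidx <- c(NA_integer_, 1L,
                      if (K > 2L)
                          vapply(3:K, function(i) sample.int(i - 1L, 1L), 1L))
            if (all(tabulate(pidx[!is.na(pidx)], K) <= 1L))
                pidx[K] <- pidx[K - 1L]   # make the last two siblings
            parents[-1L] <- ids[pidx[-1L]]
            P <- .allocateBranched(P, parents, ids, margin)
        } else {
            parents[2:3] <- ids[1L]
            if (K > 3L)
                parents[4:K] <- ids[rep_len(2:3, K - 3L)]
            ## founder A occupies the first region, founder B the last;
            ## both may collide at moderate prevalence in middle regions
            P[2L, 1L] <- runif(1, 0.65, 0.9)
            P[3L, R] <- runif(1, 0.65, 0.9)
            if (R > 2L) {
                for (r in 2:(R - 1L)) {
                    a <- runif(1, 0.15, 0.45)
                    b <- runif(1, 0.15, min(0.45, 1 - a - 0.05))
                    P[2L, r] <- a
                    P[3L, r] <- b
                }
            }
            if (K > 3L)
                P <- .allocateBranched(P, parents, ids, margin,
                                       skip = ids[2:3])
        }
        ok <- TRUE
        if (K > 1L) {
            dmat <- as.matrix(dist(P, method = "maximum"))
            ok <- min(dmat[upper.tri(dmat)]) >= margin - 1e-9
        }
        if (ok) {
            tree <- new("TruthTree", parents = parents, prevalence = P,
                        topology = topology, rootId = ids[1L])
            validObject(tree)
            return(tree)
        }
    }
    stop("could not generate a margin-separated tree; relax margin")
}

## stick-breaking allocation of children prevalences below each parent
.allocateBranched <- function(P, parents, ids, margin, skip = character(0)) {
    ## process in id order: parents always precede children by construction
    for (id in ids) {
        kids <- setdiff(names(parents)[!is.na(parents) & parents == id],
                        skip)
        if (!length(kids)) next
        for (r in seq_len(ncol(P))) {
            avail <- P[id, r]
            f <- runif(1, 0.45, 0.85)
            w <- runif(length(kids), 0.3, 1)
            prev <- avail * f * w / sum(w)
            prev <- pmin(prev, max(avail - margin, 0))
            P[kids, r] <- prev
        }
    }
    P
}

## ---- copy-number truth -----------------------------------------------------

#' Simulate a per-region integer copy-number truth profile
#'
#' Plants clonal large-scale gains/losses, focal homozygous deletions and
#' amplifications, and a one-copy-loss block (the allelic-imbalance substrate)
#' on a diploid autosomal background. Events are clonal (present in all
#' regions) unless listed in `privateEvents`.
#'
#' @param genome data.frame from [defaultGenome()].
#' @param nRegions number of tumor regions.
#' @param events data.frame describing events to plant, with columns `chrom`,
#'   `start`, `end`, `cnt` and optionally `regions` (comma-separated region
#'   names; default all regions). `NULL` plants a default complement of one
#'   large gain, one large loss, one focal HD, one focal Amp and one one-copy
#'   loss block.
#' @param seed RNG seed.
#' @return data.frame of disjoint segments with columns `region`, `chrom`,
#'   `start`, `end`, `cnt` covering the genome in every region (0-based
#'   half-open).
#' @export
simulateCnProfile <- function(genome, nRegions = 3L, events = NULL,
                              seed = NULL) {
    regions <- paste0("T", seq_len(nRegions))
    if (is.null(events)) {
        len <- genome$length[1]
        events <- data.frame(
            chrom = genome$chrom[c(1, 2, 2, 3, 4)],
            start = c(0.2, 0.10, 0.60, 0.30, 0.05) * len,
            end   = c(0.85, 0.155, 0.64, 0.90, 0.55) * len,
            cnt   = c(3L, 0L, 6L, 1L, 1L),
            regions = NA_character_,
            stringsAsFactors = FALSE)
    }
    if (is.null(events$regions))
        events$regions <- rep(NA_character_, nrow(events))
    out <- list()
    for (rg in regions) {
        ev <- events[is.na(events$regions) |
                     vapply(strsplit(events$regions, ","),
                            function(x) rg %in% x, logical(1)), , drop = FALSE]
        for (i in seq_len(nrow(genome))) {
            chrom <- genome$chrom[i]; len <- genome$length[i]
            e <- ev[ev$chrom == chrom, , drop = FALSE]
            e <- e[order(e$start), , drop = FALSE]
            bounds <- sort(unique(c(0, len, e$start, e$end)))
            seg <- data.frame(region = rg, chrom = chrom,
                              start = bounds[-length(bounds)],
                              end = bounds[-1], cnt = 2L,
                              stringsAsFactors = FALSE)
            for (j in seq_len(nrow(e)))
                seg$cnt[seg$start >= e$start[j] & seg$end <= e$end[j]] <-
                    e$cnt[j]
            out[[length(out) + 1L]] <- seg
        }
    }
    do.call(rbind, out)
}

## integer copy number at (region, chrom, pos) from a cn profile
.cnAt <- function(profile, region, chrom, pos) {
    res <- rep(2L, length(pos))
    sub <- profile[profile$region == region, , drop = FALSE]
    for (i in seq_along(pos)) {
        hit <- sub$chrom == chrom[i] & sub$start <= pos[i] & sub$end > pos[i]
        if (any(hit)) res[i] <- sub$cnt[which(hit)[1L]]
    }
    res
}

## ---- read-level simulators -------------------------------------------------

#' Simulate amplicon read counts for all mutations of a tree
#'
#' Each cluster receives `nMutPerCluster` somatic mutations at uniform genomic
#' positions (avoiding homozygously deleted loci). The variant read count in
#' each region is binomial with success probability
#' \eqn{v = p m C / (p CN_T + (1-p) CN_N)} where \eqn{p} is region purity,
#' \eqn{m} the multiplicity, \eqn{C} the cluster prevalence, and \eqn{CN_T}
#' the locus copy number; total depth is Poisson around `coverageMean`.
#' Variant reads split 50/50 binomially between strands. Multiplicity is 1
#' unless a mutation lands in a clonally gained segment, where it is drawn
#' uniformly from 1..CN_T. When the topology is `two_primary` the root carries
#' no somatic mutations (only the knock-in transgenes); otherwise the root's
#' mutations are the clonal (ubiquitous) somatic set. Two transgene knock-in
#' mutations flagged `knockin` are always emitted at prevalence 1.
#'
#' @param tree a [TruthTree-class].
#' @param nMutPerCluster mutations per cluster (scalar or per-cluster vector).
#' @param coverageMean mean sequencing depth per region.
#' @param purity numeric per-region purity, length = regions of `tree`.
#' @param cnProfile data.frame from [simulateCnProfile()].
#' @param genome data.frame from [defaultGenome()].
#' @param seed RNG seed.
#' @return data.frame in long format: one row per mutation and region with
#'   columns `id`, `gene`, `chrom`, `pos`, `cluster`, `m`, `knockin`,
#'   `region`, `cnt`, `depth`, `var`, `fwd`, `rev`, `vaf`.
#' @export
simulateMutationReads <- function(tree, nMutPerCluster = 6L,
                                  coverageMean = 300, purity,
                                  cnProfile, genome = defaultGenome(),
                                  seed = NULL) {
    stopifnot(is(tree, "TruthTree"), coverageMean > 0)
    P <- tree@prevalence
    regions <- colnames(P)
    stopifnot(length(purity) == length(regions))
    ids <- rownames(P)
    nPer <- rep_len(nMutPerCluster, length(ids))
    names(nPer) <- ids
    if (tree@topology == "two_primary")
        nPer[tree@rootId] <- 0L
    withSeed(seed, {
        rows <- list()
        mutIdx <- 0L
        addMutation <- function(cluster, gene, knockin) {
            ## position avoiding HD loci in any region
            repeat {
                ci <- sample.int(nrow(genome), 1L)
                chrom <- genome$chrom[ci]
                pos <- floor(runif(1, 0, genome$length[ci]))
                cnt <- vapply(regions, function(rg)
                    .cnAt(cnProfile, rg, chrom, pos), integer(1))
                if (all(cnt >= 1L)) break
            }
            m <- 1L
            if (length(unique(cnt)) == 1L && cnt[1L] > 2L)
                m <- sample.int(cnt[1L], 1L)
            m <- min(m, min(cnt))
            mutIdx <<- mutIdx + 1L
            id <- sprintf("mut%03d", mutIdx)
            for (k in seq_along(regions)) {
                p <- purity[k]
                C <- P[cluster, k]
                vexp <- if (cnt[k] == 0L) 0 else
                    p * m * C / (p * cnt[k] + (1 - p) * 2)
                depth <- rpois(1L, coverageMean)
                var <- rbinom(1L, depth, vexp)
                fwd <- rbinom(1L, var, 0.5)
                rows[[length(rows) + 1L]] <<- data.frame(
                    id = id, gene = gene, chrom = chrom, pos = pos,
                    cluster = cluster, m = m, knockin = knockin,
                    region = regions[k], cnt = cnt[k], depth = depth,
                    var = var, fwd = fwd, rev = var - fwd,
                    vaf = ifelse(depth > 0, var / depth, 0),
                    stringsAsFactors = FALSE)
            }
        }
        addMutation(tree@rootId, "Kras_KI", TRUE)
        addMutation(tree@rootId, "Trp53_KI", TRUE)
        for (cl in ids)
            for (j in seq_len(nPer[[cl]]))
                addMutation(cl, sprintf("%s_m%d", cl, j), FALSE)
        do.call(rbind, rows)
    })
}

#' Simulate an aCGH probe log-ratio track
#'
#' Probes are laid at fixed spacing along every chromosome; each probe reports
#' \eqn{\log_2((p CN_T + (1-p) CN_N) / CN_N)} for the copy number of its
#' segment in that region, plus Gaussian noise.
#'
#' @param cnProfile data.frame from [simulateCnProfile()].
#' @param purity numeric per-region purity (named by region or in region
#'   order).
#' @param probeSpacing probe spacing in bp.
#' @param noiseSd Gaussian noise standard deviation on the log2 ratio.
#' @param genome data.frame from [defaultGenome()].
#' @param seed RNG seed.
#' @return data.frame with columns `region`, `chrom`, `pos`, `log2ratio`.
#' @export
simulateAcgh <- function(cnProfile, purity, probeSpacing = 1e4,
                         noiseSd = 0.15, genome = defaultGenome(),
                         seed = NULL) {
    stopifnot(noiseSd >= 0)
    regions <- unique(cnProfile$region)
    stopifnot(length(purity) == length(regions))
    if (is.null(names(purity))) names(purity) <- regions
    withSeed(seed, {
        out <- list()
        for (rg in regions) {
            p <- purity[[rg]]
            sub <- cnProfile[cnProfile$region == rg, , drop = FALSE]
            for (i in seq_len(nrow(genome))) {
                chrom <- genome$chrom[i]
                pos <- seq(floor(probeSpacing / 2), genome$length[i] - 1,
                           by = probeSpacing)
                seg <- sub[sub$chrom == chrom, , drop = FALSE]
                cnt <- rep(2L, length(pos))
                for (j in seq_len(nrow(seg))) {
                    inSeg <- pos >= seg$start[j] & pos < seg$end[j]
                    cnt[inSeg] <- seg$cnt[j]
                }
                mix <- pmax(p * cnt + (1 - p) * 2, 2^-8)
                lr <- log2(mix / 2) + rnorm(length(pos), 0, noiseSd)
                out[[length(out) + 1L]] <- data.frame(
                    region = rg, chrom = chrom, pos = pos, log2ratio = lr,
                    stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, out)
    })
}

#' Simulate germline het-SNP allele counts
#'
#' SNPs are placed uniformly; the matched normal draws its alternate count at
#' probability 0.5 (balanced heterozygote). In regions of one-copy loss the
#' tumor's expected minor allele frequency is \eqn{(1-p)/(2-p)}; which parental
#' allele was lost is drawn once per SNP, so the tumor alternate-allele
#' probability is that value or its complement. Elsewhere the tumor stays at
#' 0.5.
#'
#' @param lossIntervals data.frame of one-copy-loss spans with columns
#'   `region`, `chrom`, `start`, `end` (may be empty).
#' @param purity numeric per-region purity named by region (scalar recycled).
#' @param coverage mean tumor depth at SNPs.
#' @param nSnps number of SNP positions.
#' @param normalCoverage mean normal depth at SNPs.
#' @param genome data.frame from [defaultGenome()].
#' @param regions character vector of region names.
#' @param seed RNG seed.
#' @return data.frame with one row per SNP and region: `snp`, `chrom`, `pos`,
#'   `region`, `t_ref`, `t_alt`, `n_ref`, `n_alt`.
#' @export
simulateSnpCounts <- function(lossIntervals, purity, coverage = 70,
                              nSnps = 2000L, normalCoverage = 100,
                              genome = defaultGenome(),
                              regions = paste0("T", seq_along(purity)),
                              seed = NULL) {
    stopifnot(coverage >= 1)
    if (is.null(names(purity))) names(purity) <- regions
    withSeed(seed, {
        ci <- sample.int(nrow(genome), nSnps, replace = TRUE)
        chrom <- genome$chrom[ci]
        pos <- floor(runif(nSnps, 0, genome$length[ci]))
        altLost <- runif(nSnps) < 0.5
        out <- list()
        for (rg in regions) {
            p <- purity[[rg]]
            loss <- lossIntervals[lossIntervals$region == rg, , drop = FALSE]
            inLoss <- rep(FALSE, nSnps)
            for (j in seq_len(nrow(loss)))
                inLoss <- inLoss | (chrom == loss$chrom[j] &
                                    pos >= loss$start[j] & pos < loss$end[j])
            qAlt <- rep(0.5, nSnps)
            mafLoss <- expectedLossMaf(p)
            qAlt[inLoss & altLost] <- mafLoss
            qAlt[inLoss & !altLost] <- 1 - mafLoss
            tDp <- rpois(nSnps, coverage)
            tAlt <- rbinom(nSnps, tDp, qAlt)
            nDp <- rpois(nSnps, normalCoverage)
            nAlt <- rbinom(nSnps, nDp, 0.5)
            out[[length(out) + 1L]] <- data.frame(
                snp = sprintf("snp%05d", seq_len(nSnps)), chrom = chrom,
                pos = pos, region = rg, t_ref = tDp - tAlt, t_alt = tAlt,
                n_ref = nDp - nAlt, n_alt = nAlt, stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
    })
}

## ---- whole-mouse / cohort --------------------------------------------------

#' Simulate one multi-region mouse tumor
#'
#' Draws a truth tree, per-region purity, a copy-number truth profile, then
#' all measured data layers (amplicon read counts, aCGH probes, het-SNP
#' counts, qPCR standards and sample Cts).
#'
#' @param mouseId sample name.
#' @param genotype `"KPC"` or `"KPTC"`.
#' @param nClusters,topology,margin passed to [simulateTree()].
#' @param nRegions number of tumor regions.
#' @param purity optional per-region purity; drawn from U(0.4, 0.9) if `NULL`.
#' @param coverageMean amplicon depth (tumor regions).
#' @param snpCoverage tumor depth at het-SNPs.
#' @param nSnps number of het-SNP positions.
#' @param probeSpacing,noiseSd aCGH track parameters.
#' @param nMutPerCluster somatic mutations per cluster.
#' @param cnEvents optional event table for [simulateCnProfile()].
#' @param genome synthetic genome.
#' @param seed RNG seed.
#' @return A [SimulatedMouse-class].
#' @export
simulateMouse <- function(mouseId = "M1", genotype = c("KPC", "KPTC"),
                          nClusters = 3L, topology = "branched",
                          nRegions = 3L, purity = NULL, coverageMean = 300,
                          snpCoverage = 70, nSnps = 1500L,
                          probeSpacing = 1e4, noiseSd = 0.15,
                          nMutPerCluster = 6L, margin = 0.15,
                          cnEvents = NULL, genome = defaultGenome(),
                          seed = NULL) {
    genotype <- match.arg(genotype)
    withSeed(seed, {
        if (is.null(purity))
            purity <- runif(nRegions, 0.4, 0.9)
        regions <- paste0("T", seq_len(nRegions))
        names(purity) <- regions
        tree <- simulateTree(nClusters, topology, nRegions, margin,
                             seed = NULL)
        cn <- simulateCnProfile(genome, nRegions, events = cnEvents,
                                seed = NULL)
        muts <- simulateMutationReads(tree, nMutPerCluster, coverageMean,
                                      purity, cn, genome, seed = NULL)
        probes <- simulateAcgh(cn, purity, probeSpacing, noiseSd, genome,
                               seed = NULL)
        loss <- cn[cn$cnt == 1L, c("region", "chrom", "start", "end")]
        snps <- simulateSnpCounts(loss, purity, snpCoverage, nSnps,
                                  genome = genome, regions = regions,
                                  seed = NULL)
        ## qPCR: template excised in tumor cells, so Ct rises with purity
        slope <- 8; intercept <- 22; ctSd <- 0.15
        stdPur <- rep(c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1), each = 3L)
        standards <- data.frame(
            purity = stdPur,
            ct = slope * stdPur + intercept + rnorm(length(stdPur), 0, ctSd))
        ctSample <- do.call(rbind, lapply(regions, function(rg)
            data.frame(region = rg,
                       ct = slope * purity[[rg]] + intercept +
                           rnorm(3L, 0, ctSd),
                       stringsAsFactors = FALSE)))
        new("SimulatedMouse", mouseId = mouseId, genotype = genotype,
            purity = purity, tree = tree, mutations = muts, probes = probes,
            snps = snps, cnTruth = cn, ctStandards = standards,
            ctSample = ctSample)
    })
}

#' Simulate a full multi-region cohort
#'
#' Twelve mice (half KPC, half KPTC by default), each with 2-7 mutation
#' clusters and a linear, branched or two-primary truth topology. A recurrent
#' focal homozygous deletion is planted at a fixed locus in a subset of mice
#' to exercise cross-mouse recurrence counting.
#'
#' @param nMice number of mice.
#' @param nRegions regions per mouse.
#' @param recurrentHdMice how many mice carry the planted recurrent focal
#'   deletion.
#' @param topologies optional character vector of per-mouse topologies.
#' @param nClusters optional integer vector of per-mouse cluster counts.
#' @param seed RNG seed (sub-seeds per mouse are derived from it).
#' @param ... further arguments passed to [simulateMouse()].
#' @return named list of [SimulatedMouse-class] objects.
#' @export
simulateCohort <- function(nMice = 12L, nRegions = 3L, recurrentHdMice = 9L,
                           topologies = NULL, nClusters = NULL, seed = 1L,
                           ...) {
    stopifnot(nMice >= 1L, recurrentHdMice <= nMice)
    genome <- defaultGenome()
    if (is.null(topologies)) {
        topologies <- withSeed(subSeed(seed, 900L), {
            tp <- rep_len(c("linear", "branched"), nMice)
            if (nMice >= 6L) tp[3L] <- "two_primary"
            sample(tp)
        })
    }
    if (is.null(nClusters)) {
        nClusters <- withSeed(subSeed(seed, 901L),
                              sample(2:7, nMice, replace = TRUE))
        nClusters[topologies != "linear"] <-
            pmax(nClusters[topologies != "linear"], 3L)
    }
    hdCarriers <- seq_len(recurrentHdMice)
    len <- genome$length[1]
    lapply(setNames(seq_len(nMice), sprintf("M%02d", seq_len(nMice))),
           function(i) {
        ev <- data.frame(
            chrom = genome$chrom[c(1, 3, 4)],
            start = c(0.2, 0.30, 0.05) * len,
            end   = c(0.85, 0.90, 0.55) * len,
            cnt   = c(3L, 1L, 1L),
            regions = NA_character_, stringsAsFactors = FALSE)
        if (i %in% hdCarriers)
            ev <- rbind(ev, data.frame(chrom = genome$chrom[2],
                                       start = 0.10 * len, end = 0.155 * len,
                                       cnt = 0L, regions = NA_character_))
        simulateMouse(mouseId = sprintf("M%02d", i),
                      genotype = if (i <= ceiling(nMice / 2)) "KPC"
                                 else "KPTC",
                      nClusters = nClusters[i], topology = topologies[i],
                      nRegions = nRegions, cnEvents = ev, genome = genome,
                      seed = subSeed(seed, i), ...)
    })
}
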