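## Clustering of mutations by cancer cell prevalence across tumor regions.
##
## Density-based clustering (DBSCAN) over a sweep of radius values, scored by
## average silhouette width, followed by a divisive refinement pass that
## re-examines each cluster for internal density structure; affinity
## propagation is the fallback when no density solution passes the quality
## gates. The refinement exists because the average silhouette is biased
## toward coarse solutions in nested subclonal data: the large gap between
## the clonal cluster and everything subclonal rewards merging adjacent
## subclonal clusters, so the globally best silhouette frequently hides a
## real split that a within-cluster sweep exposes.

## DBSCAN on a Euclidean distance matrix. Returns integer labels with 0 for
## noise. Classic region-query formulation; minPts includes the point itself.
.dbscan <- function(d, eps, minPts = 2L) {
    d <- as.matrix(d)
    n <- nrow(d)
    labels <- rep(0L, n)
    visited <- rep(FALSE, n)
    cl <- 0L
    neighbors <- function(i) which(d[i, ] <= eps)
    for (i in seq_len(n)) {
        if (visited[i]) next
        visited[i] <- TRUE
        nb <- neighbors(i)
        if (length(nb) < minPts) next   # provisional noise
        cl <- cl + 1L
        labels[i] <- cl
        queue <- setdiff(nb, i)
        while (length(queue)) {
            j <- queue[1L]
            queue <- queue[-1L]
            if (!visited[j]) {
                visited[j] <- TRUE
                nb2 <- neighbors(j)
                if (length(nb2) >= minPts)
                    queue <- c(queue,
                               setdiff(nb2, which(visited | labels > 0L)))
            }
            if (labels[j] == 0L) labels[j] <- cl
        }
    }
    labels
}

## Affinity propagation (responsibility/availability message passing) on a
## similarity matrix; preference defaults to the median similarity.
.affinityPropagation <- function(S, damping = 0.9, maxIter = 500L,
                                 convIter = 50L, preference = NULL) {
    n <- nrow(S)
    if (is.null(preference))
        preference <- median(S[upper.tri(S) | lower.tri(S)])
    diag(S) <- preference
    ## tiny deterministic jitter breaks symmetry without an RNG
    jit <- outer(seq_len(n), seq_len(n),
                 function(i, j) ((i * 31 + j * 17) %% 101) / 101)
    S <- S + 1e-10 * jit
    R <- matrix(0, n, n)
    A <- matrix(0, n, n)
    lastEx <- rep(-1L, n)
    stable <- 0L
    for (iter in seq_len(maxIter)) {
        AS <- A + S
        firstMax <- apply(AS, 1, max)
        whichMax <- max.col(AS, ties.method = "first")
        secondMax <- vapply(seq_len(n), function(i)
            max(AS[i, -whichMax[i]]), numeric(1))
        Rnew <- S - firstMax
        for (i in seq_len(n))
            Rnew[i, whichMax[i]] <- S[i, whichMax[i]] - secondMax[i]
        R <- damping * R + (1 - damping) * Rnew
        Rp <- pmax(R, 0)
        diag(Rp) <- diag(R)
        colSums_Rp <- colSums(Rp)
        Anew <- matrix(rep(colSums_Rp, each = n), n, n) - Rp
        dA <- diag(Anew)
        Anew <- pmin(Anew, 0)
        diag(Anew) <- dA
        A <- damping * A + (1 - damping) * Anew
        ex <- which(diag(A + R) > 0)
        if (identical(ex, lastEx) && length(ex)) {
            stable <- stable + 1L
            if (stable >= convIter) break
        } else {
            stable <- 0L
            lastEx <- ex
        }
    }
    exemplars <- which(diag(A + R) > 0)
    if (!length(exemplars))
        exemplars <- which.max(diag(A + R))
    assign <- apply(S[, exemplars, drop = FALSE], 1, which.max)
    assign[exemplars] <- seq_along(exemplars)
    as.integer(assign)
}

.meanSilhouette <- function(d, labels) {
    if (length(unique(labels)) < 2L) return(NA_real_)
    sil <- cluster::silhouette(labels, dist = d)
    mean(sil[, "sil_width"])
}

## best-silhouette multi-cluster DBSCAN solution over an eps sweep, subject
## to the noise and silhouette gates; NULL when none qualifies
.dbscanBest <- function(X, epsGrid, minPts, minSilhouette, maxNoiseFrac) {
    if (nrow(X) < 2L * minPts) return(NULL)
    d <- dist(X)
    best <- NULL
    for (eps in epsGrid) {
        lab <- .dbscan(d, eps, minPts)
        noiseFrac <- mean(lab == 0L)
        if (noiseFrac > maxNoiseFrac) next
        k <- length(unique(lab[lab > 0L]))
        if (k < 2L) next
        core <- lab > 0L
        sil <- .meanSilhouette(dist(X[core, , drop = FALSE]), lab[core])
        if (is.na(sil) || sil < minSilhouette) next
        if (is.null(best) || sil > best$sil)
            best <- list(lab = lab, sil = sil, eps = eps)
    }
    best
}

## attach noise points (label 0) to the nearest cluster centroid and
## renumber labels 1..k
.attachNoise <- function(X, lab) {
    ks <- sort(unique(lab[lab > 0L]))
    lab <- match(lab, ks, nomatch = 0L)
    centers <- do.call(rbind, lapply(seq_along(ks), function(k)
        colMeans(X[lab == k, , drop = FALSE])))
    for (i in which(lab == 0L))
        lab[i] <- which.min(colSums((t(centers) - X[i, ])^2))
    lab
}

## divisive refinement: re-sweep DBSCAN inside each cluster and accept a
## split only on strong local evidence (higher silhouette gate) and a
## meaningful prevalence separation between the resulting centers
.refineClusters <- function(X, lab, epsGrid, minPts, refineSil, minSep,
                            maxNoiseFrac) {
    repeat {
        changed <- FALSE
        for (k in sort(unique(lab))) {
            idx <- which(lab == k)
            if (length(idx) < 2L * minPts) next
            sub <- .dbscanBest(X[idx, , drop = FALSE], epsGrid, minPts,
                               refineSil, maxNoiseFrac)
            if (is.null(sub)) next
            slab <- .attachNoise(X[idx, , drop = FALSE], sub$lab)
            centers <- do.call(rbind, lapply(sort(unique(slab)), function(j)
                colMeans(X[idx[slab == j], , drop = FALSE])))
            dd <- as.matrix(dist(centers, method = "maximum"))
            if (min(dd[upper.tri(dd)]) < minSep) next
            lab[idx] <- max(lab) + slab
            lab <- match(lab, sort(unique(lab)))
            changed <- TRUE
            break
        }
        if (!changed) return(lab)
    }
}

#' Cluster mutations by cancer cell prevalence
#'
#' Runs DBSCAN over a grid of radius values on the mutations-by-regions
#' prevalence matrix; candidate solutions must label at most `maxNoiseFrac`
#' of the points as noise and reach an average silhouette width of at least
#' `minSilhouette`. The best-silhouette solution is then refined divisively:
#' each cluster is re-swept in isolation and split when the within-cluster
#' solution shows strong density structure (silhouette at least `refineSil`)
#' and the resulting centers differ by at least `minSep` in some region.
#' When no multi-cluster solution passes the gates but some radius yields a
#' single dense cluster, that cluster (after refinement) is returned;
#' otherwise affinity propagation is used as the secondary approach. Noise
#' points are attached to the nearest cluster centroid.
#'
#' Missing entries: if some columns (regions) are complete across all rows
#' they alone are used; otherwise rows containing missing values are excluded
#' from clustering and reported with `NA` assignments.
#'
#' @param prevalence numeric matrix, mutations (rows, named) x regions.
#' @param epsGrid DBSCAN radius sweep.
#' @param minPts DBSCAN minimum neighborhood size (point included).
#' @param minSilhouette,maxNoiseFrac quality gates for the global sweep.
#' @param refineSil local silhouette gate of the divisive refinement.
#' @param minSep minimum per-region separation between split centers.
#' @param seed unused randomness guard (all steps are deterministic); kept
#'   for interface stability.
#' @return A [PrevalenceClustering-class].
#' @export
clusterByPrevalence <- function(prevalence, epsGrid = seq(0.02, 0.30, 0.02),
                                minPts = 4L, minSilhouette = 0.25,
                                maxNoiseFrac = 0.2, refineSil = 0.45,
                                minSep = 0.10, seed = NULL) {
    stopifnot(is.matrix(prevalence))
    if (is.null(rownames(prevalence)))
        rownames(prevalence) <- sprintf("mut%03d", seq_len(nrow(prevalence)))
    full <- prevalence
    usedCols <- colnames(prevalence) %||%
        paste0("T", seq_len(ncol(prevalence)))
    colnames(full) <- usedCols
    ## missing-value policy
    completeCols <- colSums(is.na(full)) == 0L
    if (any(completeCols) && !all(completeCols)) {
        X <- full[, completeCols, drop = FALSE]
        usable <- rep(TRUE, nrow(full))
    } else {
        usable <- complete.cases(full)
        X <- full[usable, , drop = FALSE]
    }
    if (sum(usable) < 2L) {
        warning("fewer than 2 usable mutations: returning a trivial cluster")
        centers <- matrix(colMeans(full, na.rm = TRUE), 1,
                          dimnames = list("1", usedCols))
        sds <- matrix(0, 1, length(usedCols),
                      dimnames = list("1", usedCols))
        assign <- setNames(rep(NA_integer_, nrow(full)), rownames(full))
        assign[usable] <- 1L
        return(new("PrevalenceClustering", assignments = assign,
                   centers = centers, sds = sds, method = "trivial",
                   silhouette = NA_real_, eps = NA_real_))
    }
    d <- dist(X)
    method <- "dbscan"
    bestEps <- NA_real_
    if (max(as.matrix(d)) < 1e-12) {
        labels <- rep(1L, nrow(X))
    } else {
        best <- .dbscanBest(X, epsGrid, minPts, minSilhouette, maxNoiseFrac)
        if (!is.null(best)) {
            labels <- .attachNoise(X, best$lab)
            bestEps <- best$eps
        } else {
            ## single dense cluster at some radius?
            singleOk <- any(vapply(epsGrid, function(eps) {
                lab <- .dbscan(d, eps, minPts)
                mean(lab == 0L) <= maxNoiseFrac &&
                    length(unique(lab[lab > 0L])) == 1L
            }, logical(1)))
            if (singleOk) {
                labels <- rep(1L, nrow(X))
            } else {
                S <- -as.matrix(d)^2
                labels <- .affinityPropagation(S)
                method <- "affinity_propagation"
            }
        }
        if (method == "dbscan")
            labels <- .refineClusters(X, labels, epsGrid, minPts,
                                      refineSil, minSep, maxNoiseFrac)
    }
    bestSil <- .meanSilhouette(d, labels)
    ## report centers/sds over all regions (including incomplete ones)
    kFinal <- sort(unique(labels))
    centers <- do.call(rbind, lapply(kFinal, function(k) {
        colMeans(full[usable, , drop = FALSE][labels == k, , drop = FALSE],
                 na.rm = TRUE)
    }))
    sds <- do.call(rbind, lapply(kFinal, function(k) {
        sub <- full[usable, , drop = FALSE][labels == k, , drop = FALSE]
        vapply(seq_len(ncol(sub)), function(j) {
            v <- sub[, j]
            v <- v[!is.na(v)]
            if (length(v) > 1L) sd(v) else 0
        }, numeric(1))
    }))
    dimnames(centers) <- list(as.character(seq_along(kFinal)), usedCols)
    dimnames(sds) <- dimnames(centers)
    assign <- setNames(rep(NA_integer_, nrow(full)), rownames(full))
    assign[usable] <- labels
    new("PrevalenceClustering", assignments = assign,
        centers = pmin(pmax(centers, 0), 1), sds = sds, method = method,
        silhouette = bestSil, eps = bestEps)
}
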