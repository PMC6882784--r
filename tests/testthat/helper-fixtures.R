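## Shared fixture builders for the test suite. Everything is generated in
## code; no data files.

## a minimal segment table (0-based half-open) with the columns the
## copy-number callers expect
makeSegments <- function(chrom, start, end, cnt, nProbes = 10L,
                         segMean = NA_real_, segSd = 0.05) {
    data.frame(chrom = chrom, start = start, end = end,
               nProbes = rep_len(nProbes, length(chrom)),
               segMean = rep_len(segMean, length(chrom)),
               segSd = rep_len(segSd, length(chrom)),
               cnt = cnt, stringsAsFactors = FALSE)
}

## a one-gene-per-interval gene table
makeGenes <- function(chrom, start, end,
                      name = sprintf("g%02d", seq_along(chrom))) {
    data.frame(chrom = chrom, start = start, end = end, name = name,
               stringsAsFactors = FALSE)
}

## long-format mutation rows for one mutation across regions
makeCall <- function(id, region, depth, var, fwd = NULL, rev = NULL) {
    if (is.null(fwd)) fwd <- var %/% 2L
    if (is.null(rev)) rev <- var - fwd
    data.frame(id = id, region = region, depth = depth, var = var,
               fwd = fwd, rev = rev, stringsAsFactors = FALSE)
}

## adjusted Rand index via mclust (independent of the package's clustering)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## noisy prevalence matrix drawn around given cluster centers
drawPrevalence <- function(centers, perCluster = 10L, noiseSd = 0.03,
                           seed = 1L) {
    set.seed(seed)
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
        matrix(rep(centers[k, ], each = perCluster), perCluster) +
            rnorm(perCluster * ncol(centers), 0, noiseSd)))
    X <- pmin(pmax(X, 0), 1)
    rownames(X) <- sprintf("m%03d", seq_len(nrow(X)))
    attr(X, "truth") <- rep(seq_len(nrow(centers)), each = perCluster)
    X
}

## map truth clusters onto recovered cluster labels by nearest center;
## returns NULL when the counts differ or the mapping is not one-to-one
matchClusters <- function(truthCenters, centers) {
    if (nrow(truthCenters) != nrow(centers)) return(NULL)
    map <- vapply(seq_len(nrow(truthCenters)), function(i)
        which.min(colSums((t(centers) - truthCenters[i, ])^2)), 1L)
    if (anyDuplicated(map)) return(NULL)
    setNames(rownames(centers)[map], rownames(truthCenters))
}

## expected recovered parent map for a truth tree whose root either carries
## somatic mutations (linear/branched: root cluster observed) or not
## (two_primary: root cluster absent from the data)
expectedParentMap <- function(tree, map, rootId = "root") {
    parents <- treeParents(tree)
    obs <- names(map)
    out <- setNames(rep(NA_character_, length(obs) + 1L),
                    c(rootId, unname(map[obs])))
    out[rootId] <- NA_character_
    for (id in obs) {
        par <- parents[[id]]
        out[map[[id]]] <- if (is.na(par) || !(par %in% obs)) rootId
                          else map[[par]]
    }
    out
}
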