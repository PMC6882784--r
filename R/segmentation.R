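## Probe-track segmentation: recursive binary splitting with a permutation
## test on the max-t split statistic, followed by an "undo" merge of adjacent
## segments whose means are within 3 pooled standard deviations.

## max over split points of |mean difference| * sqrt(k (n-k) / n)
.maxSplitStat <- function(x, minSeg) {
    n <- length(x)
    ks <- seq.int(minSeg, n - minSeg)
    cs <- cumsum(x)
    tot <- cs[n]
    m1 <- cs[ks] / ks
    m2 <- (tot - cs[ks]) / (n - ks)
    stat <- abs(m1 - m2) * sqrt(ks * (n - ks) / n)
    i <- which.max(stat)
    c(stat = stat[i], k = ks[i])
}

.splitSignificant <- function(x, obs, alpha, nPerm, minSeg) {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
        if (.maxSplitStat(sample(x), minSeg)[["stat"]] >= obs)
            exceed <- exceed + 1L
    }
    (1 + exceed) / (nPerm + 1) < alpha
}

#' Segment a probe log-ratio track into constant-copy-number regions
#'
#' Within each chromosome, the probe sequence is split recursively at the
#' point maximizing the standardized mean difference between the two sides;
#' a split is kept when its statistic is significant against `nPerm`
#' permutations of the probe values at level `alpha`. Segment boundaries are
#' placed halfway between the flanking probes.
#'
#' @param probes data.frame with columns `chrom`, `pos`, `log2ratio`, probes
#'   sorted by position within chromosome (one region's track).
#' @param alpha permutation significance level for accepting a split.
#' @param nPerm number of permutations per candidate split.
#' @param minSeg minimum probes per segment.
#' @param seed RNG seed (permutations are the only randomness).
#' @return data.frame of segments with columns `chrom`, `start`, `end`
#'   (0-based half-open), `nProbes`, `segMean`, `segSd`.
#' @export
segmentTrack <- function(probes, alpha = 0.01, nPerm = 100L, minSeg = 3L,
                         seed = NULL) {
    stopifnot(is.data.frame(probes),
              all(c("chrom", "pos", "log2ratio") %in% names(probes)))
    if (nrow(probes) == 0L)
        stop("empty probe track")
    if (is.unsorted(probes$pos[probes$chrom == probes$chrom[1]]))
        stop("probes must be sorted by position within chromosome")
    withSeed(seed, {
        out <- list()
        for (chrom in unique(probes$chrom)) {
            sub <- probes[probes$chrom == chrom, , drop = FALSE]
            x <- sub$log2ratio
            pos <- sub$pos
            n <- length(x)
            ## boundaries halfway between adjacent probes; outermost
            ## boundaries sit at the first/last probe positions
            cuts <- integer(0)
            recurse <- function(lo, hi) {
                len <- hi - lo + 1L
                if (len < 2L * minSeg) return(invisible())
                best <- .maxSplitStat(x[lo:hi], minSeg)
                if (.splitSignificant(x[lo:hi], best[["stat"]], alpha,
                                      nPerm, minSeg)) {
                    k <- lo + as.integer(best[["k"]]) - 1L
                    cuts <<- c(cuts, k)
                    recurse(lo, k)
                    recurse(k + 1L, hi)
                }
                invisible()
            }
            recurse(1L, n)
            cuts <- sort(cuts)
            idxStart <- c(1L, cuts + 1L)
            idxEnd <- c(cuts, n)
            bnd <- if (length(cuts))
                floor((pos[cuts] + pos[cuts + 1L]) / 2) else numeric(0)
            segStart <- c(pos[1L], bnd)
            segEnd <- c(bnd, pos[n] + 1)
            out[[length(out) + 1L]] <- data.frame(
                chrom = chrom, start = segStart, end = segEnd,
                nProbes = idxEnd - idxStart + 1L,
                segMean = vapply(seq_along(idxStart), function(i)
                    mean(x[idxStart[i]:idxEnd[i]]), numeric(1)),
                segSd = vapply(seq_along(idxStart), function(i) {
                    v <- x[idxStart[i]:idxEnd[i]]
                    if (length(v) > 1L) sd(v) else 0
                }, numeric(1)),
                stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
    })
}

#' Merge adjacent segments with indistinguishable means ("undo" rule)
#'
#' Adjacent segments within a chromosome whose means differ by less than
#' 3 pooled within-segment standard deviations are merged, iterating (most
#' similar pair first) until no further merge applies; the result is a
#' fixpoint, so the operation is idempotent.
#'
#' @param segments data.frame from [segmentTrack()] (columns `chrom`,
#'   `start`, `end`, `nProbes`, `segMean`, `segSd`).
#' @param nSd merge window in pooled standard deviations.
#' @return data.frame of the same shape with merged segments.
#' @export
mergeUndo <- function(segments, nSd = 3) {
    stopifnot(all(c("chrom", "start", "end", "nProbes", "segMean",
                    "segSd") %in% names(segments)))
    out <- list()
    for (chrom in unique(segments$chrom)) {
        s <- segments[segments$chrom == chrom, , drop = FALSE]
        s <- s[order(s$start), , drop = FALSE]
        repeat {
            if (nrow(s) < 2L) break
            i <- seq_len(nrow(s) - 1L)
            n1 <- s$nProbes[i]; n2 <- s$nProbes[i + 1L]
            v1 <- s$segSd[i]^2; v2 <- s$segSd[i + 1L]^2
            df <- pmax(n1 + n2 - 2L, 1L)
            pooled <- sqrt((pmax(n1 - 1L, 0L) * v1 +
                            pmax(n2 - 1L, 0L) * v2) / df)
            gap <- abs(s$segMean[i + 1L] - s$segMean[i])
            mergeable <- gap < nSd * pooled
            if (!any(mergeable)) break
            ## merge the closest pair (in pooled-sd units) first
            score <- ifelse(pooled > 0, gap / pooled, Inf)
            j <- which(mergeable)[which.min(score[mergeable])]
            nA <- s$nProbes[j]; nB <- s$nProbes[j + 1L]
            mA <- s$segMean[j]; mB <- s$segMean[j + 1L]
            m <- (nA * mA + nB * mB) / (nA + nB)
            v <- (pmax(nA - 1L, 0L) * s$segSd[j]^2 +
                  pmax(nB - 1L, 0L) * s$segSd[j + 1L]^2 +
                  nA * nB / (nA + nB) * (mA - mB)^2) /
                 max(nA + nB - 1L, 1L)
            s$end[j] <- s$end[j + 1L]
            s$nProbes[j] <- nA + nB
            s$segMean[j] <- m
            s$segSd[j] <- sqrt(max(v, 0))
            s <- s[-(j + 1L), , drop = FALSE]
        }
        out[[length(out) + 1L]] <- s
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
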