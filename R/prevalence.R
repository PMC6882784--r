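## Cancer-cell-prevalence estimation from allele-specific read counts.
##
## The expected variant allele frequency of a mutation carried at
## multiplicity m by a fraction C of cancer cells, in a sample of purity p
## and locus copy number CNT (normal CNN), is
##     v = p * m * C / (p * CNT + (1 - p) * CNN).
## The variant read count is binomial(r_tot, v); normalizing the binomial
## likelihood over a prevalence grid gives a discrete posterior for C.

#' Expected variant allele frequency of a subclonal mutation
#'
#' @param p tumor purity in (0, 1].
#' @param m multiplicity (mutated copies per cancer cell), 1..CNT.
#' @param C cancer cell prevalence in [0, 1].
#' @param cnt tumor copy number at the locus (must be >= 1: a mutation
#'   cannot reside in a homozygously deleted locus).
#' @param cnn normal copy number.
#' @return expected VAF, guaranteed in [0, 1] when m <= cnt.
#' @examples
#' expectedVaf(1, 1, 1, 2, 2)        # 0.5, clonal heterozygous
#' expectedVaf(0.5, 2, 1, 4, 2)      # 1/3
#' @export
expectedVaf <- function(p, m, C, cnt, cnn = 2) {
    if (any(cnt == 0))
        stop("CN_T = 0: a mutation cannot reside in a deleted locus")
    stopifnot(all(p > 0), all(p <= 1), all(m >= 1), all(m <= cnt),
              all(C >= 0), all(C <= 1))
    p * m * C / (p * cnt + (1 - p) * cnn)
}

#' Grid posterior of cancer cell prevalence
#'
#' Evaluates the binomial likelihood of `rA` variant reads out of `rTot`
#' over a prevalence grid 0..1 (step `gridStep`), normalizes it, and reports
#' the grid argmax with a central 95% interval of the grid mass (widened when
#' necessary to contain the argmax, e.g. for boundary estimates).
#'
#' @param rA variant read count.
#' @param rTot total read count.
#' @param p tumor purity.
#' @param cnt,cnn tumor/normal copy number at the locus.
#' @param m multiplicity.
#' @param gridStep grid resolution.
#' @param level interval mass.
#' @return A [PrevalenceEstimate-class].
#' @export
prevalencePosterior <- function(rA, rTot, p, cnt, cnn = 2, m = 1L,
                                gridStep = 0.01, level = 0.95) {
    stopifnot(rA <= rTot, rTot >= 1)
    grid <- seq(0, 1, by = gridStep)
    v <- expectedVaf(p, m, grid, cnt, cnn)
    v <- pmin(v, 1)
    w <- dbinom(rA, rTot, v)
    if (!any(w > 0))
        stop("all grid weights are numerically zero (rA = ", rA,
             ", rTot = ", rTot, ", p = ", p, ", CNT = ", cnt, ", m = ", m,
             "); check the copy-number and purity inputs")
    post <- w / sum(w)
    iMax <- which.max(post)
    cm <- cumsum(post)
    tail <- (1 - level) / 2
    lo <- grid[which(cm >= tail)[1L]]
    hi <- grid[which(cm >= 1 - tail)[1L]]
    lo <- min(lo, grid[iMax])
    hi <- max(hi, grid[iMax])
    new("PrevalenceEstimate", grid = grid, posterior = post,
        pointEstimate = grid[iMax], lower = lo, upper = hi,
        multiplicity = as.integer(m), missing = FALSE)
}

.missingPrevalence <- function() {
    new("PrevalenceEstimate", grid = numeric(0), posterior = numeric(0),
        pointEstimate = NA_real_, lower = NA_real_, upper = NA_real_,
        multiplicity = NA_integer_, missing = TRUE)
}

#' Resolve mutation multiplicity by deduction
#'
#' For loci with CN_T of 1 or 2, only m = 1 is plausible. In copy-gained
#' loci every m in 1..CN_T is enumerated and those implying a raw prevalence
#' \eqn{\hat v (p CN_T + (1-p) CN_N) / (p m)} above 1 (plus `tol`) are ruled
#' out; if exactly one m survives the estimate is produced with it, otherwise
#' the prevalence is treated as missing. A mutation with zero variant reads
#' has prevalence 0 regardless of m.
#'
#' @param rA,rTot variant/total read counts.
#' @param p tumor purity.
#' @param cnt,cnn tumor/normal copy number (CN_T >= 1).
#' @param tol tolerance above 1 for ruling out a multiplicity.
#' @param gridStep passed to [prevalencePosterior()].
#' @return list with elements `m` (integer or `NA`) and `estimate`
#'   (a [PrevalenceEstimate-class], missing when unresolved).
#' @export
resolveMultiplicity <- function(rA, rTot, p, cnt, cnn = 2, tol = 0.05,
                                gridStep = 0.01) {
    stopifnot(cnt >= 1)
    if (rA == 0)
        return(list(m = 1L,
                    estimate = prevalencePosterior(0L, rTot, p, cnt, cnn,
                                                   m = 1L,
                                                   gridStep = gridStep)))
    if (cnt <= 2L)
        return(list(m = 1L,
                    estimate = prevalencePosterior(rA, rTot, p, cnt, cnn,
                                                   m = 1L,
                                                   gridStep = gridStep)))
    vhat <- rA / rTot
    rawC <- vhat * (p * cnt + (1 - p) * cnn) / (p * seq_len(cnt))
    plausible <- which(rawC <= 1 + tol)
    if (length(plausible) == 1L) {
        m <- plausible[[1L]]
        return(list(m = as.integer(m),
                    estimate = prevalencePosterior(rA, rTot, p, cnt, cnn,
                                                   m = m,
                                                   gridStep = gridStep)))
    }
    list(m = NA_integer_, estimate = .missingPrevalence())
}

#' Exclude tumor regions unusable for prevalence analysis
#'
#' A region is dropped when the maximum VAF over all its mutations is at or
#' below `maxVaf` (no mutation signal) or when it lacks a copy-number
#' profile.
#'
#' @param calls long-format mutation table with `region`, `depth`, `var`.
#' @param regionsWithCn character vector of regions that have a copy-number
#'   profile (defaults to all).
#' @param maxVaf the low-VAF exclusion cutoff.
#' @return character vector of retained region names.
#' @export
excludeLowVafRegions <- function(calls,
                                 regionsWithCn = unique(calls$region),
                                 maxVaf = 0.02) {
    vaf <- ifelse(calls$depth > 0, calls$var / calls$depth, 0)
    keep <- vapply(split(vaf, calls$region), function(v) max(v) > maxVaf,
                   logical(1))
    analyzed <- names(keep)[keep]
    intersect(analyzed, regionsWithCn)
}

#' Per-mutation prevalence estimates for a whole mouse
#'
#' Applies [resolveMultiplicity()] to every validated mutation in every
#' analyzed region, returning the mutations-by-regions matrix of point
#' estimates alongside the per-row detail table.
#'
#' @param calls long-format mutation table (`id`, `region`, `depth`, `var`,
#'   `cnt`).
#' @param purity named per-region purity vector.
#' @param regions regions to analyze.
#' @param cnn normal copy number.
#' @param tol multiplicity-deduction tolerance.
#' @return list with `matrix` (point estimates, `NA` where missing) and
#'   `detail` (data.frame with `id`, `region`, `m`, `c_hat`, `lower`,
#'   `upper`, `missing`).
#' @export
estimatePrevalence <- function(calls, purity,
                               regions = unique(calls$region), cnn = 2,
                               tol = 0.05) {
    calls <- calls[calls$region %in% regions, , drop = FALSE]
    ids <- unique(calls$id)
    mat <- matrix(NA_real_, length(ids), length(regions),
                  dimnames = list(ids, regions))
    rows <- list()
    for (i in seq_len(nrow(calls))) {
        id <- calls$id[i]; rg <- calls$region[i]
        cnt <- calls$cnt[i]
        if (is.na(cnt) || cnt < 1L || calls$depth[i] < 1L) {
            rows[[length(rows) + 1L]] <- data.frame(
                id = id, region = rg, m = NA_integer_, c_hat = NA_real_,
                lower = NA_real_, upper = NA_real_, missing = TRUE,
                stringsAsFactors = FALSE)
            next
        }
        res <- resolveMultiplicity(calls$var[i], calls$depth[i],
                                   purity[[rg]], cnt, cnn, tol)
        est <- res$estimate
        if (!est@missing)
            mat[id, rg] <- est@pointEstimate
        rows[[length(rows) + 1L]] <- data.frame(
            id = id, region = rg, m = res$m,
            c_hat = est@pointEstimate, lower = est@lower,
            upper = est@upper, missing = est@missing,
            stringsAsFactors = FALSE)
    }
    list(matrix = mat, detail = do.call(rbind, rows))
}
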