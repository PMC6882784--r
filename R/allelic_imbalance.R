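## Allelic-imbalance detection from germline heterozygous SNPs.
##
## In a tumor of purity p, a region with one-copy loss shows an expected
## minor allele frequency of (1 - p) / (2 - p) instead of 0, because the
## admixed normal cells retain both alleles. A per-sample MAF threshold is
## therefore calibrated by simulation at the sample's purity and coverage,
## and genes are tested by comparing tumor and normal MAFs of the ten
## informative SNPs nearest each gene midpoint.

#' Expected tumor minor allele frequency under one-copy loss
#'
#' @param p tumor purity in [0, 1].
#' @return \eqn{(1 - p) / (2 - p)}; 0.5 at p = 0, 0 at p = 1.
#' @examples
#' expectedLossMaf(0.5)   # 1/3
#' @export
expectedLossMaf <- function(p) {
    stopifnot(all(p >= 0), all(p <= 1))
    (1 - p) / (2 - p)
}

#' Calibrate the per-sample MAF threshold for allelic imbalance
#'
#' Simulates minor-allele read counts for `nSnps` hypothetical SNPs per class
#' (one-copy loss at the expected MAF for the sample's purity; balanced at
#' 0.5) with binomial sampling at the sample's coverage. MAFs are averaged
#' over disjoint consecutive subsets of `subsetSize`, then every threshold on
#' a 0-0.5 grid (step `gridStep`) is scored for classifying "MAF below
#' threshold" as imbalance. Among thresholds with sensitivity and specificity
#' above `minSensSpec`, the one maximizing F1 is chosen; if none qualifies
#' the sample is flagged as lacking power.
#'
#' @param p tumor purity in (0, 1].
#' @param coverage sequencing depth used for the binomial draws.
#' @param nSnps simulated SNPs per class.
#' @param subsetSize averaging block size (must divide `nSnps`).
#' @param gridStep threshold grid resolution.
#' @param minSensSpec sensitivity/specificity gate.
#' @param sample optional sample id carried into the result.
#' @param seed RNG seed.
#' @return A [ThresholdCalibration-class].
#' @export
calibrateMafThreshold <- function(p, coverage, nSnps = 10000L,
                                  subsetSize = 10L, gridStep = 0.01,
                                  minSensSpec = 0.8, sample = "",
                                  seed = NULL) {
    stopifnot(coverage >= 1, p > 0, p <= 1)
    if (nSnps %% subsetSize != 0L)
        stop("subsetSize must divide nSnps")
    withSeed(seed, {
        mafOf <- function(prob) {
            k <- rbinom(nSnps, coverage, prob)
            pmin(k, coverage - k) / coverage
        }
        block <- rep(seq_len(nSnps / subsetSize), each = subsetSize)
        lossAvg <- tapply(mafOf(expectedLossMaf(p)), block, mean)
        normAvg <- tapply(mafOf(0.5), block, mean)
        grid <- seq(0, 0.5, by = gridStep)
        nPos <- length(lossAvg); nNeg <- length(normAvg)
        best <- NULL
        for (thr in grid) {
            tp <- sum(lossAvg < thr); fn <- nPos - tp
            fp <- sum(normAvg < thr); tn <- nNeg - fp
            sens <- tp / nPos
            specv <- tn / nNeg
            if (sens <= minSensSpec || specv <= minSensSpec) next
            prec <- if (tp + fp > 0) tp / (tp + fp) else 0
            f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
            if (is.null(best) || f1 > best$f1)
                best <- list(thr = thr, sens = sens, spec = specv, f1 = f1)
        }
        if (is.null(best))
            return(new("ThresholdCalibration", sample = sample, purity = p,
                       coverage = as.numeric(coverage),
                       threshold = NA_real_, lackingPower = TRUE,
                       sensitivity = NA_real_, specificity = NA_real_,
                       f1 = NA_real_))
        new("ThresholdCalibration", sample = sample, purity = p,
            coverage = as.numeric(coverage), threshold = best$thr,
            lackingPower = FALSE, sensitivity = best$sens,
            specificity = best$spec, f1 = best$f1)
    })
}

## per-row MAF and DP from ref/alt counts
.mafCols <- function(snps) {
    snps$t_dp <- snps$t_ref + snps$t_alt
    snps$n_dp <- snps$n_ref + snps$n_alt
    snps$t_maf <- ifelse(snps$t_dp > 0,
                         pmin(snps$t_ref, snps$t_alt) / snps$t_dp, NA_real_)
    snps$n_maf <- ifelse(snps$n_dp > 0,
                         pmin(snps$n_ref, snps$n_alt) / snps$n_dp, NA_real_)
    snps
}

#' Test genes for allelic imbalance in one tumor region
#'
#' For each gene, the `k` informative SNPs (tumor and normal depth at least
#' `minDp`) nearest the gene midpoint (mean of its start/end, same
#' chromosome; ties broken by lower coordinate) are selected, and tumor MAFs
#' are compared to matched normal MAFs with a one-tailed paired t test
#' (alternative: tumor below normal). p values are Benjamini-Hochberg
#' corrected across all tested genes; a gene is flagged as harboring allelic
#' imbalance when its FDR is below `fdrLevel` and its mean tumor MAF is below
#' the calibrated threshold.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `name`.
#' @param snps data.frame with `chrom`, `pos`, `t_ref`, `t_alt`, `n_ref`,
#'   `n_alt` for one tumor region and its matched normal.
#' @param threshold calibrated MAF threshold (a number or a
#'   [ThresholdCalibration-class]); if the calibration lacks power every
#'   gene is returned untested with `ai = NA`.
#' @param k SNPs per gene.
#' @param minDp informative-depth cutoff.
#' @param fdrLevel FDR level for the imbalance call.
#' @return data.frame per gene: `gene`, `n_snps`, `mean_t_maf`,
#'   `mean_n_maf`, `p`, `fdr`, `ai` (logical).
#' @export
testAllelicImbalance <- function(genes, snps, threshold, k = 10L,
                                 minDp = 20L, fdrLevel = 0.05) {
    if (is(threshold, "ThresholdCalibration")) {
        if (threshold@lackingPower)
            return(data.frame(gene = genes$name, n_snps = 0L,
                              mean_t_maf = NA_real_, mean_n_maf = NA_real_,
                              p = NA_real_, fdr = NA_real_, ai = NA,
                              stringsAsFactors = FALSE))
        threshold <- threshold@threshold
    }
    snps <- .mafCols(snps)
    inf <- snps[snps$t_dp >= minDp & snps$n_dp >= minDp, , drop = FALSE]
    res <- lapply(seq_len(nrow(genes)), function(i) {
        mid <- (genes$start[i] + genes$end[i]) / 2
        cand <- inf[inf$chrom == genes$chrom[i], , drop = FALSE]
        if (nrow(cand) < 2L) {
            warning("gene ", genes$name[i],
                    " skipped: fewer than 2 informative SNPs")
            return(data.frame(gene = genes$name[i], n_snps = nrow(cand),
                              mean_t_maf = NA_real_, mean_n_maf = NA_real_,
                              p = NA_real_, stringsAsFactors = FALSE))
        }
        ord <- order(abs(cand$pos - mid), cand$pos)
        sel <- cand[ord[seq_len(min(k, nrow(cand)))], , drop = FALSE]
        d <- sel$t_maf - sel$n_maf
        pv <- if (all(abs(d - d[1]) < 1e-12)) {
            ## constant differences: no evidence either way
            1
        } else {
            t.test(sel$t_maf, sel$n_maf, paired = TRUE,
                   alternative = "less")$p.value
        }
        data.frame(gene = genes$name[i], n_snps = nrow(sel),
                   mean_t_maf = mean(sel$t_maf),
                   mean_n_maf = mean(sel$n_maf), p = pv,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$fdr <- p.adjust(res$p, method = "BH")
    res$ai <- !is.na(res$fdr) & res$fdr < fdrLevel &
        res$mean_t_maf < threshold
    res
}

#' Per-mouse union of allelic-imbalance gene sets
#'
#' Regions flagged as lacking power contribute nothing; at least one powered
#' region is required.
#'
#' @param aiSets list of character vectors of AI gene names per region;
#'   entries that are `NULL` or `NA` denote regions lacking power.
#' @return character vector (the union).
#' @export
aiUnion <- function(aiSets) {
    powered <- Filter(function(x) !is.null(x) && !anyNA(x), aiSets)
    if (!length(powered))
        stop("no powered region available for the union")
    sort(unique(unlist(powered)))
}

#' Cohort-level enrichment of allelic imbalance per gene
#'
#' The background rate is the mean per-mouse fraction of AI genes in the
#' group; each gene's upper-tail binomial p value for being AI in k of n mice
#' at that rate is Benjamini-Hochberg corrected across genes.
#'
#' @param aiMatrix logical matrix, genes (rows, named) x mice (cols).
#' @return data.frame per gene: `gene`, `nMice`, `k`, `p`, `fdr`.
#' @export
aiEnrichment <- function(aiMatrix) {
    stopifnot(is.matrix(aiMatrix))
    n <- ncol(aiMatrix)
    background <- mean(colMeans(aiMatrix))
    k <- rowSums(aiMatrix)
    p <- pbinom(k - 1, n, background, lower.tail = FALSE)
    data.frame(gene = rownames(aiMatrix), nMice = n, k = as.integer(k),
               p = p, fdr = p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a het-SNP allele count table
#'
#' TSV with columns `chrom`, `pos`, `t_ref`, `t_alt`, `n_ref`, `n_alt`
#' (and optionally `region`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readSnpCounts <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "t_ref", "t_alt", "n_ref", "n_alt")
                  %in% names(df)))
    df
}
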