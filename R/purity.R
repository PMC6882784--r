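#' Fit the qPCR purity standard curve
#'
#' Ordinary least squares fit of Ct against purity over a dilution series of
#' tumor-cell and normal DNA mixtures. All replicate points enter the fit
#' individually (not replicate means). The assay amplifies a template present
#' in normal but excised in tumor cells, so Ct grows as purity grows and the
#' slope is positive; a negative slope (template gained in tumor) is equally
#' valid — only a zero slope is rejected.
#'
#' @param standards data.frame with numeric columns `purity` (fraction in
#'   [0, 1]) and `ct`; one row per replicate measurement.
#' @return A [StandardCurve-class] object.
#' @examples
#' std <- data.frame(purity = c(0, 0.5, 1), ct = c(30, 25, 20))
#' fitStandardCurve(std)
#' @export
fitStandardCurve <- function(standards) {
    stopifnot(is.data.frame(standards),
              all(c("purity", "ct") %in% names(standards)))
    if (!all(is.finite(standards$ct)) || !all(is.finite(standards$purity)))
        stop("all purity and Ct values must be finite")
    if (length(unique(standards$purity)) < 2L)
        stop("standard curve needs at least 2 distinct purity levels ",
             "(singular design)")
    fit <- lm(ct ~ purity, data = standards)
    cf <- coef(fit)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (!is.finite(r2)) r2 <- NA_real_
    new("StandardCurve", slope = unname(cf[["purity"]]),
        intercept = unname(cf[["(Intercept)"]]), r.squared = r2,
        nPoints = nrow(standards))
}

#' Estimate tumor purity from sample Ct values
#'
#' Inverts the standard curve for each replicate Ct, averages the per-replicate
#' estimates, and clamps the mean into [0, 1] (assay noise can push estimates
#' slightly past the outermost standards).
#'
#' @param ct numeric vector of replicate Ct measurements for one sample.
#' @param curve a [StandardCurve-class].
#' @return A single purity value in [0, 1].
#' @examples
#' curve <- fitStandardCurve(data.frame(purity = c(0, 1), ct = c(30, 20)))
#' estimatePurity(c(24, 26), curve)   # 0.5
#' @export
estimatePurity <- function(ct, curve) {
    stopifnot(is(curve, "StandardCurve"))
    if (length(ct) < 1L)
        stop("at least one Ct replicate required")
    if (!all(is.finite(ct)))
        stop("non-finite Ct value")
    est <- mean((ct - curve@intercept) / curve@slope)
    min(1, max(0, est))
}

#' Read a qPCR standards table
#'
#' TSV with columns `purity` and `ct` (additional columns pass through).
#'
#' @param path file path.
#' @return data.frame suitable for [fitStandardCurve()].
#' @export
readCtStandards <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("purity", "ct") %in% names(df)))
    df
}
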