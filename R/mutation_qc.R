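## Read-count filters for somatic mutation discovery and validation, and
## spatial-heterogeneity categorization across tumor regions.

#' Discovery-stage read-count filter
#'
#' A candidate call passes in its discovery region when it has coverage of at
#' least 10 reads, at least 3 variant reads, a variant allele frequency of at
#' least 1%, and at least one variant read on each of the forward and reverse
#' strands.
#'
#' @param calls data.frame with per-call columns `depth`, `var`, `fwd`,
#'   `rev`.
#' @param minDepth,minVar,minVaf,minStrand the four cutoffs.
#' @return logical vector, `TRUE` for passing calls.
#' @export
discoveryFilter <- function(calls, minDepth = 10L, minVar = 3L,
                            minVaf = 0.01, minStrand = 1L) {
    stopifnot(all(c("depth", "var", "fwd", "rev") %in% names(calls)))
    vaf <- ifelse(calls$depth > 0, calls$var / calls$depth, 0)
    calls$depth >= minDepth & calls$var >= minVar & vaf >= minVaf &
        calls$fwd >= minStrand & calls$rev >= minStrand
}

#' Validation-stage four-filter rule over all regions
#'
#' A mutation is validated when each of the four criteria is met in at least
#' one tumor region (possibly different regions per criterion): variant
#' allele frequency at least 1%, at least 5 variant reads, at least 3 forward
#' strand variant reads, and at least 3 reverse strand variant reads.
#'
#' @param calls long-format data.frame with columns `id`, `depth`, `var`,
#'   `fwd`, `rev` (one row per mutation and region).
#' @param minVaf,minVar,minStrand the cutoffs.
#' @return named logical vector, one entry per mutation id.
#' @export
validationFilter <- function(calls, minVaf = 0.01, minVar = 5L,
                             minStrand = 3L) {
    stopifnot(all(c("id", "depth", "var", "fwd", "rev") %in% names(calls)))
    vaf <- ifelse(calls$depth > 0, calls$var / calls$depth, 0)
    byId <- split(seq_len(nrow(calls)), calls$id)
    vapply(byId, function(i) {
        any(vaf[i] >= minVaf) && any(calls$var[i] >= minVar) &&
            any(calls$fwd[i] >= minStrand) &&
            any(calls$rev[i] >= minStrand)
    }, logical(1))
}

#' Categorize validated mutations by spatial heterogeneity
#'
#' Knock-in transgene mutations are excluded. A mutation is present in a
#' region when its VAF is at least `minVaf` with at least `minVar` variant
#' reads there; it is ubiquitous when present in all analyzed regions,
#' partially shared when present in more than one but not all, and private
#' when present in exactly one. Regions excluded from analysis shrink the
#' denominator.
#'
#' @param calls long-format data.frame with `id`, `region`, `depth`, `var`
#'   and optionally `knockin`.
#' @param analyzedRegions regions considered (defaults to all in `calls`).
#' @param minVaf,minVar per-region presence rule.
#' @return data.frame per non-transgene mutation: `id`, `nPresent`,
#'   `category` (`ubiquitous`/`partially shared`/`private`/`absent`).
#' @export
categorizeHeterogeneity <- function(calls,
                                    analyzedRegions = unique(calls$region),
                                    minVaf = 0.01, minVar = 3L) {
    stopifnot(all(c("id", "region", "depth", "var") %in% names(calls)))
    if (!is.null(calls$knockin))
        calls <- calls[!calls$knockin, , drop = FALSE]
    calls <- calls[calls$region %in% analyzedRegions, , drop = FALSE]
    vaf <- ifelse(calls$depth > 0, calls$var / calls$depth, 0)
    present <- vaf >= minVaf & calls$var >= minVar
    byId <- split(present, calls$id)
    nPresent <- vapply(byId, sum, integer(1))
    nAnalyzed <- length(analyzedRegions)
    category <- ifelse(nPresent == 0L, "absent",
                ifelse(nPresent >= nAnalyzed, "ubiquitous",
                ifelse(nPresent > 1L, "partially shared", "private")))
    data.frame(id = names(byId), nPresent = as.integer(nPresent),
               category = category, stringsAsFactors = FALSE,
               row.names = NULL)
}
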