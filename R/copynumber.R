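## Purity-corrected integer copy number and focal / large-scale SCNA calling.
##
## The observed log2 tumor/normal ratio of a segment in a sample of purity p
## is log2((p*CNT + (1-p)*CNN) / CNN); inverting it and rounding yields the
## integer tumor copy number. Internal coordinates are 0-based half-open
## (BED convention); SEG I/O converts from 1-based inclusive.

#' Forward purity mixing: expected log2 ratio of a segment
#'
#' @param cnt integer tumor copy number.
#' @param p tumor purity in (0, 1].
#' @param cnn normal copy number (2 on autosomes).
#' @return numeric expected log2 tumor/normal ratio.
#' @export
purityLog2Ratio <- function(cnt, p, cnn = 2) {
    stopifnot(all(p > 0), all(p <= 1), all(cnn >= 1))
    log2((p * cnt + (1 - p) * cnn) / cnn)
}

#' Invert the purity mixing model to integer copy number
#'
#' @param log2ratio observed segment mean log2 ratio.
#' @param p tumor purity in (0, 1].
#' @param cnn normal copy number.
#' @return list with `realCn` (continuous) and `cnt` (rounded, floored at 0);
#'   both vectorized over `log2ratio`.
#' @examples
#' purityCorrect(1, p = 1)$cnt            # 4
#' purityCorrect(log2(1.25), p = 0.5)$cnt # 3
#' @export
purityCorrect <- function(log2ratio, p, cnn = 2) {
    if (any(p <= 0))
        stop("purity must be positive (p = 0 is not invertible)")
    stopifnot(all(p <= 1), all(cnn >= 1))
    realCn <- cnn * (2^log2ratio - (1 - p)) / p
    list(realCn = realCn, cnt = pmax(0L, as.integer(round(realCn))))
}

#' Attach purity-corrected copy number and class labels to segments
#'
#' @param segments data.frame with at least `chrom`, `start`, `end`,
#'   `nProbes`, `segMean`.
#' @param p tumor purity of the sample.
#' @param cnn normal copy number.
#' @return the segments with added columns `realCn`, `cnt`, `class`
#'   (`HD`, `loss`, `neutral`, `gain`, `Amp`).
#' @export
annotateCopyNumber <- function(segments, p, cnn = 2) {
    cc <- purityCorrect(segments$segMean, p, cnn)
    segments$realCn <- cc$realCn
    segments$cnt <- cc$cnt
    segments$class <- cut(segments$cnt,
                          breaks = c(-0.5, 0.5, cnn - 0.5, cnn + 0.5, 4.5,
                                     Inf),
                          labels = c("HD", "loss", "neutral", "gain", "Amp"))
    segments$class <- as.character(segments$class)
    segments
}

.toGRanges <- function(df) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(start = df$start + 1,
                                                  end = df$end))
    if (!is.null(df$name))
        S4Vectors::mcols(gr)$name <- df$name
    gr
}

#' Call focal copy-number events
#'
#' Focal events are homozygous deletions (CN_T = 0) or amplifications
#' (CN_T >= 5, i.e. a gain of at least three copies over the diploid state)
#' smaller than `sizeLimit`, covered by at least `minProbes` probes, on
#' autosomes. Same-class events whose boundaries lie less than `mergeGap`
#' apart are merged, and events not overlapping the coding span of at least
#' one gene are dropped.
#'
#' @param segments data.frame from [annotateCopyNumber()].
#' @param genes data.frame with `chrom`, `start`, `end`, `name` (0-based
#'   half-open), or a `GRanges`.
#' @param sizeLimit maximum focal span in bp (default 4 Mb).
#' @param minProbes minimum probes supporting a segment.
#' @param mergeGap same-class events closer than this are one event.
#' @return data.frame of events: `class`, `chrom`, `start`, `end`,
#'   `nProbes`, `genes` (comma-separated); zero rows if none.
#' @export
callFocalEvents <- function(segments, genes, sizeLimit = 4e6,
                            minProbes = 5L, mergeGap = 1e5) {
    stopifnot(all(c("cnt", "nProbes") %in% names(segments)))
    if (is.data.frame(genes)) genes <- .toGRanges(genes)
    cand <- segments[(segments$cnt == 0L | segments$cnt >= 5L) &
                     (segments$end - segments$start) < sizeLimit &
                     segments$nProbes >= minProbes &
                     isAutosome(segments$chrom), , drop = FALSE]
    if (!nrow(cand))
        return(data.frame(class = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          nProbes = integer(0), genes = character(0),
                          stringsAsFactors = FALSE))
    cand$class <- ifelse(cand$cnt == 0L, "HD", "Amp")
    out <- list()
    for (cls in unique(cand$class)) {
        sub <- cand[cand$class == cls, , drop = FALSE]
        gr <- .toGRanges(sub)
        S4Vectors::mcols(gr)$nProbes <- sub$nProbes
        red <- GenomicRanges::reduce(gr, min.gapwidth = mergeGap)
        hits <- GenomicRanges::findOverlaps(gr, red)
        np <- tapply(sub$nProbes[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits), sum)
        gh <- GenomicRanges::findOverlaps(red, genes, minoverlap = 1L)
        geneStr <- vapply(seq_along(red), function(i) {
            g <- S4Vectors::mcols(genes)$name[
                S4Vectors::subjectHits(gh)[S4Vectors::queryHits(gh) == i]]
            paste(g, collapse = ",")
        }, character(1))
        keep <- geneStr != ""
        if (any(keep))
            out[[length(out) + 1L]] <- data.frame(
                class = cls,
                chrom = as.character(GenomicRanges::seqnames(red))[keep],
                start = GenomicRanges::start(red)[keep] - 1,
                end = as.numeric(GenomicRanges::end(red))[keep],
                nProbes = as.integer(np)[keep], genes = geneStr[keep],
                stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(class = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          nProbes = integer(0), genes = character(0),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$start, res$class), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Match focal events across tumor regions of one mouse
#'
#' Events of the same class whose spans share an overlap/union ratio of at
#' least 0.5 are considered the same event (transitively). Each matched event
#' receives an id and an evolutionary status: ubiquitous (all analyzed
#' regions), partially shared (more than one but not all), or private.
#'
#' @param events data.frame of per-region focal events (columns of
#'   [callFocalEvents()] plus `region`).
#' @param regions character vector of all analyzed region names (defaults to
#'   the regions present in `events`).
#' @param minRatio overlap/union ratio for identity.
#' @return `events` with added columns `eventId` and `status`.
#' @export
matchFocalEvents <- function(events, regions = unique(events$region),
                             minRatio = 0.5) {
    stopifnot("region" %in% names(events))
    n <- nrow(events)
    if (!n) {
        events$eventId <- integer(0)
        events$status <- character(0)
        return(events)
    }
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i) next
        if (events$class[i] != events$class[j]) next
        if (events$chrom[i] != events$chrom[j]) next
        ov <- min(events$end[i], events$end[j]) -
              max(events$start[i], events$start[j])
        if (ov <= 0) next
        un <- max(events$end[i], events$end[j]) -
              min(events$start[i], events$start[j])
        ## integer-safe test of overlap/union >= minRatio at minRatio = 1/2
        if (ov / un >= minRatio - 1e-12)
            parent[find(i)] <- find(j)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    events$eventId <- match(comp, unique(comp))
    nRegions <- length(regions)
    support <- vapply(split(events$region, events$eventId),
                      function(r) length(unique(r)), integer(1))
    status <- ifelse(support >= nRegions, "ubiquitous",
                     ifelse(support > 1L, "partially shared", "private"))
    events$status <- unname(status[as.character(events$eventId)])
    events
}

#' Call large-scale chromosomal gains and losses
#'
#' A chromosome is labeled gained (lost) when segments with CN_T above
#' (below) the normal copy number cumulatively span at least half of its
#' length.
#'
#' @param segments data.frame from [annotateCopyNumber()] covering each
#'   chromosome.
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to the spanned extent of the segments.
#' @param cnn normal copy number.
#' @param minFrac minimum altered fraction of the chromosome.
#' @return data.frame with columns `chrom`, `call` (`gain`/`loss`/`none`),
#'   `gainFrac`, `lossFrac`.
#' @export
callLargeScale <- function(segments, chromLengths = NULL, cnn = 2,
                           minFrac = 0.5) {
    chroms <- unique(segments$chrom)
    res <- lapply(chroms, function(chrom) {
        s <- segments[segments$chrom == chrom, , drop = FALSE]
        len <- if (!is.null(chromLengths)) chromLengths[[chrom]]
               else max(s$end) - min(s$start)
        w <- s$end - s$start
        gainFrac <- sum(w[s$cnt > cnn]) / len
        lossFrac <- sum(w[s$cnt < cnn]) / len
        call <- "none"
        if (gainFrac >= minFrac && gainFrac >= lossFrac) call <- "gain"
        else if (lossFrac >= minFrac) call <- "loss"
        data.frame(chrom = chrom, call = call, gainFrac = gainFrac,
                   lossFrac = lossFrac, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Fraction of genes hit by copy-number alteration
#'
#' A gene counts as altered when at least one overlapping segment has
#' CN_T different from the normal copy number.
#'
#' @param segments data.frame from [annotateCopyNumber()].
#' @param genes data.frame (`chrom`, `start`, `end`, `name`) or `GRanges`.
#' @param cnn normal copy number.
#' @return fraction of genes altered (numeric in [0, 1]).
#' @export
geneAlterationFraction <- function(segments, genes, cnn = 2) {
    if (is.data.frame(genes)) genes <- .toGRanges(genes)
    alt <- segments[segments$cnt != cnn, , drop = FALSE]
    if (!nrow(alt)) return(0)
    hits <- GenomicRanges::findOverlaps(genes, .toGRanges(alt))
    length(unique(S4Vectors::queryHits(hits))) / length(genes)
}
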