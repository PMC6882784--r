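## Standard-format I/O. Internal coordinates are 0-based half-open; SEG files
## are converted from/to 1-based inclusive on the way through.

#' Read a SEG file
#'
#' Tab-separated with header columns sample, chrom, start, end, num_probes,
#' seg_mean (1-based inclusive coordinates).
#'
#' @param path file path.
#' @return data.frame with `sample`, `chrom`, `start`, `end` (0-based
#'   half-open), `nProbes`, `segMean`.
#' @export
readSeg <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    cols <- c("sample", "chrom", "start", "end", "num_probes", "seg_mean")
    stopifnot(all(cols %in% names(df)))
    data.frame(sample = df$sample, chrom = df$chrom, start = df$start - 1,
               end = df$end, nProbes = df$num_probes, segMean = df$seg_mean,
               stringsAsFactors = FALSE)
}

#' Write segments as a SEG file
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `nProbes`, `segMean`.
#' @param path output file.
#' @param sample sample name for the first column.
#' @return the path, invisibly.
#' @export
writeSeg <- function(segments, path, sample = "sample") {
    out <- data.frame(sample = sample, chrom = segments$chrom,
                      start = segments$start + 1, end = segments$end,
                      num_probes = segments$nProbes,
                      seg_mean = round(segments$segMean, 6))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a probe log-ratio track
#'
#' TSV with columns `chrom`, `pos`, `log2ratio` (optionally `region`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readProbeTrack <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "log2ratio") %in% names(df)))
    df
}

#' Read gene coordinates from a BED file
#'
#' @param path BED file (chrom, start, end, name).
#' @return data.frame with `chrom`, `start`, `end`, `name` in 0-based
#'   half-open coordinates.
#' @export
readGenesBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               name = S4Vectors::mcols(gr)$name,
               stringsAsFactors = FALSE)
}

#' Write gene coordinates to a BED file
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `name` (0-based
#'   half-open).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGenesBed <- function(genes, path) {
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1,
                                                  genes$end),
                                 name = genes$name)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read a long-format mutation read-count table
#'
#' TSV with one row per mutation and region: `id`, `region`, `depth`, `var`,
#' `fwd`, `rev` plus any annotation columns (`chrom`, `pos`, `gene`, `cnt`,
#' `knockin`, ...).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readMutationTable <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("id", "region", "depth", "var", "fwd", "rev")
                  %in% names(df)))
    df
}

#' Write a mutation table with filter verdicts
#'
#' @param calls data.frame (long format).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMutationTable <- function(calls, path) {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-region mutation counts from a minimal multi-sample VCF
#'
#' Expects one VCF sample per tumor region with `AD` (ref,alt depths) and
#' per-allele strand counts in `ADF`/`ADR` when present; without strand
#' fields the variant reads are split evenly (flagged by `strand_imputed`).
#'
#' @param path VCF path (plain text or bgzipped).
#' @return long-format data.frame compatible with [readMutationTable()].
#' @export
readMutationVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    ad <- VariantAnnotation::geno(vcf)$AD
    if (is.null(ad))
        stop("VCF must carry an AD genotype field")
    samples <- colnames(ad)
    hasStrand <- all(c("ADF", "ADR") %in%
                     names(VariantAnnotation::geno(vcf)))
    rr <- SummarizedExperiment::rowRanges(vcf)
    ids <- names(rr) %||% sprintf("mut%03d", seq_along(rr))
    rows <- list()
    for (i in seq_along(rr)) for (s in samples) {
        counts <- ad[i, s][[1L]]
        ref <- counts[1L]; alt <- counts[2L]
        if (hasStrand) {
            fwd <- VariantAnnotation::geno(vcf)$ADF[i, s][[1L]][2L]
            rev <- VariantAnnotation::geno(vcf)$ADR[i, s][[1L]][2L]
        } else {
            fwd <- alt %/% 2L
            rev <- alt - fwd
        }
        rows[[length(rows) + 1L]] <- data.frame(
            id = ids[i],
            chrom = as.character(GenomicRanges::seqnames(rr))[i],
            pos = GenomicRanges::start(rr)[i] - 1, region = s,
            depth = ref + alt, var = alt, fwd = fwd, rev = rev,
            strand_imputed = !hasStrand, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Write the data layers of a simulated mouse to plain-text files
#'
#' Emits mutation TSV, per-region probe TSV, SNP TSV, qPCR TSVs, truth SEG
#' (per region) and a truth JSON (tree, purity, topology).
#'
#' @param mouse a [SimulatedMouse-class].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulatedMouse <- function(mouse, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        mutations = file.path(dir, "mutations.tsv"),
        probes = file.path(dir, "probes.tsv"),
        snps = file.path(dir, "snps.tsv"),
        ct_standards = file.path(dir, "ct_standards.tsv"),
        ct_sample = file.path(dir, "ct_sample.tsv"),
        truth = file.path(dir, "truth.json"))
    write.table(mouse@mutations, paths["mutations"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(mouse@probes, paths["probes"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(mouse@snps, paths["snps"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(mouse@ctStandards, paths["ct_standards"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(mouse@ctSample, paths["ct_sample"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (rg in unique(mouse@cnTruth$region)) {
        seg <- mouse@cnTruth[mouse@cnTruth$region == rg, , drop = FALSE]
        p <- mouse@purity[[rg]]
        segOut <- data.frame(chrom = seg$chrom, start = seg$start,
                             end = seg$end, nProbes = NA_integer_,
                             segMean = purityLog2Ratio(pmax(seg$cnt, 0.01),
                                                       p))
        writeSeg(segOut, file.path(dir, sprintf("truth_%s.seg", rg)),
                 sample = paste0(mouse@mouseId, "_", rg))
    }
    truth <- list(mouseId = mouse@mouseId, genotype = mouse@genotype,
                  purity = as.list(mouse@purity),
                  topology = mouse@tree@topology,
                  parents = as.list(mouse@tree@parents),
                  prevalence = apply(mouse@tree@prevalence, 1, as.list))
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(paths)
}
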