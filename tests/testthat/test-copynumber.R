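test_that("purity correction inverts the forward mixing model exactly", {
    for (p in seq(0.2, 1, by = 0.1)) {
        for (cnt in 0:10) {
            lr <- purityLog2Ratio(cnt, p)
            expect_identical(purityCorrect(lr, p)$cnt, as.integer(cnt))
        }
    }
    expect_equal(purityCorrect(0, 0.37)$cnt, 2L)        # identity at log2R=0
    expect_equal(purityCorrect(1, 1)$cnt, 4L)
    expect_equal(purityCorrect(log2(1.25), 0.5)$cnt, 3L)
    expect_error(purityCorrect(0, 0), "positive")
})

test_that("segment classes follow the integer copy number", {
    seg <- makeSegments("chr1", c(0, 1, 2, 3, 4) * 1e6,
                        c(1, 2, 3, 4, 5) * 1e6, cnt = c(0L, 1L, 2L, 4L, 6L))
    seg$segMean <- purityLog2Ratio(pmax(seg$cnt, 0.001), 1)
    ann <- annotateCopyNumber(seg[, setdiff(names(seg), "cnt")], p = 1)
    expect_equal(ann$class, c("HD", "loss", "neutral", "gain", "Amp"))
})

test_that("focal calling applies size, probe, autosome and gene rules", {
    genes <- makeGenes(rep(c("chr2", "chrX"), c(4, 1)),
                       c(0.5e6, 2.5e6, 7e6, 20e6, 1e6),
                       c(0.6e6, 2.6e6, 7.1e6, 20.1e6, 1.1e6))
    seg <- makeSegments(
        chrom = c("chr2", "chr2", "chr2", "chr2", "chrX"),
        start = c(0e6, 2e6, 6e6, 19e6, 0e6),
        end   = c(1e6, 5e6, 7.2e6, 26e6, 2e6),
        cnt   = c(0L, 0L, 6L, 0L, 0L),
        nProbes = c(7L, 20L, 8L, 60L, 9L))
    ev <- callFocalEvents(seg, genes)
    ## chr2 0-1M (HD, 3 Mb away from the next HD -> separate), chr2 2-5M HD,
    ## chr2 Amp; 19-26M is 7 Mb (too large); chrX excluded
    expect_equal(nrow(ev), 3)
    expect_setequal(ev$class, c("HD", "HD", "Amp"))
    expect_false(any(ev$chrom == "chrX"))
    ## a CN_T = 4 segment is not focal (gain below three extra copies)
    seg4 <- makeSegments("chr2", 1e6, 2e6, cnt = 4L)
    expect_equal(nrow(callFocalEvents(seg4, genes)), 0)
    ## probe support below 5 is dropped
    segP <- makeSegments("chr2", 2e6, 3e6, cnt = 0L, nProbes = 4L)
    expect_equal(nrow(callFocalEvents(segP, genes)), 0)
    ## no gene overlap -> dropped
    segG <- makeSegments("chr2", 30e6, 31e6, cnt = 0L)
    expect_equal(nrow(callFocalEvents(segG, genes)), 0)
})

test_that("the 100 kb merge joins events below the gap and not at it", {
    genes <- makeGenes(rep("chr3", 2), c(1.0e6, 1.7e6), c(1.1e6, 1.75e6))
    near <- makeSegments(rep("chr3", 2), c(1e6, 1.58e6), c(1.5e6, 2e6),
                         cnt = 0L)   # 80 kb gap
    evNear <- callFocalEvents(near, genes)
    expect_equal(nrow(evNear), 1)
    expect_equal(evNear$nProbes, 20L)
    far <- makeSegments(rep("chr3", 2), c(1e6, 1.62e6), c(1.5e6, 2e6),
                        cnt = 0L)    # 120 kb gap
    expect_equal(nrow(callFocalEvents(far, genes)), 2)
})

test_that("cross-region matching honours the 50% overlap/union boundary", {
    ev <- data.frame(class = "HD", chrom = "chr1",
                     start = c(0, 0.4e6), end = c(1e6, 1.2e6),
                     nProbes = 10L, genes = "g",
                     region = c("T1", "T2"), stringsAsFactors = FALSE)
    m <- matchFocalEvents(ev, regions = c("T1", "T2", "T3"))
    ## overlap 0.6 / union 1.2 = exactly 0.5 -> same event
    expect_equal(length(unique(m$eventId)), 1)
    expect_true(all(m$status == "partially shared"))
    ## ratio just below 0.5 -> distinct
    ev2 <- transform(ev, start = c(0, 0.42e6), end = c(1e6, 1.25e6))
    m2 <- matchFocalEvents(ev2, regions = c("T1", "T2"))
    expect_equal(length(unique(m2$eventId)), 2)
    expect_true(all(m2$status == "private"))
    ## class mismatch -> distinct even with full overlap
    ev3 <- transform(ev, class = c("HD", "Amp"), start = 0, end = 1e6)
    m3 <- matchFocalEvents(ev3, regions = c("T1", "T2"))
    expect_equal(length(unique(m3$eventId)), 2)
})

test_that("large-scale calls need half the chromosome", {
    len <- c(chr1 = 1e7)
    seg60 <- makeSegments("chr1", c(0, 6e6), c(6e6, 1e7), cnt = c(3L, 2L))
    expect_equal(callLargeScale(seg60, len)$call, "gain")
    seg49 <- makeSegments("chr1", c(0, 4.9e6), c(4.9e6, 1e7),
                          cnt = c(1L, 2L))
    expect_equal(callLargeScale(seg49, len)$call, "none")
    segNeutral <- makeSegments("chr1", 0, 1e7, cnt = 2L)
    expect_equal(callLargeScale(segNeutral, len)$call, "none")
})

test_that("gene alteration fraction matches a per-gene oracle", {
    ## 20 genes at 1 Mb intervals; segment 0-10.5 Mb at CN 3
    genes <- makeGenes(rep("chr1", 20), (0:19) * 1e6 + 1e5,
                       (0:19) * 1e6 + 2e5)
    segNeutral <- makeSegments("chr1", 0, 2e7, cnt = 2L)
    expect_equal(geneAlterationFraction(segNeutral, genes), 0)
    seg <- makeSegments("chr1", c(0, 1.05e7), c(1.05e7, 2e7),
                        cnt = c(3L, 2L))
    ## oracle: a gene is altered iff it intersects [0, 10.5 Mb)
    oracle <- mean(genes$start < 1.05e7)
    expect_equal(geneAlterationFraction(seg, genes), oracle)
    expect_equal(oracle, 0.55)
})

test_that("focal calling is invariant to segment order", {
    set.seed(9)
    genes <- makeGenes(rep("chr1", 10), (0:9) * 3e6, (0:9) * 3e6 + 1e5)
    seg <- makeSegments(rep("chr1", 6),
                        c(0, 3e6, 9e6, 12e6, 20e6, 24e6),
                        c(1e6, 4e6, 10e6, 13e6, 21e6, 27e6),
                        cnt = c(0L, 6L, 0L, 2L, 5L, 0L))
    ev1 <- callFocalEvents(seg, genes)
    ev2 <- callFocalEvents(seg[sample(nrow(seg)), ], genes)
    rownames(ev1) <- rownames(ev2) <- NULL
    expect_identical(ev1, ev2)
})

test_that("SEG round trip preserves coordinates and means", {
    seg <- makeSegments("chr1", c(0, 5e6), c(5e6, 1e7), cnt = c(2L, 3L),
                        segMean = c(0, 0.58))
    path <- tempfile(fileext = ".seg")
    writeSeg(seg, path, sample = "s1")
    back <- readSeg(path)
    expect_equal(back$start, seg$start)
    expect_equal(back$end, seg$end)
    expect_equal(back$segMean, seg$segMean)
})
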