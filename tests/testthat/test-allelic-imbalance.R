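test_that("expected loss MAF matches the analytic form and is monotone", {
    expect_equal(expectedLossMaf(0), 0.5)
    expect_equal(expectedLossMaf(1), 0)
    expect_equal(expectedLossMaf(0.5), 1/3)
    grid <- seq(0, 1, by = 0.01)
    expect_true(all(diff(expectedLossMaf(grid)) < 0))
})

test_that("threshold calibration separates classes at high purity", {
    cal <- calibrateMafThreshold(0.9, 100, seed = 1)
    expect_false(lackingPower(cal))
    expect_equal(cal@sensitivity, 1)
    expect_equal(cal@specificity, 1)
    ## threshold sits strictly between the two class means
    expect_gt(mafThreshold(cal), expectedLossMaf(0.9))
    expect_lt(mafThreshold(cal), 0.5)
})

test_that("calibration flags lacking power at very low purity", {
    cal <- calibrateMafThreshold(0.05, 30, seed = 1)
    expect_true(lackingPower(cal))
    expect_true(is.na(mafThreshold(cal)))
})

test_that("calibration is deterministic and validates subset size", {
    c1 <- calibrateMafThreshold(0.7, 80, seed = 5)
    c2 <- calibrateMafThreshold(0.7, 80, seed = 5)
    expect_identical(mafThreshold(c1), mafThreshold(c2))
    expect_identical(c1@f1, c2@f1)
    expect_error(calibrateMafThreshold(0.7, 80, nSnps = 10000,
                                       subsetSize = 7), "divide")
})

test_that("gene test flags imbalance only under the threshold and FDR", {
    genes <- makeGenes(c("chr1", "chr1"), c(4.9e6, 9.9e6), c(5.1e6, 10.1e6),
                       name = c("lost", "balanced"))
    set.seed(2)
    mkSnps <- function(center, tProb) {
        pos <- center + seq(-5e4, 5e4, length.out = 12)
        tAlt <- rbinom(12, 80, tProb)
        nAlt <- rbinom(12, 80, 0.5)
        data.frame(chrom = "chr1", pos = pos, t_ref = 80 - tAlt,
                   t_alt = tAlt, n_ref = 80 - nAlt, n_alt = nAlt)
    }
    snps <- rbind(mkSnps(5e6, 0.05), mkSnps(10e6, 0.5))
    res <- testAllelicImbalance(genes, snps, threshold = 0.30)
    expect_true(res$ai[res$gene == "lost"])
    expect_false(res$ai[res$gene == "balanced"])
    ## paired one-tailed t oracle for the lost gene
    sel <- snps[order(abs(snps$pos - 5e6))[1:10], ]
    tm <- pmin(sel$t_ref, sel$t_alt) / (sel$t_ref + sel$t_alt)
    nm <- pmin(sel$n_ref, sel$n_alt) / (sel$n_ref + sel$n_alt)
    d <- tm - nm
    tStat <- mean(d) / (sd(d) / sqrt(10))
    pOracle <- pt(tStat, df = 9)
    expect_equal(res$p[res$gene == "lost"], pOracle, tolerance = 1e-12)
})

test_that("null genes are not flagged when tumor equals normal", {
    genes <- makeGenes("chr1", 4.9e6, 5.1e6, name = "g")
    counts <- rbinom(12, 60, 0.5)
    snps <- data.frame(chrom = "chr1",
                       pos = 5e6 + seq(-5e4, 5e4, length.out = 12),
                       t_ref = 60 - counts, t_alt = counts,
                       n_ref = 60 - counts, n_alt = counts)
    res <- testAllelicImbalance(genes, snps, threshold = 0.3)
    expect_equal(res$p, 1)
    expect_false(res$ai)
})

test_that("positions below the informative depth never enter the test", {
    genes <- makeGenes("chr1", 0.9e6, 1.1e6, name = "g")
    ## the nearest SNP has DP 19 and a wildly imbalanced MAF; it must be
    ## ignored in favor of deeper positions
    snps <- data.frame(chrom = "chr1",
                       pos = c(1e6, 1e6 + 1e3 * (1:11)),
                       t_ref = c(19, rep(15, 11)),
                       t_alt = c(0, rep(15, 11)),
                       n_ref = c(10, rep(15, 11)),
                       n_alt = c(9, rep(15, 11)))
    res <- testAllelicImbalance(genes, snps, threshold = 0.3)
    expect_equal(res$n_snps, 10)
    expect_equal(res$mean_t_maf, 0.5)
})

test_that("mouse-level union skips regions lacking power", {
    expect_setequal(aiUnion(list(T1 = c("A", "B"), T3 = c("B", "C"))),
                    c("A", "B", "C"))
    expect_setequal(aiUnion(list(T1 = NA, T3 = c("B", "C"))), c("B", "C"))
    expect_length(aiUnion(list(T1 = character(0), T3 = character(0))), 0)
    expect_error(aiUnion(list(T1 = NA, T3 = NA)), "powered")
})

test_that("enrichment p values match the binomial tail", {
    aiMat <- matrix(FALSE, 3, 12,
                    dimnames = list(c("g1", "g2", "g3"), NULL))
    aiMat["g2", 1:6] <- TRUE   # 6 of 12 mice
    ## per-mouse fractions: 6 mice at 1/3, rest 0 -> background 1/6
    res <- aiEnrichment(aiMat)
    bg <- mean(colMeans(aiMat))
    expect_equal(res$p[res$gene == "g1"], 1)
    expect_equal(res$p[res$gene == "g2"],
                 sum(dbinom(6:12, 12, bg)), tolerance = 1e-12)
    ## background 0.5 by construction: two complementary genes
    aiHalf <- rbind(gA = c(rep(TRUE, 6), rep(FALSE, 6)),
                    gB = c(rep(FALSE, 6), rep(TRUE, 6)))
    resHalf <- aiEnrichment(aiHalf)
    expect_equal(resHalf$p, rep(0.61279296875, 2), tolerance = 1e-10)
})
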