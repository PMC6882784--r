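test_that("expected VAF follows the purity/copy-number mixing model", {
    expect_equal(expectedVaf(1, 1, 1, 2, 2), 0.5)
    expect_equal(expectedVaf(0.8, 1, 0.5, 2, 2), 0.2)
    expect_equal(expectedVaf(0.5, 2, 1, 4, 2), 1/3)
    expect_error(expectedVaf(1, 1, 1, 0, 2), "deleted")
})

test_that("grid argmax matches the closed-form MLE within one grid step", {
    set.seed(11)
    for (i in 1:200) {
        p <- runif(1, 0.2, 1)
        cnt <- sample(1:6, 1)
        m <- sample(seq_len(cnt), 1)
        rTot <- sample(c(50, 100, 300), 1)
        rA <- sample(0:rTot, 1)
        est <- tryCatch(prevalencePosterior(rA, rTot, p, cnt, m = m),
                        error = function(e) NULL)
        if (is.null(est)) next
        vhat <- rA / rTot
        mle <- min(1, vhat * (p * cnt + (1 - p) * 2) / (p * m))
        expect_lte(abs(pointEstimate(est) - mle), 0.01 + 1e-9)
    }
})

test_that("posterior normalizes, covers its argmax, and narrows with depth", {
    est <- prevalencePosterior(50, 100, 1, 2)
    expect_equal(sum(est@posterior), 1, tolerance = 1e-9)
    expect_equal(pointEstimate(est), 1)
    expect_true(est@lower <= pointEstimate(est) &
                pointEstimate(est) <= est@upper)
    zero <- prevalencePosterior(0, 100, 0.8, 2)
    expect_equal(pointEstimate(zero), 0)
    ## interval width shrinks monotonically with depth at fixed vhat
    widths <- vapply(c(40, 100, 400, 1600), function(n) {
        e <- prevalencePosterior(0.25 * n, n, 1, 2)
        e@upper - e@lower
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
})

test_that("multiplicity deduction matches the enumeration oracle", {
    ## the worked examples
    r1 <- resolveMultiplicity(90, 100, 1, 4)
    expect_equal(r1$m, 4L)
    r2 <- resolveMultiplicity(10, 100, 1, 3)
    expect_true(is.na(r2$m))
    expect_true(r2$estimate@missing)
    expect_equal(resolveMultiplicity(30, 100, 0.9, 2)$m, 1L)
    ## zero variant reads: prevalence 0 regardless of multiplicity
    r0 <- resolveMultiplicity(0, 100, 0.7, 5)
    expect_equal(pointEstimate(r0$estimate), 0)
    ## randomized agreement with an independent oracle
    set.seed(12)
    sawForced <- sawMissing <- FALSE
    for (i in 1:300) {
        p <- runif(1, 0.2, 1)
        cnt <- sample(1:6, 1)
        rTot <- 200
        rA <- sample(0:rTot, 1)
        got <- resolveMultiplicity(rA, rTot, p, cnt)
        if (rA == 0 || cnt <= 2) {
            expect_equal(got$m, 1L)
            next
        }
        vhat <- rA / rTot
        feasible <- Filter(function(m)
            vhat * (p * cnt + (1 - p) * 2) / (p * m) <= 1.05,
            seq_len(cnt))
        if (length(feasible) == 1L) {
            expect_equal(got$m, as.integer(feasible[[1]]))
            sawForced <- TRUE
        } else {
            expect_true(is.na(got$m))
            expect_true(got$estimate@missing)
            sawMissing <- TRUE
        }
    }
    expect_true(sawForced)
    expect_true(sawMissing)
})

test_that("low-VAF regions and regions without copy number are excluded", {
    calls <- rbind(
        makeCall("a", c("T1", "T2", "T3"), 1000, c(15, 100, 300)),
        makeCall("b", c("T1", "T2", "T3"), 1000, c(18, 250, 50)))
    ## T1 max VAF 0.018 <= 0.02 -> dropped
    expect_setequal(excludeLowVafRegions(calls), c("T2", "T3"))
    ## T3 has no copy-number profile -> dropped too
    expect_setequal(excludeLowVafRegions(calls,
                                         regionsWithCn = c("T1", "T2")),
                    "T2")
    ## a single mutation above the cutoff keeps the region
    calls2 <- makeCall("c", "T1", 100, 5)
    expect_equal(excludeLowVafRegions(calls2), "T1")
})

test_that("whole-mouse prevalence estimation recovers truth at depth", {
    tree <- simulateTree(3, "linear", 3, seed = 21)
    cn <- simulateCnProfile(defaultGenome(), 3,
                            events = data.frame(chrom = character(0),
                                                start = numeric(0),
                                                end = numeric(0),
                                                cnt = integer(0)))
    purity <- c(T1 = 0.8, T2 = 0.8, T3 = 0.8)
    muts <- simulateMutationReads(tree, nMutPerCluster = 5,
                                  coverageMean = 2000, purity = purity,
                                  cnProfile = cn, seed = 22)
    muts <- muts[!muts$knockin, ]
    res <- estimatePrevalence(muts, purity)
    P <- prevalenceMatrix(tree)
    for (i in seq_len(nrow(res$detail))) {
        d <- res$detail[i, ]
        truthC <- P[muts$cluster[muts$id == d$id][1], d$region]
        expect_lt(abs(d$c_hat - truthC), 0.08)
    }
})
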