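test_that("discovery filter enforces all four conditions", {
    calls <- rbind(
        makeCall("a", "T1", 100, 5, 3, 2),   # pass
        makeCall("b", "T1", 9, 5, 3, 2),     # depth below 10
        makeCall("c", "T1", 100, 2, 1, 1),   # fewer than 3 variant reads
        makeCall("d", "T1", 1000, 5, 3, 2),  # VAF 0.5% below 1%
        makeCall("e", "T1", 100, 3, 3, 0))   # no reverse-strand read
    expect_identical(unname(discoveryFilter(calls)),
                     c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("validation allows criteria met in different regions", {
    ## VAF >= 1% only in T1, var >= 5 only in T2, strand pairs split T2/T3
    calls <- rbind(
        makeCall("x", "T1", 100, 4, 2, 2),
        makeCall("x", "T2", 900, 6, 4, 2),
        makeCall("x", "T3", 800, 4, 1, 3))
    expect_true(validationFilter(calls)[["x"]])
    ## no region reaches 3 reverse reads
    calls2 <- rbind(
        makeCall("y", "T1", 100, 6, 4, 2),
        makeCall("y", "T2", 100, 6, 5, 1),
        makeCall("y", "T3", 100, 6, 6, 0))
    expect_false(validationFilter(calls2)[["y"]])
    ## VAF 0.5% everywhere fails
    calls3 <- rbind(
        makeCall("z", "T1", 1000, 5, 3, 2),
        makeCall("z", "T2", 1000, 5, 3, 2))
    expect_false(validationFilter(calls3)[["z"]])
})

test_that("filters are monotone in the read counts", {
    set.seed(8)
    for (i in 1:200) {
        depth <- sample(5:400, 1)
        var <- sample(0:min(depth, 40), 1)
        fwd <- sample(0:var, 1)
        base <- makeCall("m", "T1", depth, var, fwd, var - fwd)
        up <- base
        up$depth <- up$depth + sample(0:50, 1)
        extraF <- sample(0:10, 1); extraR <- sample(0:10, 1)
        up$var <- up$var + extraF + extraR
        up$fwd <- up$fwd + extraF
        up$rev <- up$rev + extraR
        up$depth <- pmax(up$depth, up$var)
        if (discoveryFilter(base) && up$var / up$depth >= 0.01)
            expect_true(discoveryFilter(up))
    }
})

test_that("heterogeneity categories partition the validated set", {
    calls <- rbind(
        makeCall("ubi", c("T1", "T2", "T3"), 100, c(10, 12, 9)),
        makeCall("shared", c("T1", "T2", "T3"), 100, c(10, 12, 0)),
        makeCall("priv", c("T1", "T2", "T3"), 100, c(0, 0, 30)),
        makeCall("ki", c("T1", "T2", "T3"), 100, c(50, 50, 50)))
    calls$knockin <- calls$id == "ki"
    het <- categorizeHeterogeneity(calls)
    expect_false("ki" %in% het$id)     # transgenes excluded
    expect_equal(het$category[het$id == "ubi"], "ubiquitous")
    expect_equal(het$category[het$id == "shared"], "partially shared")
    expect_equal(het$category[het$id == "priv"], "private")
    expect_equal(nrow(het), 3)
    ## shrinking the analyzed regions reclassifies
    het2 <- categorizeHeterogeneity(calls, analyzedRegions = c("T1", "T2"))
    expect_equal(het2$category[het2$id == "shared"], "ubiquitous")
})

test_that("random fixtures agree with a rule-by-rule oracle", {
    set.seed(10)
    n <- 300
    calls <- data.frame(id = sprintf("m%03d", seq_len(n)), region = "T1",
                        depth = sample(0:200, n, replace = TRUE))
    calls$var <- pmin(calls$depth, rpois(n, 4))
    calls$fwd <- rbinom(n, calls$var, 0.5)
    calls$rev <- calls$var - calls$fwd
    got <- discoveryFilter(calls)
    oracle <- with(calls, depth >= 10 & var >= 3 &
                   ifelse(depth > 0, var / depth, 0) >= 0.01 &
                   fwd >= 1 & rev >= 1)
    expect_identical(unname(got), oracle)
})
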