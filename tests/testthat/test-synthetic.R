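test_that("smallest linear tree has one child below the root everywhere", {
    tree <- simulateTree(2, "linear", 3, seed = 1)
    parents <- treeParents(tree)
    expect_identical(unname(parents[["C1"]]), "C0")
    expect_true(all(prevalenceMatrix(tree)["C1", ] < 1))
})

test_that("two-primary founders occupy disjoint high-prevalence regions", {
    tree <- simulateTree(3, "two_primary", 3, seed = 7)
    P <- prevalenceMatrix(tree)
    highA <- which(P["C1", ] >= 0.5)
    highB <- which(P["C2", ] >= 0.5)
    expect_gte(length(highA), 1)
    expect_gte(length(highB), 1)
    expect_length(intersect(highA, highB), 0)
    ## each founder is absent from the other's flank region
    expect_equal(unname(P["C1", 3]), 0)
    expect_equal(unname(P["C2", 1]), 0)
})

test_that("sum rule holds exhaustively for generated trees", {
    for (seed in 1:25) {
        topo <- c("linear", "branched", "two_primary")[seed %% 3 + 1]
        k <- 2 + seed %% 6
        if (topo != "linear") k <- max(k, 3)
        tree <- simulateTree(k, topo, 3, seed = seed)
        P <- prevalenceMatrix(tree)
        parents <- treeParents(tree)
        for (id in rownames(P)) {
            kids <- names(parents)[!is.na(parents) & parents == id]
            if (length(kids))
                expect_true(all(colSums(P[kids, , drop = FALSE]) <=
                                P[id, ] + 1e-9),
                            info = paste("seed", seed, "node", id))
        }
        ## pairwise margin separation
        d <- as.matrix(dist(P, method = "maximum"))
        expect_gte(min(d[upper.tri(d)]), 0.15 - 1e-9)
    }
})

test_that("tree generation rejects infeasible requests", {
    expect_error(simulateTree(2, "two_primary", 3, seed = 1), "at least 3")
    expect_error(simulateTree(2, "branched", 3, seed = 1), "at least 3")
})

test_that("mutation read counts follow the expected-VAF binomial model", {
    tree <- simulateTree(2, "linear", 2, seed = 3)
    cn <- simulateCnProfile(defaultGenome(), 2,
                            events = data.frame(chrom = character(0),
                                                start = numeric(0),
                                                end = numeric(0),
                                                cnt = integer(0)))
    ## clonal mutations at p = 1 in diploid loci: VAF concentrates at 0.5
    muts <- simulateMutationReads(tree, nMutPerCluster = 40,
                                  coverageMean = 10000,
                                  purity = c(T1 = 1, T2 = 1),
                                  cnProfile = cn, seed = 5)
    clonal <- muts[muts$cluster == "C0" & !muts$knockin, ]
    se <- sqrt(0.25 / clonal$depth)
    expect_true(all(abs(clonal$vaf - 0.5) < 3.5 * se))
    ## counts are consistent
    expect_true(all(muts$var <= muts$depth))
    expect_true(all(muts$fwd + muts$rev == muts$var))
})

test_that("a zero-prevalence cluster yields zero variant reads", {
    tree <- simulateTree(3, "two_primary", 3, seed = 7)
    cn <- simulateCnProfile(defaultGenome(), 3,
                            events = data.frame(chrom = character(0),
                                                start = numeric(0),
                                                end = numeric(0),
                                                cnt = integer(0)))
    muts <- simulateMutationReads(tree, nMutPerCluster = 5,
                                  coverageMean = 300,
                                  purity = c(T1 = 0.8, T2 = 0.8, T3 = 0.8),
                                  cnProfile = cn, seed = 9)
    c1t3 <- muts[muts$cluster == "C1" & muts$region == "T3", ]
    expect_true(all(c1t3$var == 0))   # C1 prevalence is 0 in T3
})

test_that("simulators are deterministic under a fixed seed", {
    m1 <- simulateMouse(seed = 77)
    m2 <- simulateMouse(seed = 77)
    expect_identical(m1@mutations, m2@mutations)
    expect_identical(m1@probes, m2@probes)
    expect_identical(m1@snps, m2@snps)
    expect_identical(prevalenceMatrix(m1@tree), prevalenceMatrix(m2@tree))
})

test_that("aCGH probes follow the purity mixing model", {
    genome <- defaultGenome(1, 1e6)
    cn <- data.frame(region = "T1", chrom = "chr1", start = 0, end = 1e6,
                     cnt = 4L)
    ## noiseless: all probes exactly at log2(2) = 1 for purity 1, CNT 4
    probes <- simulateAcgh(cn, purity = c(T1 = 1), probeSpacing = 1e4,
                           noiseSd = 0, genome = genome, seed = 1)
    expect_true(all(probes$log2ratio == 1))
    ## purity 0.5, CNT 0: log2((0 + 0.5*2)/2) = -1
    cn0 <- transform(cn, cnt = 0L)
    probes0 <- simulateAcgh(cn0, purity = c(T1 = 0.5), probeSpacing = 1e4,
                            noiseSd = 0, genome = genome, seed = 1)
    expect_true(all(probes0$log2ratio == -1))
    ## Gaussian noise: probe mean within 3 sd / sqrt(n) of the forward value
    probesN <- simulateAcgh(cn, purity = c(T1 = 1), probeSpacing = 1e3,
                            noiseSd = 0.2, genome = genome, seed = 2)
    n <- nrow(probesN)
    expect_lt(abs(mean(probesN$log2ratio) - 1), 3 * 0.2 / sqrt(n))
})

test_that("SNP counts reproduce the loss-region MAF expectation", {
    genome <- defaultGenome(1, 1e7)
    loss <- data.frame(region = "T1", chrom = "chr1", start = 0, end = 5e6)
    snps <- simulateSnpCounts(loss, purity = c(T1 = 0.5),
                              coverage = 10000, nSnps = 400,
                              genome = genome, regions = "T1", seed = 4)
    snps$dp <- snps$t_ref + snps$t_alt
    snps$maf <- pmin(snps$t_ref, snps$t_alt) / snps$dp
    inLoss <- snps$pos < 5e6
    ## Within the loss the MAF concentrates at (1-p)/(2-p) = 1/3
    se <- sqrt((1/3) * (2/3) / snps$dp[inLoss])
    expect_true(mean(abs(snps$maf[inLoss] - 1/3) < 3 * se) > 0.98)
    ## outside the loss the MAF stays near 0.5 (minor-allele folding biases
    ## slightly downward at finite depth)
    expect_lt(abs(mean(snps$maf[!inLoss]) - 0.5), 0.01)
    ## pure tumor: minor allele vanishes entirely in loss regions
    pure <- simulateSnpCounts(loss, purity = c(T1 = 1), coverage = 100,
                              nSnps = 200, genome = genome,
                              regions = "T1", seed = 5)
    pureLoss <- pure[pure$pos < 5e6, ]
    expect_true(all(pmin(pureLoss$t_ref, pureLoss$t_alt) == 0))
})
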