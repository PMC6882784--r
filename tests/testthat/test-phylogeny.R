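## independent brute-force tree scorer used as the oracle: enumerates all
## parent vectors in R and recounts violations from first principles
bruteForceTrees <- function(prev, mayParent, sumTol = 0.10) {
    n <- nrow(prev)
    nodes <- rownames(prev)
    choicesPer <- lapply(2:n, function(i) setdiff(seq_len(n), i))
    grid <- do.call(expand.grid, choicesPer)
    best <- NULL
    bestCost <- Inf
    for (g in seq_len(nrow(grid))) {
        par <- c(NA, as.integer(grid[g, ]))
        ## acyclic?
        ok <- TRUE
        for (s in 2:n) {
            cur <- s; seen <- integer(0)
            while (!is.na(par[cur])) {
                if (cur %in% seen) { ok <- FALSE; break }
                seen <- c(seen, cur)
                cur <- par[cur]
            }
            if (!ok) break
        }
        if (!ok) next
        cp <- sum(vapply(2:n, function(c) !mayParent[par[c], c],
                         logical(1)))
        cs <- 0
        for (u in seq_len(n)) {
            kids <- which(!is.na(par) & par == u)
            if (length(kids))
                cs <- cs + sum(colSums(prev[kids, , drop = FALSE]) >
                               prev[u, ] + sumTol)
        }
        cost <- cp + cs
        if (cost < bestCost) { bestCost <- cost; best <- list() }
        if (cost == bestCost)
            best[[length(best) + 1]] <- setNames(
                ifelse(is.na(par), NA_character_, nodes[par]), nodes)
    }
    list(cost = bestCost, trees = best)
}

test_that("precedence test encodes dominance, crossing and ties", {
    expect_true(precedenceTest(c(1, 1, 1), c(0.4, 0.3, 0.2)))
    expect_false(precedenceTest(c(0.4, 0.3, 0.2), c(1, 1, 1)))
    expect_false(precedenceTest(c(0.5, 0.1), c(0.1, 0.5)))
    expect_false(precedenceTest(c(0.1, 0.5), c(0.5, 0.1)))
    expect_true(precedenceTest(c(0.5, 0.5), c(0.5, 0.5)))
    expect_true(precedenceTest(c(0.5, 0.5), c(0.5, 0.5) + 0.01))
})

test_that("nested prevalences admit the linear chain at zero cost", {
    centers <- rbind(A = c(1, 1, 1), B = c(0.6, 0.5, 0.7),
                     C = c(0.2, 0.1, 0.3))
    trees <- enumerateTrees(centers)
    expect_equal(treeCost(trees[[1]]), 0L)
    chains <- Filter(function(t)
        identical(unname(treeParents(t)[c("A", "B", "C")]),
                  c("root", "A", "B")), trees)
    expect_length(chains, 1)
    ## agreement with the independent brute-force scorer
    prev <- rbind(root = c(1, 1, 1), centers)
    bf <- bruteForceTrees(prev, precedenceMatrix(centers))
    expect_equal(bf$cost, 0)
    expect_equal(length(trees), length(bf$trees))
})

test_that("sibling sums above the parent force the chain uniquely", {
    centers <- rbind(A = c(1, 1, 1), B = c(0.7, 0.7, 0.7),
                     C = c(0.45, 0.45, 0.45))
    trees <- enumerateTrees(centers)
    ## B + C = 1.15 > 1 + 0.1 under A or root, so only the chain is free
    expect_length(trees, 1)
    expect_equal(treeCost(trees[[1]]), 0L)
    expect_identical(unname(treeParents(trees[[1]])[c("A", "B", "C")]),
                     c("root", "A", "B"))
    expect_equal(topologyClass(trees[[1]]), "linear")
})

test_that("a sum-rule violation is charged per offending region", {
    ## children at 0.6 and 0.5 under a parent at 1.0: 1.1 > 1.0 in region 1
    star <- new("SubcloneTree",
                parents = c(root = NA_character_, A = "root", B = "root"),
                prevalence = rbind(root = c(1, 1), A = c(0.6, 0.2),
                                   B = c(0.5, 0.2)),
                cost = 1L, costPrecedence = 0L, costSumRule = 1L,
                topology = "branched", synchronousPrimary = FALSE,
                rootId = "root")
    rc <- treeCostRecount(star, sumTol = 0)
    expect_equal(rc$costSumRule, 1L)
    expect_equal(rc$costPrecedence, 0L)
    ## with the default 0.10 tolerance the same placement is not charged
    expect_equal(treeCostRecount(star, sumTol = 0.10)$costSumRule, 0L)
})

test_that("single cluster yields root with one child at zero cost", {
    centers <- matrix(c(0.8, 0.9), 1, dimnames = list("A", NULL))
    trees <- enumerateTrees(centers)
    expect_length(trees, 1)
    expect_equal(unname(treeParents(trees[[1]])[["A"]]), "root")
    expect_equal(treeCost(trees[[1]]), 0L)
    expect_equal(topologyClass(trees[[1]]), "linear")
})

test_that("enumeration is invariant to cluster relabeling", {
    centers <- rbind(A = c(1, 1), B = c(0.5, 0.6), C = c(0.3, 0.1))
    t1 <- enumerateTrees(centers)
    relabeled <- centers[c(2, 3, 1), ]
    rownames(relabeled) <- c("B", "C", "A")
    t2 <- enumerateTrees(relabeled)
    canon <- function(ts) sort(vapply(ts, function(t)
        paste(sort(paste(treeParents(t), names(treeParents(t)))),
              collapse = "|"), character(1)))
    expect_identical(canon(t1), canon(t2))
})

test_that("cost recount matches the search for random inputs", {
    set.seed(41)
    for (rep in 1:10) {
        k <- sample(2:5, 1)
        centers <- matrix(runif(k * 3), k,
                          dimnames = list(LETTERS[1:k], NULL))
        trees <- enumerateTrees(centers)
        for (t in trees) {
            rc <- treeCostRecount(t)
            expect_equal(rc$cost, treeCost(t))
            expect_equal(rc$costPrecedence, t@costPrecedence)
            expect_equal(rc$costSumRule, t@costSumRule)
        }
        ## brute-force minimal cost agrees
        prev <- rbind(root = rep(1, 3), centers)
        bf <- bruteForceTrees(prev, precedenceMatrix(centers))
        expect_equal(bf$cost, treeCost(trees[[1]]))
        expect_equal(length(bf$trees), length(trees))
    }
})

test_that("topology classification distinguishes the study's patterns", {
    ## chain: linear
    chain <- enumerateTrees(rbind(A = c(1, 1, 1), B = c(0.7, 0.7, 0.7),
                                  C = c(0.45, 0.45, 0.45)))[[1]]
    expect_equal(topologyClass(chain), "linear")
    expect_false(chain@synchronousPrimary)
    ## two founders with disjoint support: branched + synchronous primaries
    centers <- rbind(A = c(0.8, 0.3, 0), B = c(0, 0.3, 0.8))
    trees <- enumerateTrees(centers)
    expect_true(all(vapply(trees, topologyClass, "") == "branched"))
    expect_true(all(vapply(trees, function(t) t@synchronousPrimary,
                           logical(1))))
    ## ordinary branching below a high clonal cluster: not synchronous
    centers2 <- rbind(A = c(1, 1, 1), B = c(0.5, 0.1, 0.4),
                      C = c(0.1, 0.6, 0.2))
    trees2 <- enumerateTrees(centers2)
    expect_true(all(vapply(trees2, topologyClass, "") == "branched"))
    expect_false(any(vapply(trees2, function(t) t@synchronousPrimary,
                            logical(1))))
})

test_that("more than 8 clusters is rejected", {
    centers <- matrix(runif(27), 9)
    expect_error(enumerateTrees(centers), "8 clusters")
})

test_that("newick and DOT outputs encode the tree", {
    trees <- enumerateTrees(rbind(A = c(1, 1), B = c(0.6, 0.6),
                                  C = c(0.3, 0.3)))
    chain <- Filter(function(t)
        identical(unname(treeParents(t)[c("A", "B", "C")]),
                  c("root", "A", "B")), trees)[[1]]
    nwk <- subcloneNewick(chain, withComment = FALSE)
    expect_equal(nwk, "(((C)B)A)root;")
    ph <- asPhylo(chain)
    expect_s3_class(ph, "phylo")
    dotFile <- tempfile(fileext = ".dot")
    writeTreeDot(chain, dotFile)
    dot <- readLines(dotFile)
    expect_true(any(grepl("\"A\" -> \"B\"", dot)))
    expect_true(any(grepl("digraph", dot)))
})
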