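## Subclone-tree reconstruction by pairwise precedence tests and exhaustive
## enumeration of rooted trees over mutation clusters.
##
## Under the infinite sites assumption an ancestral cluster's cancer cell
## prevalence is at least its descendant's in every region; a tree is scored
## by the number of parent-child pairs violating that ordering plus the
## number of (node, region) pairs where children's prevalences sum above the
## parent's. All minimal-cost trees are reported.

#' Pairwise precedence test between two clusters
#'
#' Cluster i may be an ancestor of cluster j unless some region shows
#' j's mean prevalence above i's by more than \eqn{z_{1-\alpha}} pooled
#' standard deviations (a one-sided violation in any region rejects
#' ancestry). Standard deviations are floored at `sdFloor`.
#'
#' @param meanI,meanJ per-region mean prevalences.
#' @param sdI,sdJ per-region standard deviations (from cluster member
#'   spread).
#' @param alpha one-sided test level.
#' @param sdFloor lower bound on each sd.
#' @return `TRUE` when i may parent j.
#' @export
precedenceTest <- function(meanI, meanJ, sdI = 0, sdJ = 0, alpha = 0.05,
                           sdFloor = 0.02) {
    stopifnot(length(meanI) == length(meanJ))
    sdI <- pmax(rep_len(sdI, length(meanI)), sdFloor)
    sdJ <- pmax(rep_len(sdJ, length(meanJ)), sdFloor)
    pooled <- sqrt(sdI^2 + sdJ^2)
    !any(meanJ - meanI > qnorm(1 - alpha) * pooled)
}

#' Precedence matrix over clusters (root included)
#'
#' @param centers clusters x regions prevalence means.
#' @param sds matching standard deviations (0 if `NULL`).
#' @param alpha,sdFloor passed to [precedenceTest()].
#' @return logical matrix `M` with `M[i, j]` = i may parent j; the first
#'   row/column is the added root (prevalence 1, sd 0).
#' @export
precedenceMatrix <- function(centers, sds = NULL, alpha = 0.05,
                             sdFloor = 0.02) {
    if (is.null(sds)) sds <- centers * 0
    nodes <- rbind(root = rep(1, ncol(centers)), centers)
    nodeSds <- rbind(root = rep(0, ncol(centers)), sds)
    n <- nrow(nodes)
    M <- matrix(FALSE, n, n, dimnames = list(rownames(nodes),
                                             rownames(nodes)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        M[i, j] <- precedenceTest(nodes[i, ], nodes[j, ], nodeSds[i, ],
                                  nodeSds[j, ], alpha, sdFloor)
    }
    M
}

#' Enumerate minimal-cost subclone trees
#'
#' Adds a root node (the knock-in ancestral cell, prevalence 1 in every
#' region) above the observed clusters and scores every rooted labeled tree
#' by precedence violations plus region-wise sum-rule violations. All
#' minimal-cost trees are returned in deterministic (lexicographic parent
#' vector) order.
#'
#' @param centers clusters x regions prevalence means (rows named; at most 8
#'   clusters).
#' @param sds matching standard deviations (`NULL` for zeros).
#' @param alpha precedence-test level.
#' @param sumTol tolerance on the sum rule.
#' @param sdFloor precedence sd floor.
#' @param rootId label of the added root node.
#' @param maxTrees cap on returned trees.
#' @return list of [SubcloneTree-class] objects, all sharing the minimal
#'   cost.
#' @export
enumerateTrees <- function(centers, sds = NULL, alpha = 0.05,
                           sumTol = 0.10, sdFloor = 0.02, rootId = "root",
                           maxTrees = 1000L) {
    stopifnot(is.matrix(centers))
    if (nrow(centers) > 8L)
        stop("more than 8 clusters: exhaustive enumeration is out of scale; ",
             "reduce the cluster count")
    if (is.null(rownames(centers)))
        rownames(centers) <- as.character(seq_len(nrow(centers)))
    if (rootId %in% rownames(centers))
        stop("rootId clashes with a cluster id")
    M <- precedenceMatrix(centers, sds, alpha, sdFloor)
    prev <- rbind(rep(1, ncol(centers)), centers)
    rownames(prev) <- c(rootId, rownames(centers))
    res <- .enumerateTreesCpp(prev, M, sumTol, as.integer(maxTrees))
    if (res$truncated)
        warning("more than ", maxTrees, " minimal-cost trees; ",
                "returning the first ", maxTrees)
    ids <- rownames(prev)
    lapply(seq_len(nrow(res$parents)), function(t) {
        pv <- res$parents[t, ]
        parents <- setNames(c(NA_character_, ids[pv[-1L] + 1L]), ids)
        topo <- classifyTopology(parents, prev, rootId)
        new("SubcloneTree", parents = parents, prevalence = prev,
            cost = as.integer(res$cost),
            costPrecedence = res$costPrecedence[t],
            costSumRule = res$costSumRule[t],
            topology = topo$topology,
            synchronousPrimary = topo$synchronousPrimary, rootId = rootId)
    })
}

#' Classify a subclone tree as linear or branched
#'
#' Linear means every node has at most one child. The synchronous-primary
#' flag is set when the root has two or more children and no non-root
#' cluster sits at high prevalence (>= `highPrev`) in every analyzed region
#' -- the signature of two independently initiated tumors.
#'
#' @param parents named parent map (root maps to `NA`), or a
#'   [SubcloneTree-class].
#' @param prevalence nodes x regions matrix (required when `parents` is a
#'   map).
#' @param rootId root node label.
#' @param highPrev high-prevalence cutoff.
#' @return list with `topology` (`"linear"`/`"branched"`) and
#'   `synchronousPrimary` (logical).
#' @export
classifyTopology <- function(parents, prevalence = NULL, rootId = "root",
                             highPrev = 0.5) {
    if (is(parents, "SubcloneTree")) {
        prevalence <- parents@prevalence
        rootId <- parents@rootId
        parents <- parents@parents
    }
    kids <- table(parents[!is.na(parents)])
    linear <- !length(kids) || max(kids) <= 1L
    nonRoot <- setdiff(rownames(prevalence), rootId)
    anyUbiquitousHigh <- any(vapply(nonRoot, function(id)
        all(prevalence[id, ] >= highPrev), logical(1)))
    rootKids <- sum(parents[!is.na(parents)] == rootId)
    list(topology = if (linear) "linear" else "branched",
         synchronousPrimary = rootKids >= 2L && !anyUbiquitousHigh)
}

#' Recount a tree's violation cost independently of the search
#'
#' @param tree a [SubcloneTree-class].
#' @param alpha,sumTol,sdFloor scoring parameters (must match the search).
#' @param sds optional cluster sds (rows must match the non-root rows of the
#'   tree's prevalence matrix).
#' @return list with `costPrecedence`, `costSumRule`, `cost`.
#' @export
treeCostRecount <- function(tree, sds = NULL, alpha = 0.05, sumTol = 0.10,
                            sdFloor = 0.02) {
    P <- tree@prevalence
    ids <- rownames(P)
    centers <- P[setdiff(ids, tree@rootId), , drop = FALSE]
    M <- precedenceMatrix(centers, sds, alpha, sdFloor)
    rownames(M)[1L] <- colnames(M)[1L] <- tree@rootId
    cp <- 0L
    for (id in ids) {
        par <- tree@parents[[id]]
        if (!is.na(par) && !M[par, id]) cp <- cp + 1L
    }
    cs <- 0L
    for (id in ids) {
        kids <- names(tree@parents)[!is.na(tree@parents) &
                                    tree@parents == id]
        if (!length(kids)) next
        s <- colSums(P[kids, , drop = FALSE])
        cs <- cs + sum(s > P[id, ] + sumTol)
    }
    list(costPrecedence = cp, costSumRule = cs, cost = cp + cs)
}

#' Newick string of a subclone tree
#'
#' Cluster ids are tip/node labels; the tree cost is appended as a trailing
#' comment.
#'
#' @param tree a [SubcloneTree-class].
#' @param withComment append `[cost=..]` after the terminating semicolon.
#' @return character scalar.
#' @export
subcloneNewick <- function(tree, withComment = TRUE) {
    children <- function(id)
        names(tree@parents)[!is.na(tree@parents) & tree@parents == id]
    rec <- function(id) {
        kids <- children(id)
        if (!length(kids)) return(id)
        paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
               ")", id)
    }
    paste0(rec(tree@rootId), ";",
           if (withComment) sprintf("[cost=%d]", tree@cost) else "")
}

#' Convert a subclone tree to an ape \code{phylo} object
#'
#' @param tree a [SubcloneTree-class].
#' @return an \code{ape::phylo}.
#' @export
asPhylo <- function(tree) {
    ape::read.tree(text = subcloneNewick(tree, withComment = FALSE))
}

#' Write a subclone tree as a Graphviz DOT diagram
#'
#' @param tree a [SubcloneTree-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTreeDot <- function(tree, path) {
    lines <- c("digraph subclones {", "  node [shape=ellipse];")
    for (id in names(tree@parents)) {
        lab <- sprintf("%s\\n[%s]", id,
                       paste(sprintf("%.2f", tree@prevalence[id, ]),
                             collapse = ", "))
        lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];", id, lab))
    }
    for (id in names(tree@parents)) {
        par <- tree@parents[[id]]
        if (!is.na(par))
            lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", par, id))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
    invisible(path)
}
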