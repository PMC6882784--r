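#' qPCR standard curve relating tumor purity to Ct
#'
#' Linear model \eqn{Ct = A \cdot purity + B} fitted by ordinary least squares
#' over all replicate points of a dilution series of tumor and normal DNA.
#' Inverting the line converts a sample Ct into a purity estimate.
#'
#' @slot slope numeric, Ct change per unit purity (A); negative for an assay
#'   whose template is lost in tumor cells.
#' @slot intercept numeric, Ct at purity 0 (B).
#' @slot r.squared numeric, fraction of Ct variance explained by the line.
#' @slot nPoints integer, number of replicate points used in the fit.
#' @exportClass StandardCurve
setClass("StandardCurve",
    representation(slope = "numeric", intercept = "numeric",
                   r.squared = "numeric", nPoints = "integer"))

setValidity("StandardCurve", function(object) {
    if (length(object@slope) != 1L || !is.finite(object@slope))
        return("slope must be a single finite number")
    if (object@slope == 0)
        return("slope must be non-zero (curve not invertible)")
    if (object@nPoints < 2L)
        return("curve must be fitted from at least 2 points")
    TRUE
})

setMethod("show", "StandardCurve", function(object) {
    cat("StandardCurve: Ct =", format(object@slope, digits = 4),
        "* purity +", format(object@intercept, digits = 4), "\n")
    cat("  fitted on", object@nPoints, "points, R^2 =",
        format(object@r.squared, digits = 3), "\n")
})

#' Simulation-calibrated MAF threshold for allelic imbalance
#'
#' Result of the per-sample calibration that simulates minor-allele
#' frequencies for SNPs under one-copy loss (expected MAF \eqn{(1-p)/(2-p)})
#' and under balance (0.5) at the sample's coverage, then scans candidate
#' thresholds for the best F1 among those with sensitivity and specificity
#' above the gate.
#'
#' @slot sample character sample id (may be empty).
#' @slot purity numeric tumor purity used for the simulation.
#' @slot coverage numeric sequencing coverage used for the simulation.
#' @slot threshold numeric chosen MAF threshold, `NA` when lacking power.
#' @slot lackingPower logical, `TRUE` when no threshold met the gates.
#' @slot sensitivity,specificity,f1 numeric performance at the chosen
#'   threshold (`NA` when lacking power).
#' @exportClass ThresholdCalibration
setClass("ThresholdCalibration",
    representation(sample = "character", purity = "numeric",
                   coverage = "numeric", threshold = "numeric",
                   lackingPower = "logical", sensitivity = "numeric",
                   specificity = "numeric", f1 = "numeric"))

setValidity("ThresholdCalibration", function(object) {
    if (!object@lackingPower) {
        if (!is.finite(object@threshold) ||
            object@threshold < 0 || object@threshold > 0.5)
            return("threshold must lie in [0, 0.5] unless lacking power")
        if (object@sensitivity <= 0.8 || object@specificity <= 0.8)
            return("a powered calibration requires sensitivity and specificity > 0.8")
    }
    TRUE
})

setMethod("show", "ThresholdCalibration", function(object) {
    if (object@lackingPower) {
        cat("ThresholdCalibration: lacking power (purity",
            format(object@purity, digits = 3), ", coverage",
            object@coverage, ")\n")
    } else {
        cat("ThresholdCalibration: MAF threshold", object@threshold,
            " (sens", format(object@sensitivity, digits = 3),
            ", spec", format(object@specificity, digits = 3),
            ", F1", format(object@f1, digits = 3), ")\n")
    }
})

#' Ground-truth subclone tree of a simulated mouse
#'
#' The generating hierarchy of mutation clusters: a parent map rooted at the
#' knock-in transgene cluster and a cluster-by-region cancer-cell-prevalence
#' matrix. Within every region the prevalences of a node's children sum to at
#' most the node's own prevalence (the sum rule of the infinite sites model).
#'
#' @slot parents named character vector mapping each cluster id to its parent
#'   id; the root maps to `NA`.
#' @slot prevalence numeric matrix, clusters (rows, named) by regions (cols).
#' @slot topology one of `"linear"`, `"branched"`, `"two_primary"`.
#' @slot rootId character, cluster id of the root.
#' @exportClass TruthTree
setClass("TruthTree",
    representation(parents = "character", prevalence = "matrix",
                   topology = "character", rootId = "character"))

setValidity("TruthTree", function(object) {
    ids <- rownames(object@prevalence)
    if (!identical(sort(names(object@parents)), sort(ids)))
        return("parent map and prevalence matrix must cover the same clusters")
    if (!object@rootId %in% ids)
        return("rootId must be a cluster")
    if (!is.na(object@parents[[object@rootId]]))
        return("root must have parent NA")
    if (sum(is.na(object@parents)) != 1L)
        return("exactly one root allowed")
    P <- object@prevalence
    if (any(P < -1e-9 | P > 1 + 1e-9))
        return("prevalences must lie in [0, 1]")
    if (any(abs(P[object@rootId, ] - 1) > 1e-9))
        return("root prevalence must be 1 in every region")
    for (id in ids) {
        kids <- names(object@parents)[!is.na(object@parents) &
                                      object@parents == id]
        if (length(kids)) {
            s <- colSums(P[kids, , drop = FALSE])
            if (any(s > P[id, ] + 1e-9))
                return(sprintf("sum rule violated under cluster %s", id))
        }
    }
    if (!object@topology %in% c("linear", "branched", "two_primary"))
        return("unknown topology label")
    TRUE
})

setMethod("show", "TruthTree", function(object) {
    cat("TruthTree:", nrow(object@prevalence), "clusters x",
        ncol(object@prevalence), "regions, topology =",
        object@topology, "\n")
    edges <- paste(object@parents[!is.na(object@parents)], "->",
                   names(object@parents)[!is.na(object@parents)])
    cat(" ", paste(edges, collapse = "; "), "\n")
})

#' A fully simulated multi-region mouse tumor
#'
#' Holds everything the analysis pipeline consumes for one animal: the truth
#' tree, per-region purity, the somatic mutation read-count table, probe-level
#' aCGH log-ratio tracks, germline het-SNP allele counts, the copy-number
#' truth segments, and the qPCR standards/sample Cts from which purity is
#' re-estimated.
#'
#' @slot mouseId character.
#' @slot genotype `"KPC"` or `"KPTC"`.
#' @slot purity numeric per-region tumor purity in (0, 1].
#' @slot tree [TruthTree-class] generating hierarchy.
#' @slot mutations data.frame of per-mutation, per-region read counts.
#' @slot probes data.frame of probe log ratios (chrom, pos, region, log2ratio).
#' @slot snps data.frame of het-SNP allele counts per region.
#' @slot cnTruth data.frame of truth copy-number segments per region.
#' @slot ctStandards data.frame (purity, ct) of the dilution series.
#' @slot ctSample data.frame (region, ct) of sample measurements.
#' @exportClass SimulatedMouse
setClass("SimulatedMouse",
    representation(mouseId = "character", genotype = "character",
                   purity = "numeric", tree = "TruthTree",
                   mutations = "data.frame", probes = "data.frame",
                   snps = "data.frame", cnTruth = "data.frame",
                   ctStandards = "data.frame", ctSample = "data.frame"))

setValidity("SimulatedMouse", function(object) {
    if (!object@genotype %in% c("KPC", "KPTC"))
        return("genotype must be KPC or KPTC")
    if (any(object@purity <= 0 | object@purity > 1))
        return("purity must lie in (0, 1]")
    m <- object@mutations
    if (nrow(m)) {
        if (any(m$var > m$depth))
            return("variant count exceeds depth")
        if (any(m$var < 0 | m$depth < 0))
            return("negative read counts")
        if (any(m$fwd + m$rev != m$var))
            return("strand counts must sum to the variant count")
    }
    TRUE
})

setMethod("show", "SimulatedMouse", function(object) {
    cat("SimulatedMouse", object@mouseId, sprintf("(%s)", object@genotype),
        "-", ncol(object@tree@prevalence), "regions\n")
    cat("  purity:", paste(format(object@purity, digits = 2),
                           collapse = ", "), "\n")
    cat("  ", length(unique(object@mutations$id)), "mutations in",
        nrow(object@tree@prevalence), "clusters; topology",
        object@tree@topology, "\n")
})

#' Grid posterior of cancer cell prevalence for one mutation in one region
#'
#' Binomial likelihood of the observed variant/total read counts evaluated on
#' a prevalence grid 0 to 1 in steps of 0.01 and normalized to a discrete
#' posterior (flat prior). Point estimate is the grid argmax; the interval is
#' the central 95% of the grid mass, widened if needed to contain the argmax.
#'
#' @slot grid numeric prevalence grid.
#' @slot posterior numeric normalized grid weights (sums to 1).
#' @slot pointEstimate numeric grid argmax.
#' @slot lower,upper numeric interval bounds.
#' @slot multiplicity integer mutation multiplicity used, `NA` if unresolved.
#' @slot missing logical, `TRUE` when no estimate could be produced.
#' @exportClass PrevalenceEstimate
setClass("PrevalenceEstimate",
    representation(grid = "numeric", posterior = "numeric",
                   pointEstimate = "numeric", lower = "numeric",
                   upper = "numeric", multiplicity = "integer",
                   missing = "logical"))

setValidity("PrevalenceEstimate", function(object) {
    if (object@missing)
        return(TRUE)
    if (abs(sum(object@posterior) - 1) > 1e-9)
        return("posterior must sum to 1")
    if (object@pointEstimate < 0 || object@pointEstimate > 1)
        return("point estimate outside [0, 1]")
    if (object@pointEstimate < object@lower - 1e-12 ||
        object@pointEstimate > object@upper + 1e-12)
        return("interval must contain the point estimate")
    TRUE
})

setMethod("show", "PrevalenceEstimate", function(object) {
    if (object@missing) {
        cat("PrevalenceEstimate: missing\n")
    } else {
        cat(sprintf("PrevalenceEstimate: C = %.2f [%.2f, %.2f], m = %s\n",
                    object@pointEstimate, object@lower, object@upper,
                    ifelse(is.na(object@multiplicity), "?",
                           object@multiplicity)))
    }
})

#' Clustering of mutations by cancer cell prevalence across regions
#'
#' @slot assignments integer cluster label per mutation (named by mutation
#'   id); mutations excluded for missing values carry `NA`.
#' @slot centers numeric matrix, clusters x regions mean prevalence.
#' @slot sds numeric matrix, clusters x regions prevalence standard deviation.
#' @slot method `"dbscan"`, `"affinity_propagation"` or `"trivial"`.
#' @slot silhouette numeric average silhouette width of the chosen solution
#'   (`NA` for a single cluster).
#' @slot eps numeric DBSCAN radius used (`NA` for other methods).
#' @exportClass PrevalenceClustering
setClass("PrevalenceClustering",
    representation(assignments = "integer", centers = "matrix",
                   sds = "matrix", method = "character",
                   silhouette = "numeric", eps = "numeric"))

setValidity("PrevalenceClustering", function(object) {
    if (nrow(object@centers) < 1L)
        return("at least one cluster required")
    if (any(object@centers < -1e-9 | object@centers > 1 + 1e-9))
        return("cluster means must lie in [0, 1]")
    lab <- object@assignments[!is.na(object@assignments)]
    if (length(lab) && !all(lab %in% seq_len(nrow(object@centers))))
        return("assignments refer to unknown clusters")
    TRUE
})

setMethod("show", "PrevalenceClustering", function(object) {
    cat("PrevalenceClustering:", nrow(object@centers), "clusters over",
        sum(!is.na(object@assignments)), "mutations [", object@method, "]\n")
    print(round(object@centers, 3))
})

#' Reconstructed subclone hierarchy
#'
#' A rooted tree over mutation clusters (root = knock-in ancestral cell,
#' prevalence 1 in every region) scored by the number of parent-child
#' precedence violations plus region-wise sum-rule violations.
#'
#' @slot parents named character parent map; root maps to `NA`.
#' @slot prevalence numeric matrix, nodes x regions (includes the root row).
#' @slot cost integer total violation count.
#' @slot costPrecedence,costSumRule integer cost components.
#' @slot topology `"linear"` or `"branched"`.
#' @slot synchronousPrimary logical, `TRUE` when the root has several children
#'   and no non-root cluster is at high prevalence in every region.
#' @slot rootId character id of the root node.
#' @exportClass SubcloneTree
setClass("SubcloneTree",
    representation(parents = "character", prevalence = "matrix",
                   cost = "integer", costPrecedence = "integer",
                   costSumRule = "integer", topology = "character",
                   synchronousPrimary = "logical", rootId = "character"))

setValidity("SubcloneTree", function(object) {
    if (sum(is.na(object@parents)) != 1L)
        return("exactly one root allowed")
    if (is.na(object@parents[[object@rootId]]) == FALSE)
        return("rootId must be the parentless node")
    ## acyclicity: walking up from every node must reach the root
    for (id in names(object@parents)) {
        seen <- character(0)
        cur <- id
        while (!is.na(object@parents[[cur]])) {
            if (cur %in% seen)
                return("parent map contains a cycle")
            seen <- c(seen, cur)
            cur <- object@parents[[cur]]
        }
    }
    if (object@cost < 0)
        return("cost must be non-negative")
    TRUE
})

setMethod("show", "SubcloneTree", function(object) {
    cat("SubcloneTree (", object@topology,
        if (object@synchronousPrimary) ", synchronous primaries" else "",
        "), cost ", object@cost, " (precedence ", object@costPrecedence,
        " + sum-rule ", object@costSumRule, ")\n", sep = "")
    edges <- paste(object@parents[!is.na(object@parents)], "->",
                   names(object@parents)[!is.na(object@parents)])
    cat(" ", paste(edges, collapse = "; "), "\n")
})
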