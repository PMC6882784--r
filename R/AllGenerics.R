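#' Accessors for mrclone classes
#'
#' Small accessor layer over the S4 slots; user code should prefer these to
#' direct slot access.
#'
#' @param object an mrclone S4 object.
#' @return The slot value named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveSlope", function(object) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setMethod("curveSlope", "StandardCurve", function(object) object@slope)

#' @rdname accessors
#' @export
setGeneric("curveIntercept",
           function(object) standardGeneric("curveIntercept"))
#' @rdname accessors
#' @export
setMethod("curveIntercept", "StandardCurve",
          function(object) object@intercept)

#' @rdname accessors
#' @export
setGeneric("mafThreshold", function(object) standardGeneric("mafThreshold"))
#' @rdname accessors
#' @export
setMethod("mafThreshold", "ThresholdCalibration",
          function(object) object@threshold)

#' @rdname accessors
#' @export
setGeneric("lackingPower", function(object) standardGeneric("lackingPower"))
#' @rdname accessors
#' @export
setMethod("lackingPower", "ThresholdCalibration",
          function(object) object@lackingPower)

#' @rdname accessors
#' @export
setGeneric("treeParents", function(object) standardGeneric("treeParents"))
#' @rdname accessors
#' @export
setMethod("treeParents", "TruthTree", function(object) object@parents)
#' @rdname accessors
#' @export
setMethod("treeParents", "SubcloneTree", function(object) object@parents)

#' @rdname accessors
#' @export
setGeneric("prevalenceMatrix",
           function(object) standardGeneric("prevalenceMatrix"))
#' @rdname accessors
#' @export
setMethod("prevalenceMatrix", "TruthTree",
          function(object) object@prevalence)
#' @rdname accessors
#' @export
setMethod("prevalenceMatrix", "SubcloneTree",
          function(object) object@prevalence)

#' @rdname accessors
#' @export
setGeneric("topologyClass", function(object) standardGeneric("topologyClass"))
#' @rdname accessors
#' @export
setMethod("topologyClass", "TruthTree", function(object) object@topology)
#' @rdname accessors
#' @export
setMethod("topologyClass", "SubcloneTree", function(object) object@topology)

#' @rdname accessors
#' @export
setGeneric("treeCost", function(object) standardGeneric("treeCost"))
#' @rdname accessors
#' @export
setMethod("treeCost", "SubcloneTree", function(object) object@cost)

#' @rdname accessors
#' @export
setGeneric("pointEstimate", function(object) standardGeneric("pointEstimate"))
#' @rdname accessors
#' @export
setMethod("pointEstimate", "PrevalenceEstimate",
          function(object) object@pointEstimate)

#' @rdname accessors
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "PrevalenceClustering",
          function(object) object@assignments)

#' @rdname accessors
#' @export
setGeneric("clusterCenters",
           function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setMethod("clusterCenters", "PrevalenceClustering",
          function(object) object@centers)

#' @rdname accessors
#' @export
setGeneric("clusterSds", function(object) standardGeneric("clusterSds"))
#' @rdname accessors
#' @export
setMethod("clusterSds", "PrevalenceClustering", function(object) object@sds)
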