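#' @rdname SampleMeta-class
#' @param object A \code{SampleMeta}.
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))

#' @rdname SampleMeta-class
#' @export
setGeneric("ploidy", function(object) standardGeneric("ploidy"))

#' @rdname SampleMeta-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname SampleMeta-class
#' @export
setGeneric("randomSeed", function(object) standardGeneric("randomSeed"))

#' Evaluate a detection-sensitivity curve
#'
#' @param object A \code{\link{SensitivityCurve}} (or NULL for flat
#'   sensitivity 1).
#' @param theta Fractions of tumor cells in (0, 1].
#' @return \eqn{S(\theta)} for each theta.
#' @export
setGeneric("sensitivity", function(object, theta) standardGeneric("sensitivity"))

#' @rdname ClusterFit-class
#' @param object A \code{ClusterFit}.
#' @export
setGeneric("clusterLocations", function(object) standardGeneric("clusterLocations"))

#' @rdname ClusterFit-class
#' @export
setGeneric("clusterWeights", function(object) standardGeneric("clusterWeights"))

#' @rdname ClusterFit-class
#' @export
setGeneric("clusterCounts", function(object) standardGeneric("clusterCounts"))

#' @rdname ClusterFit-class
#' @export
setGeneric("posteriorDensity", function(object) standardGeneric("posteriorDensity"))
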