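# Accessors and show methods.

#' @rdname SampleMeta-class
#' @export
setMethod("purity", "SampleMeta", function(object) object@purity)

#' @rdname SampleMeta-class
#' @export
setMethod("ploidy", "SampleMeta", function(object) object@ploidy)

#' @rdname SampleMeta-class
#' @export
setMethod("sampleId", "SampleMeta", function(object) object@sampleId)

#' @rdname SampleMeta-class
#' @export
setMethod("randomSeed", "SampleMeta", function(object) object@seed)

setMethod("show", "SampleMeta", function(object) {
  cat(sprintf("SampleMeta '%s': purity %.3f, ploidy %.3f, seed %d\n",
              object@sampleId, object@purity, object@ploidy, object@seed))
})

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "SensitivityCurve", function(object, theta) {
  stopifnot(all(theta > 0 & theta <= 1))
  object@A / (1 + exp((object@chi - log(theta)) / object@sigma))
})

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "NULL", function(object, theta) {
  rep(1, length(theta))
})

setMethod("show", "SensitivityCurve", function(object) {
  cat(sprintf("SensitivityCurve: A = %.4f, chi = %.4f, sigma = %.4f\n",
              object@A, object@chi, object@sigma))
  if (nrow(object@rawPoints))
    cat(sprintf("  fitted to %d spike-in points (theta %.3g..%.3g)\n",
                nrow(object@rawPoints), min(object@rawPoints$theta),
                max(object@rawPoints$theta)))
})

#' @rdname ClusterFit-class
#' @export
setMethod("clusterLocations", "ClusterFit", function(object)
  object@clusterSummary$location)

#' @rdname ClusterFit-class
#' @export
setMethod("clusterWeights", "ClusterFit", function(object)
  object@clusterSummary$weight)

#' @rdname ClusterFit-class
#' @export
setMethod("clusterCounts", "ClusterFit", function(object)
  object@clusterSummary[, c("location", "count", "countLo", "countHi")])

#' @rdname ClusterFit-class
#' @export
setMethod("posteriorDensity", "ClusterFit", function(object) object@density)

setMethod("show", "ClusterFit", function(object) {
  cs <- object@clusterSummary
  cat(sprintf("ClusterFit: %d occupied clusters (of H = %d), %d monitored draws\n",
              nrow(cs), ncol(object@locations), nrow(object@locations)))
  if (!object@converged)
    cat(sprintf("  WARNING: convergence diagnostic exceeded (Rhat = %.3f)\n",
                object@rhat))
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  cluster at %.1f%% of tumor cells: weight %.3f, ~%d mutations (%d-%d)\n",
                100 * cs$location[i], cs$weight[i], round(cs$count[i]),
                round(cs$countLo[i]), round(cs$countHi[i])))
})

.showNode <- function(node, indent = "") {
  amb <- if (isTRUE(node$ambiguous)) " [unplaced]" else ""
  ev <- if (length(node$events)) paste0(" {", paste(node$events, collapse = ","), "}") else ""
  cat(sprintf("%s%s (%.0f%% of tumor cells, %d mutations)%s%s\n", indent,
              node$label, 100 * node$fraction, node$nMutations, ev, amb))
  for (ch in node$children) .showNode(ch, paste0(indent, "  "))
}

setMethod("show", "CloneTree", function(object) {
  cat("CloneTree:\n")
  .showNode(object@root, "  ")
})
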