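# Generics, accessors and show methods.

#' Extract the value grid of a probability map
#' @param x a [ProbabilityMap-class].
#' @return numeric matrix in \[0, 1\].
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "ProbabilityMap", function(x) x@values)

#' Physical pixel scale (microns per pixel)
#' @param x a [ProbabilityMap-class] or [SyntheticScene-class].
#' @return microns per pixel.
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname pixelSizeUm
#' @export
setMethod("pixelSizeUm", "ProbabilityMap", function(x) x@mpp)

#' @rdname pixelSizeUm
#' @export
setMethod("pixelSizeUm", "SyntheticScene", function(x) x@spec@mpp)

#' Number of connected components
#' @param x a [ComponentSet-class].
#' @return integer count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname nComponents
#' @export
setMethod("nComponents", "ComponentSet", function(x) nrow(x@table))

#' Component table
#' @param x a [ComponentSet-class].
#' @return data.frame with one row per component.
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname componentTable
#' @export
setMethod("componentTable", "ComponentSet", function(x) x@table)

#' Label matrix of a component set
#' @param x a [ComponentSet-class].
#' @return integer matrix (0 = background).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "ComponentSet", function(x) x@labels)

#' Per-nerve decision table
#' @param x a [DecisionResult-class].
#' @return data.frame with one row per detected nerve structure.
#' @export
setGeneric("nerveTable", function(x) standardGeneric("nerveTable"))

#' @rdname nerveTable
#' @export
setMethod("nerveTable", "DecisionResult", function(x) x@nerves)

#' Confusion counts as a named vector
#' @param x a [ConfusionMatrix-class].
#' @return named numeric vector `c(tp, fp, fn, tn)`.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname confusionCounts
#' @export
setMethod("confusionCounts", "ConfusionMatrix",
          function(x) c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))

#' Displayed (truncated) percentages of a metrics report
#'
#' Truncation -- not rounding -- to 2 decimals is the display convention for
#' sensitivity, specificity and accuracy percentages.
#'
#' @param x a [MetricsReport-class].
#' @return named numeric vector with entries `sensitivity`, `specificity`,
#'   `accuracy`, truncated to 2 decimals (`NA` where undefined).
#' @examples
#' displayedMetrics(metrics(ConfusionMatrix(12, 7, 4, 384)))
#' @export
setGeneric("displayedMetrics", function(x) standardGeneric("displayedMetrics"))

#' @rdname displayedMetrics
#' @export
setMethod("displayedMetrics", "MetricsReport", function(x) {
  c(sensitivity = trunc2(x@sensitivity),
    specificity = trunc2(x@specificity),
    accuracy = trunc2(x@accuracy))
})

#' Patch origins of a grid
#' @param x a [PatchGrid-class].
#' @return integer matrix of 0-based (row, col) origins.
#' @export
setGeneric("patchOrigins", function(x) standardGeneric("patchOrigins"))

#' @rdname patchOrigins
#' @export
setMethod("patchOrigins", "PatchGrid", function(x) x@origins)

#' Sweep table
#' @param x a [SweepResult-class].
#' @return data.frame, one row per cutoff.
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname sweepTable
#' @export
setMethod("sweepTable", "SweepResult", function(x) x@table)

# --- show methods ----------------------------------------------------------

setMethod("show", "ProbabilityMap", function(object) {
  v <- object@values
  cat(sprintf("ProbabilityMap [%s]: %d x %d px at %.3g um/px, range [%.3f, %.3f]\n",
              object@channel, nrow(v), ncol(v), object@mpp, min(v), max(v)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0(
    "SceneSpec: %d x %d px at %.3g um/px\n",
    "  nerves: %d (PNI fraction %.2f), semi-axes %g-%g px, perineurium %g px\n",
    "  nests: %g-%g cells of %.1f px; noise blobs: %d (%s); specks: %d\n",
    "  seed: %d\n"),
    object@heightPx, object@widthPx, object@mpp, object@nNerves,
    object@pniFraction, object@nerveAxisRangePx[1], object@nerveAxisRangePx[2],
    object@perineuriumThicknessPx, object@pniNestCells[1],
    object@pniNestCells[2], object@tumorCellDiameterPx, object@nNoiseBlobs,
    object@noiseSizeDist$name, object@nSpecks, as.integer(object@seed)))
})

setMethod("show", "SyntheticScene", function(object) {
  rec <- object@nerveRecords
  cat(sprintf("SyntheticScene: %d x %d px, %d nerves (%d PNI), %d noise objects\n",
              nrow(object@nerveTruth), ncol(object@nerveTruth), nrow(rec),
              sum(rec$class == "PNI"), length(object@noiseAreas)))
})

setMethod("show", "DecisionConfig", function(object) {
  cat(sprintf(paste0(
    "DecisionConfig: pyramid levels %d, nerve threshold %.2f, smoothing r=%d px\n",
    "  PNI constant threshold %.2f (combined with Otsu by max)\n",
    "  size cutoff %s px^2, adjacency %s px (Chebyshev), connectivity %d\n"),
    object@pyramidLevels, object@nerveThreshold, object@smoothingRadiusPx,
    object@pniConstThreshold, format(object@sizeCutoffPx2),
    format(object@adjacencyPx), object@connectivity))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components (connectivity %d), total area %s px^2\n",
              nrow(object@table), object@connectivity,
              format(sum(object@table$area_px2))))
})

setMethod("show", "DecisionResult", function(object) {
  n <- object@nerves
  cat(sprintf("DecisionResult: %d nerve structures, %d PNI-positive\n",
              nrow(n), sum(n$predicted_class == "PNI")))
  cat(sprintf("  PNI components: %d retained, %d removed by size filter (cutoff %s px^2)\n",
              nrow(object@retained), nrow(object@removed),
              format(object@config@sizeCutoffPx2)))
})

setMethod("show", "SizeFilterCalibration", function(object) {
  cat(sprintf("SizeFilterCalibration: n = %d, alpha = %.2f -> cutoff %s px^2\n",
              length(object@sampleAreasPx2), object@alpha,
              format(object@cutoffPx2)))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP %d  FP %d  FN %d  TN %d\n",
              object@tp, object@fp, object@fn, object@tn))
})

setMethod("show", "MetricsReport", function(object) {
  d <- displayedMetrics(object)
  fmt <- function(x) ifelse(is.na(x), "undefined", sprintf("%.2f%%", x))
  cat(sprintf("MetricsReport: sensitivity %s  specificity %s  accuracy %s\n",
              fmt(d[1]), fmt(d[2]), fmt(d[3])))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %d x %d (stride %d x %d) over %d x %d\n",
              nrow(object@origins), object@patchSize[1], object@patchSize[2],
              object@stride[1], object@stride[2],
              object@imageSize[1], object@imageSize[2]))
})

setMethod("show", "SegModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0(
    "SegModel: %d x %d x 3 -> %d x %d x 1 (sigmoid head)\n",
    "  base channels %d, branches %d, %s trainable parameters, step %d\n"),
    cfg@inputSize[1], cfg@inputSize[2], cfg@inputSize[1], cfg@inputSize[2],
    cfg@baseChannels, cfg@nBranches,
    format(nParameters(object), big.mark = ","), object@env$step))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d cutoffs from %s to %s px^2\n",
              nrow(object@table), format(min(object@table$cutoff_px2)),
              format(max(object@table$cutoff_px2))))
})
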