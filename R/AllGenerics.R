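# Constructors, accessors and show methods for the core S4 classes.

#' Construct an EdgeMap
#'
#' @param magnitudes numeric H x W matrix in \[0, 255\].
#' @param provenance operator label.
#' @return An [EdgeMap-class] object.
#' @examples
#' em <- edgeMap(matrix(0, 4, 4), "sobel")
#' @export
edgeMap <- function(magnitudes, provenance = "unknown") {
  storage.mode(magnitudes) <- "double"
  new("EdgeMap", magnitudes = magnitudes, provenance = provenance)
}

#' Construct a PixelPath
#'
#' @param nodes n x 2 (row, col) matrix, 1-based.
#' @param cost path cost under some edge map, or `NA` for geometric chains.
#' @return A [PixelPath-class] object.
#' @export
pixelPath <- function(nodes, cost = NA_real_) {
  nodes <- .nodes(nodes)
  new("PixelPath", nodes = nodes, cost = as.numeric(cost))
}

#' Construct a ContourAnnotation
#'
#' @param start,end (row, col) endpoint positions, 1-based.
#' @param keypoints k x 2 (row, col) matrix (or NULL), ordered from start
#'   toward end.
#' @param side `"left"` or `"right"`.
#' @return A [ContourAnnotation-class] object.
#' @export
contourAnnotation <- function(start, end, keypoints = NULL, side = "left") {
  if (is.null(keypoints)) keypoints <- matrix(integer(0), 0L, 2L)
  keypoints <- matrix(as.integer(round(keypoints)), ncol = 2L)
  new("ContourAnnotation",
      start = as.integer(round(start)), end = as.integer(round(end)),
      keypoints = keypoints, side = side)
}

#' Construct arc-weight parameters
#'
#' Defaults give roughly a 600:1 weight ratio between arcs through
#' non-edge pixels (g = 0) and strong-edge pixels (g = 255), attracting
#' shortest paths to edges without numerical overflow.
#'
#' @param alpha positive scale of the exponential term (default 1).
#' @param beta positive decay per gray level (default 0.025).
#' @param gamma nonnegative additive floor (default 0.005).
#' @param diagonalFactor multiplier for diagonal arcs (default `sqrt(2)`,
#'   the Euclidean length of a diagonal step).
#' @return An [EdgeWeightParams-class] object.
#' @examples
#' p <- edgeWeightParams()
#' arcWeight(255, 255, "straight", p)  # alpha + gamma
#' @export
edgeWeightParams <- function(alpha = 1, beta = 0.025, gamma = 0.005,
                             diagonalFactor = sqrt(2)) {
  new("EdgeWeightParams", alpha = alpha, beta = beta, gamma = gamma,
      diagonalFactor = diagonalFactor)
}

#' @describeIn edgeMap Accessor for the magnitude matrix.
#' @param x object.
#' @export
edgeMagnitudes <- function(x) .mags(x)

#' @describeIn edgeMap Accessor for the provenance label.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "EdgeMap"))
  x@provenance
}

#' @describeIn pixelPath Accessor for the node matrix.
#' @param x object.
#' @export
pathNodes <- function(x) .nodes(x)

#' @describeIn pixelPath Accessor for the stored path cost.
#' @export
totalCost <- function(x) {
  stopifnot(is(x, "PixelPath"))
  x@cost
}

#' @describeIn evaluateOperator Per-contour errors of an EvalResult.
#' @param x an [EvalResult-class].
#' @export
perImageErrors <- function(x) {
  stopifnot(is(x, "EvalResult"))
  x@perImageErrors
}

#' @describeIn evaluateOperator Summary (mean/sd/max, %) of an EvalResult.
#' @export
evalSummary <- function(x) {
  stopifnot(is(x, "EvalResult"))
  x@summary
}

setMethod("show", "EdgeMap", function(object) {
  m <- object@magnitudes
  cat(sprintf("EdgeMap [%s]: %d x %d, magnitudes in [%.1f, %.1f]\n",
              object@provenance, nrow(m), ncol(m), min(m), max(m)))
})

setMethod("show", "PixelPath", function(object) {
  n <- object@nodes
  cat(sprintf("PixelPath: %d nodes, (%d,%d) -> (%d,%d), cost %s\n",
              nrow(n), n[1, 1], n[1, 2], n[nrow(n), 1], n[nrow(n), 2],
              ifelse(is.na(object@cost), "NA", format(object@cost, digits = 6))))
})

setMethod("show", "ContourAnnotation", function(object) {
  cat(sprintf("ContourAnnotation [%s]: (%d,%d) -> (%d,%d), %d keypoints\n",
              object@side, object@start[1], object@start[2],
              object@end[1], object@end[2], nrow(object@keypoints)))
})

setMethod("show", "EdgeWeightParams", function(object) {
  cat(sprintf(
    "EdgeWeightParams: alpha=%g beta=%g gamma=%g diagonalFactor=%.4f\n",
    object@alpha, object@beta, object@gamma, object@diagonalFactor))
})

setMethod("show", "SobelUNet", function(object) {
  cat(sprintf(
    "SobelUNet: depth %d, base %d, bottleneck %d features, %s parameters (%s)\n",
    object@depth, object@baseFeatures,
    object@baseFeatures * 2L^(object@depth - 1L),
    format(sobelUNetParamCount(object), big.mark = ","), object@mode))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %dx%d, contrast %g, %d distractors, noise %g, seed %d\n",
    object@height, object@width, object@contourContrast,
    object@nDistractors, object@noiseSd, object@seed))
})

setMethod("show", "SceneSample", function(object) {
  cat(sprintf("SceneSample: %dx%d image, 2 annotated contours (%d + %d nodes)\n",
              nrow(object@image), ncol(object@image),
              nrow(object@gtChains[[1]]@nodes), nrow(object@gtChains[[2]]@nodes)))
})

setMethod("show", "EvalResult", function(object) {
  s <- object@summary
  cat(sprintf(
    "EvalResult [%s%s]: n=%d contours, mean %.3f%%, sd %.3f%%, max %.3f%%\n",
    object@operator,
    ifelse(is.na(object@fold), "", sprintf(", fold %d", object@fold)),
    length(object@perImageErrors), s["mean"], s["sd"], s["max"]))
})
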