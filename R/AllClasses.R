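#' @import methods
NULL

#' Gradient-magnitude edge map
#'
#' An H x W grid of edge strengths on the 0--255 scale produced by one of
#' the edge operators ([sobelMagnitude()], [prewittMagnitude()],
#' [cannyEdges()], [combineChannels()]) or by a trained [SobelUNet-class]
#' model.  The magnitudes are the quantity \eqn{g} entering the arc-weight
#' function \eqn{f(g) = \alpha e^{\beta(255-g)} + \gamma} when the map is
#' converted into a weighted pixel graph.
#'
#' @slot magnitudes numeric matrix, finite, in \[0, 255\].
#' @slot provenance single string naming the producing operator
#'   (`"sobel"`, `"prewitt"`, `"canny"`, `"learned"`, `"combined"`, ...).
#' @seealso [edgeMap()], [normalizeEdgeMap()], [shortestPath()]
#' @export
setClass("EdgeMap",
  representation(magnitudes = "matrix", provenance = "character"),
  validity = function(object) {
    m <- object@magnitudes
    if (!is.numeric(m)) return("magnitudes must be numeric")
    if (nrow(m) < 2L || ncol(m) < 2L) return("edge map must be at least 2x2")
    if (!all(is.finite(m))) return("magnitudes contain non-finite values")
    if (min(m) < 0 || max(m) > 255) return("magnitudes must lie in [0, 255]")
    if (length(object@provenance) != 1L) return("provenance must be a single string")
    TRUE
  })

#' Ordered 8-connected pixel chain
#'
#' A contour candidate: an ordered, duplicate-free sequence of pixel
#' positions in which consecutive nodes are 8-adjacent.  The `cost` slot
#' holds the path cost (sum of arc weights) under the edge map the path was
#' extracted from, or `NA` for purely geometric chains such as rasterized
#' ground-truth arcs.
#'
#' @slot nodes integer n x 2 matrix of (row, col) positions, 1-based.
#' @slot cost single numeric, nonnegative or `NA`.
#' @seealso [pixelPath()], [shortestPath()], [pathCost()]
#' @export
setClass("PixelPath",
  representation(nodes = "matrix", cost = "numeric"),
  validity = function(object) {
    n <- object@nodes
    if (!is.integer(n) || ncol(n) != 2L) return("nodes must be an integer n x 2 matrix")
    if (nrow(n) < 1L) return("a path has at least one node")
    if (nrow(n) > 1L) {
      d <- abs(diff(n))
      if (any(pmax(d[, 1], d[, 2]) != 1L))
        return("consecutive nodes must be 8-adjacent and distinct")
      key <- complex(real = n[, 1], imaginary = n[, 2])
      if (anyDuplicated(key)) return("path revisits a node")
    }
    if (length(object@cost) != 1L) return("cost must be a single number")
    if (!is.na(object@cost) && (!is.finite(object@cost) || object@cost < 0))
      return("cost must be nonnegative")
    TRUE
  })

#' Weak contour annotation: endpoints plus ordered keypoints
#'
#' The semi-automatic setting takes the two contour endpoints as input; a
#' ground-truth contour is derived from annotator keypoints by chaining
#' shortest-path segments through them (see [groundTruthPath()]).
#'
#' @slot start,end integer (row, col) endpoint positions, 1-based.
#' @slot keypoints integer k x 2 matrix (possibly 0 rows), ordered from
#'   `start` toward `end`.
#' @slot side `"left"` or `"right"` (patient's breast side).
#' @seealso [contourAnnotation()], [readAnnotation()]
#' @export
setClass("ContourAnnotation",
  representation(start = "integer", end = "integer",
                 keypoints = "matrix", side = "character"),
  validity = function(object) {
    if (length(object@start) != 2L || length(object@end) != 2L)
      return("start and end must be (row, col) pairs")
    if (!is.integer(object@keypoints) || ncol(object@keypoints) != 2L)
      return("keypoints must be an integer k x 2 matrix")
    if (!object@side %in% c("left", "right"))
      return("side must be 'left' or 'right'")
    TRUE
  })

#' Arc-weight parameters of the pixel graph
#'
#' Parameters of the arc-weight function
#' \eqn{f(g) = \alpha e^{\beta(255-g)} + \gamma} mapping the mean edge
#' magnitude \eqn{g} of two adjacent pixels to a graph arc weight; diagonal
#' arcs are scaled by `diagonalFactor` (default \eqn{\sqrt 2}) to account
#' for their longer physical length.
#'
#' @slot alpha positive scale of the exponential term.
#' @slot beta positive decay rate per gray level.
#' @slot gamma nonnegative additive floor.
#' @slot diagonalFactor diagonal arc length multiplier, at least 1.
#' @seealso [edgeWeightParams()], [arcWeight()]
#' @export
setClass("EdgeWeightParams",
  representation(alpha = "numeric", beta = "numeric",
                 gamma = "numeric", diagonalFactor = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != 1L || !is.finite(object@alpha) || object@alpha <= 0)
      return("alpha must be a positive number")
    if (length(object@beta) != 1L || !is.finite(object@beta) || object@beta <= 0)
      return("beta must be a positive number")
    if (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma < 0)
      return("gamma must be nonnegative")
    if (length(object@diagonalFactor) != 1L || !is.finite(object@diagonalFactor) ||
        object@diagonalFactor < 1)
      return("diagonalFactor must be at least 1")
    TRUE
  })

#' Shape-prior multiplier mask
#'
#' Per-pixel arc-weight multipliers encoding where a plausible breast
#' contour is expected given the two endpoints.  Multipliers are at least 1
#' everywhere: the prior penalises implausible regions but never rewards a
#' pixel below its base weight.
#'
#' @slot weights numeric H x W matrix, finite, >= 1.
#' @seealso [shapePriorMask()]
#' @export
setClass("PriorMask",
  representation(weights = "matrix"),
  validity = function(object) {
    w <- object@weights
    if (!all(is.finite(w))) return("prior weights must be finite")
    if (min(w) < 1) return("prior weights must be >= 1")
    TRUE
  })

#' Sobel-skip U-Net edge detector
#'
#' A lightweight U-Net whose decoder skip connections carry the (fixed,
#' non-learned) Sobel magnitude of the input image, downsampled to each
#' decoder resolution.  The encoder stacks `depth` blocks of two 3x3
#' convolutions + ReLU followed by 2x2 max pooling, doubling the channel
#' count up to the bottleneck (`baseFeatures * 2^(depth-1)`); the decoder
#' runs `depth` iterations of a convolutional block followed by a 2x2
#' transposed-convolution upsample, concatenating the Sobel pyramid level
#' at each resolution, and a final 1x1 convolution + sigmoid yields a
#' single edge channel.
#'
#' @slot depth number of encoder blocks (and decoder iterations).
#' @slot baseFeatures channels of the first encoder block.
#' @slot inChannels 1 (grayscale) or 3 (RGB).
#' @slot kernelSize convolution kernel size (odd).
#' @slot weights named list of parameter arrays.
#' @slot seed integer seed the initial parameters were drawn with.
#' @slot mode `"train"` or `"eval"` (informational; the forward pass is
#'   deterministic in both).
#' @seealso [sobelUNet()], [predictEdgeMap()], [trainSobelUNet()]
#' @export
setClass("SobelUNet",
  representation(depth = "integer", baseFeatures = "integer",
                 inChannels = "integer", kernelSize = "integer",
                 weights = "list", seed = "integer", mode = "character"),
  validity = function(object) {
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@baseFeatures < 2L || object@baseFeatures %% 2L != 0L)
      return("baseFeatures must be an even number >= 2")
    if (!object@inChannels %in% c(1L, 3L)) return("inChannels must be 1 or 3")
    if (object@kernelSize %% 2L != 1L) return("kernelSize must be odd")
    if (!object@mode %in% c("train", "eval")) return("mode must be 'train' or 'eval'")
    TRUE
  })

#' Parametric synthetic torso scene
#'
#' Describes a torso-against-background test image with two breast-contour
#' arcs of controllable edge contrast, optional distractor edges,
#' illumination gradient and Gaussian noise.  The rendered intensity step
#' across each contour arc equals `contourContrast`, so scenes with low
#' values emulate the weak-contour regime that defeats plain gradient
#' operators.
#'
#' @slot height,width image size in pixels.
#' @slot torsoIntensity,backgroundIntensity gray levels in \[0, 255\].
#' @slot contourContrast intensity step across each breast contour.
#' @slot arcParams list of two lists (left, right), each with `center`
#'   (row, col), `radii` (row, col semi-axes) and `span` (start/end angle in
#'   radians measured from the positive column axis, rows increasing
#'   downward).
#' @slot nDistractors number of distractor line/arc edges.
#' @slot distractorContrast intensity amplitude of distractors.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot illuminationGradient multiplicative linear shading ramp on/off.
#' @slot seed integer RNG seed used when rendering.
#' @seealso [sceneSpec()], [generateScene()]
#' @export
setClass("SceneSpec",
  representation(height = "integer", width = "integer",
                 torsoIntensity = "numeric", backgroundIntensity = "numeric",
                 contourContrast = "numeric", arcParams = "list",
                 nDistractors = "integer", distractorContrast = "numeric",
                 noiseSd = "numeric", illuminationGradient = "logical",
                 seed = "integer"),
  validity = function(object) {
    ints <- c(object@torsoIntensity, object@backgroundIntensity)
    if (any(ints < 0) || any(ints > 255)) return("intensities must lie in [0, 255]")
    if (object@contourContrast < 0) return("contourContrast must be nonnegative")
    if (object@height < 32L || object@width < 32L)
      return("scenes smaller than 32x32 are not supported")
    if (length(object@arcParams) != 2L) return("arcParams must describe two breasts")
    if (object@nDistractors < 0L) return("nDistractors must be nonnegative")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    TRUE
  })

#' A rendered synthetic scene with ground truth
#'
#' @slot image numeric H x W matrix in \[0, 255\].
#' @slot annotations list of two [ContourAnnotation-class] (left, right).
#' @slot gtChains list of two [PixelPath-class]: the rasterized true
#'   contour arcs.
#' @slot spec the [SceneSpec-class] the scene was rendered from.
#' @seealso [generateScene()]
#' @export
setClass("SceneSample",
  representation(image = "matrix", annotations = "list",
                 gtChains = "list", spec = "SceneSpec"))

#' Contour-error evaluation result
#'
#' Per-contour normalized errors (percent of the image diagonal) and their
#' summary for one operator on one set of annotated images.
#'
#' @slot perImageErrors named numeric vector of per-contour errors (%).
#' @slot summary numeric vector with elements `mean`, `sd`, `max` (%).
#' @slot operator operator label.
#' @slot fold fold identifier (`NA` when not part of a k-fold run).
#' @seealso [evaluateOperator()], [pathError()]
#' @export
setClass("EvalResult",
  representation(perImageErrors = "numeric", summary = "numeric",
                 operator = "character", fold = "integer"),
  validity = function(object) {
    if (length(object@perImageErrors) > 0 && min(object@perImageErrors) < 0)
      return("errors must be nonnegative")
    if (!all(c("mean", "sd", "max") %in% names(object@summary)))
      return("summary must contain mean, sd and max")
    TRUE
  })

#' Training configuration for the structured path loss
#'
#' @slot epochs number of passes over the training samples.
#' @slot learningRate Adam step size.
#' @slot batchSize samples per optimizer step (the structured loss runs one
#'   Dijkstra per sample; gradients are averaged over the batch).
#' @slot seed RNG seed controlling initial sample order shuffling.
#' @slot resizeLongSide images whose long side exceeds this are downscaled
#'   (annotations rescaled accordingly) before training.
#' @slot weightParams [EdgeWeightParams-class] used inside the loss.
#' @slot priorStrength shape-prior strength inside the loss's shortest-path
#'   computation (0 disables the prior during training).
#' @slot checkpointInterval epochs between checkpoint saves (0 = only at
#'   the end).
#' @slot patience consecutive all-zero-loss epochs before early stop.
#' @slot gradClip global L2 norm the per-step parameter gradient is clipped
#'   to (the hinge gradient scales with the exponential arc weights and can
#'   be several orders of magnitude larger than typical losses; clipping
#'   keeps the first optimizer steps from saturating the output sigmoid).
#' @slot weightDecay decoupled L2 weight decay added to each update.
#' @seealso [trainConfig()], [trainSobelUNet()]
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", learningRate = "numeric",
                 batchSize = "integer", seed = "integer",
                 resizeLongSide = "integer", weightParams = "EdgeWeightParams",
                 priorStrength = "numeric", checkpointInterval = "integer",
                 patience = "integer", gradClip = "numeric",
                 weightDecay = "numeric"),
  validity = function(object) {
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@patience < 1L) return("patience must be >= 1")
    TRUE
  })
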