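# Contour-error metric and the fold-based comparison harness.  Errors are
# pixel distances between predicted and ground-truth chains standardized by
# the image diagonal and reported as percentages.

#' Normalized contour error between two pixel chains
#'
#' Symmetric mean nearest-neighbour distance: the average over predicted
#' nodes of the distance to the nearest ground-truth node, averaged with
#' the reverse direction, divided by the image diagonal
#' \eqn{\sqrt{H^2+W^2}} and multiplied by 100.  `"hausdorff"` instead takes
#' the larger of the two directed maximum distances.
#'
#' @param pred,gt [PixelPath-class] objects (or n x 2 node matrices) in the
#'   same image frame.
#' @param imageShape `c(H, W)`.
#' @param metric `"mean_sym"` (default) or `"hausdorff"`.
#' @return nonnegative error in percent of the image diagonal.
#' @examples
#' a <- cbind(5, 1:20); b <- cbind(8, 1:20)
#' pathError(a, b, c(100, 100))  # 100 * 3 / sqrt(2e4)
#' @export
pathError <- function(pred, gt, imageShape,
                      metric = c("mean_sym", "hausdorff")) {
  metric <- match.arg(metric)
  p <- .nodes(pred); g <- .nodes(gt)
  if (nrow(p) == 0L || nrow(g) == 0L) stop("paths must be nonempty")
  d2 <- outer(p[, 1], g[, 1], "-")^2 + outer(p[, 2], g[, 2], "-")^2
  dPG <- sqrt(apply(d2, 1, min))
  dGP <- sqrt(apply(d2, 2, min))
  v <- if (metric == "mean_sym") (mean(dPG) + mean(dGP)) / 2
       else max(max(dPG), max(dGP))
  100 * v / sqrt(sum(imageShape[1:2]^2))
}

#' Deterministic k-fold split
#'
#' Disjoint, exhaustive test folds with sizes differing by at most one,
#' deterministic given the seed.
#'
#' @param n number of items (>= k).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` elements, each `list(train = , test = )` of indices.
#' @examples
#' sizes <- vapply(kfoldSplit(221, 5, 1), function(f) length(f$test), 1L)
#' sort(sizes, decreasing = TRUE)  # 45 44 44 44 44
#' @export
kfoldSplit <- function(n, k, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed n")
  idx <- .withSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- sort(idx[starts[i]:ends[i]])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

# Resolve an operator name (+ optional model) to a function image -> EdgeMap.
#' @noRd
.operatorFun <- function(operator, model = NULL, canny = list()) {
  switch(operator,
    sobel = sobelMagnitude,
    prewitt = prewittMagnitude,
    canny = function(img) do.call(cannyEdges, c(list(img), canny)),
    learned = {
      if (is.null(model)) stop("operator 'learned' requires a model")
      function(img) predictEdgeMap(model, img)
    },
    stop("unknown operator: ", operator))
}

#' Evaluate an edge operator on an annotated dataset
#'
#' For every annotated contour: compute the operator's edge map, extract
#' the shortest-path contour between the annotated endpoints, and score it
#' against the ground-truth chain with [pathError()].  Ground truth is the
#' true polyline stored with the annotation when present, otherwise the
#' keypoint-derived [groundTruthPath()] over the Sobel map.  Left and right
#' contours are scored as separate items.
#'
#' @param manifest path to a `manifest.json` written by
#'   [generateDataset()] (or the already-parsed manifest list with a
#'   `dir` attribute).
#' @param operator `"sobel"`, `"prewitt"`, `"canny"` or `"learned"`.
#' @param model a [SobelUNet-class] (required for `"learned"`).
#' @param params an [EdgeWeightParams-class].
#' @param priorStrength,priorBandWidth shape-prior settings (0 disables).
#' @param canny list of arguments forwarded to [cannyEdges()].
#' @param indices subset of manifest entries to evaluate (default all).
#' @param metric forwarded to [pathError()].
#' @param fold fold identifier stored in the result.
#' @return An [EvalResult-class].
#' @export
evaluateOperator <- function(manifest, operator = "sobel", model = NULL,
                             params = edgeWeightParams(),
                             priorStrength = 0, priorBandWidth = 10,
                             canny = list(), indices = NULL,
                             metric = "mean_sym", fold = NA_integer_) {
  mf <- .loadManifest(manifest)
  op <- .operatorFun(operator, model, canny)
  entries <- mf$entries
  if (!is.null(indices)) entries <- entries[indices]
  errs <- numeric(0)
  for (e in entries) {
    imgPath <- file.path(mf$dir, e$image)
    if (!file.exists(imgPath)) stop("missing image file: ", e$image)
    img <- readImageGray(imgPath)
    em <- op(img)
    for (annFile in unlist(e$annotations)) {
      ann <- readAnnotation(file.path(mf$dir, annFile))
      gt <- attr(ann, "gtPolyline")
      if (is.null(gt))
        gt <- groundTruthPath(sobelMagnitude(img), ann, params)@nodes
      prior <- if (priorStrength > 0)
        shapePriorMask(ann@start, ann@end, priorStrength, priorBandWidth,
                       dim(img)) else NULL
      pred <- shortestPath(em, ann@start, ann@end, params, prior)
      errs[paste0(e$image, ":", ann@side)] <-
        pathError(pred, gt, dim(img), metric)
    }
  }
  .evalResult(errs, operator, fold)
}

#' @noRd
.evalResult <- function(errs, operator, fold = NA_integer_) {
  new("EvalResult", perImageErrors = errs,
      summary = c(mean = mean(errs), sd = stats::sd(errs), max = max(errs)),
      operator = operator, fold = as.integer(fold))
}

#' @noRd
.loadManifest <- function(manifest) {
  if (is.character(manifest)) {
    mf <- jsonlite::read_json(manifest)
    mf$dir <- dirname(manifest)
    mf
  } else {
    if (is.null(manifest$dir)) stop("parsed manifest needs a 'dir' element")
    manifest
  }
}

#' Compare operators on one dataset (benchmark table)
#'
#' Runs [evaluateOperator()] for each requested operator on the same
#' entries and returns a summary table with one row per operator (mean, sd
#' and max normalized error, %).
#'
#' @inheritParams evaluateOperator
#' @param operators character vector of operator names.
#' @param models named list of [SobelUNet-class] models for `"learned"`
#'   entries.
#' @return `data.frame` with columns operator, mean, sd, max, n.
#' @export
benchOperators <- function(manifest, operators = c("sobel", "prewitt", "canny"),
                           models = list(), params = edgeWeightParams(),
                           indices = NULL, metric = "mean_sym") {
  rows <- lapply(operators, function(opn) {
    res <- evaluateOperator(manifest, opn, model = models[[opn]],
                            params = params, indices = indices,
                            metric = metric)
    s <- res@summary
    data.frame(operator = opn, mean = s[["mean"]], sd = s[["sd"]],
               max = s[["max"]], n = length(res@perImageErrors))
  })
  do.call(rbind, rows)
}
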