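# Classical edge operators.  All operators return EdgeMap objects on the
# 0-255 scale expected by the graph stage; convolutions use reflect padding
# so image borders do not produce spurious strong edges that would attract
# shortest paths.

.SOBEL_X <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dcol
.PREWITT_X <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)

#' Convert an image to grayscale
#'
#' RGB channels are combined with the standard luminance weights
#' (0.299, 0.587, 0.114); grayscale input is returned unchanged.
#'
#' @param img H x W numeric matrix or H x W x 3 array, intensities in
#'   \[0, 255\].
#' @return H x W numeric matrix.
#' @examples
#' rgb <- array(100, c(4, 4, 3))
#' all(toGrayscale(rgb) == 100)
#' @export
toGrayscale <- function(img) {
  img <- .checkImage(img)
  if (length(dim(img)) == 2L) return(img)
  if (dim(img)[3] == 1L) return(img[, , 1])
  if (dim(img)[3] != 3L) stop("expected 1 or 3 channels")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Rescale a raw gradient grid to a 0-255 edge map
#'
#' Linear rescaling so the per-image maximum maps to 255 (an all-zero grid
#' stays all-zero).  Per-image normalization makes the arc-weight decay
#' `beta` comparable across images and across operators.
#'
#' @param raw nonnegative finite numeric matrix.
#' @param provenance operator label stored in the result.
#' @return An [EdgeMap-class].
#' @export
normalizeEdgeMap <- function(raw, provenance = "unknown") {
  if (!is.matrix(raw) || !is.numeric(raw)) stop("'raw' must be a numeric matrix")
  if (!all(is.finite(raw))) stop("'raw' contains non-finite values")
  if (min(raw) < 0) stop("'raw' contains negative values")
  m <- max(raw)
  if (m > 0) raw <- pmin(raw * (255 / m), 255)  # guard rounding overshoot
  edgeMap(raw, provenance)
}

.gradientMagnitude <- function(img, kx, label) {
  img <- toGrayscale(img)
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3x3 for a 3x3 operator")
  gx <- .cg_filter2_reflect(img, kx)
  gy <- .cg_filter2_reflect(img, t(kx))
  normalizeEdgeMap(sqrt(gx^2 + gy^2), label)
}

#' Sobel gradient magnitude
#'
#' Euclidean magnitude of the two 3x3 Sobel responses, reflect-padded and
#' rescaled to \[0, 255\] by [normalizeEdgeMap()].  This is the
#' conventional operator of the original shortest-path contour method and
#' the fixed skip pathway of the [SobelUNet-class].
#'
#' @inheritParams toGrayscale
#' @return An [EdgeMap-class] with provenance `"sobel"`.
#' @examples
#' step <- cbind(matrix(0, 8, 4), matrix(255, 8, 4))
#' sobelMagnitude(step)
#' @export
sobelMagnitude <- function(img) .gradientMagnitude(img, .SOBEL_X, "sobel")

#' Prewitt gradient magnitude
#'
#' @inheritParams toGrayscale
#' @return An [EdgeMap-class] with provenance `"prewitt"`.
#' @export
prewittMagnitude <- function(img) .gradientMagnitude(img, .PREWITT_X, "prewitt")

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding.  The binary
#' decision is scaled to \{0, 255\} so the exponential arc weights apply
#' uniformly across operators.  Thresholds refer to the gradient magnitude
#' after per-image rescaling to \[0, 255\].
#'
#' @inheritParams toGrayscale
#' @param low,high hysteresis thresholds, `0 <= low <= high`.
#' @param sigma Gaussian smoothing scale in pixels.
#' @return An [EdgeMap-class] with provenance `"canny"`, values in
#'   \{0, 255\}.
#' @export
cannyEdges <- function(img, low = 40, high = 90, sigma = 1.4) {
  if (low < 0 || low > high) stop("need 0 <= low <= high")
  if (sigma <= 0) stop("sigma must be positive")
  img <- toGrayscale(img)
  if (nrow(img) < 3L || ncol(img) < 3L) stop("image must be at least 3x3")

  r <- max(1L, ceiling(3 * sigma))
  r <- min(r, nrow(img) - 1L, ncol(img) - 1L)
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  sm <- .cg_filter2_reflect(img, matrix(g1, ncol = 1))
  sm <- .cg_filter2_reflect(sm, matrix(g1, nrow = 1))

  gx <- .cg_filter2_reflect(sm, .SOBEL_X)
  gy <- .cg_filter2_reflect(sm, t(.SOBEL_X))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx > 0) mag <- mag * (255 / mx)

  # Non-maximum suppression with the gradient direction quantized to the
  # four principal orientations.
  H <- nrow(mag); W <- ncol(mag)
  ang <- atan2(gy, gx)  # gy = d/drow
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: col-grad, 1: diag, 2: row-grad, 3: anti-diag
  dr <- c(0, 1, 1, 1)[sector + 1]
  dc <- c(1, 1, 0, -1)[sector + 1]
  rows <- row(mag); cols <- col(mag)
  at <- function(rr, cc) {
    v <- matrix(0, H, W)
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    v[ok] <- mag[cbind(rr[ok], cc[ok])]
    v
  }
  n1 <- at(rows + dr, cols + dc)
  n2 <- at(rows - dr, cols - dc)
  # strict on the forward neighbour so a symmetric two-pixel ridge thins to
  # one pixel
  nms <- ifelse(mag > n1 & mag >= n2, mag, 0)

  keep <- .cg_hysteresis(nms, low, high)
  edgeMap(ifelse(keep, 255, 0), "canny")
}

#' Weighted linear combination of edge maps
#'
#' Combines multiple edge channels (e.g. outputs of different operators or
#' of a multi-head edge model) into one map: elementwise weighted sum,
#' clipped at 0 and renormalized to \[0, 255\].
#'
#' @param maps list of [EdgeMap-class] objects (or magnitude matrices) of
#'   identical shape.
#' @param weights numeric vector, one weight per map.
#' @return An [EdgeMap-class] with provenance `"combined"`.
#' @export
combineChannels <- function(maps, weights) {
  if (length(maps) == 0L) stop("'maps' is empty")
  if (length(weights) != length(maps))
    stop("'weights' must have one entry per map")
  ms <- lapply(maps, .mags)
  d <- dim(ms[[1]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), logical(1))))
    stop("all maps must have the same shape")
  acc <- matrix(0, d[1], d[2])
  for (i in seq_along(ms)) acc <- acc + weights[i] * ms[[i]]
  normalizeEdgeMap(pmax(acc, 0), "combined")
}
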