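# Weighted pixel-graph contour search.  An edge map induces an implicit
# 8-connected graph whose arc weights decay exponentially with edge
# strength: f(g) = alpha * exp(beta * (255 - g)) + gamma, with g the mean
# magnitude of the two incident pixels and diagonal arcs scaled by
# diagonalFactor.  Contours are minimum-cost paths between endpoints.

#' Arc weight between two adjacent pixels
#'
#' Computes \eqn{f(g) = \alpha e^{\beta(255-g)} + \gamma} with
#' \eqn{g = (g_i + g_j)/2}; diagonal adjacency multiplies the result by
#' `diagonalFactor`.  Vectorized over `gi`/`gj`.
#'
#' @param gi,gj edge magnitudes of the two incident pixels, in \[0, 255\].
#' @param adjacency `"straight"` (horizontal/vertical) or `"diagonal"`.
#' @param params an [EdgeWeightParams-class].
#' @return positive arc weight(s).
#' @examples
#' p <- edgeWeightParams(alpha = 1, beta = 0.01, gamma = 0)
#' arcWeight(255, 255, "straight", p)       # exp(0) = 1
#' arcWeight(255, 0, "straight", p)         # exp(0.01 * 127.5)
#' @export
arcWeight <- function(gi, gj, adjacency = c("straight", "diagonal"),
                      params = edgeWeightParams()) {
  adjacency <- match.arg(adjacency)
  if (any(!is.finite(gi)) || any(!is.finite(gj)) ||
      any(gi < 0 | gi > 255) || any(gj < 0 | gj > 255))
    stop("magnitudes must lie in [0, 255]")
  g <- (gi + gj) / 2
  w <- params@alpha * exp(params@beta * (255 - g)) + params@gamma
  if (adjacency == "diagonal") w <- w * params@diagonalFactor
  w
}

#' Minimum-cost contour between two endpoints
#'
#' Runs Dijkstra's algorithm on the implicit weighted pixel graph of an
#' edge map.  Arc weights follow [arcWeight()]; when a prior mask is given
#' each arc is additionally multiplied by the mean of the mask values at
#' its two incident pixels.  Ties are broken deterministically (priority by
#' cost, then row-major pixel index; predecessors updated only on strict
#' improvement), so identical inputs always yield the identical node
#' sequence.
#'
#' @param edgeMap an [EdgeMap-class] or magnitude matrix.
#' @param start,end (row, col) positions, 1-based.
#' @param params an [EdgeWeightParams-class].
#' @param prior optional [PriorMask-class] (or multiplier matrix >= 1).
#' @return A [PixelPath-class]; `start == end` yields a single-node path of
#'   cost 0.
#' @examples
#' em <- edgeMap(matrix(255, 6, 6), "sobel")
#' shortestPath(em, c(1, 1), c(1, 6))  # straight run along the row
#' @export
shortestPath <- function(edgeMap, start, end, params = edgeWeightParams(),
                         prior = NULL) {
  m <- .mags(edgeMap)
  start <- .checkPoint(start, dim(m), "start")
  end <- .checkPoint(end, dim(m), "end")
  pm <- if (is.null(prior)) NULL else .priorWeights(prior, dim(m))
  res <- .cg_dijkstra(m, start, end, params@alpha, params@beta,
                      params@gamma, params@diagonalFactor, pm)
  pixelPath(res$nodes, res$cost)
}

#' @noRd
.priorWeights <- function(prior, shape) {
  w <- if (is(prior, "PriorMask")) prior@weights else prior
  if (!is.matrix(w) || !identical(dim(w), as.integer(shape)))
    stop("prior mask shape must match the edge map")
  w
}

#' Cost of a pixel chain under an edge map
#'
#' Sums [arcWeight()] over consecutive node pairs (with the prior applied
#' as in [shortestPath()]).  A single-node path costs 0.
#'
#' @inheritParams shortestPath
#' @param nodes a [PixelPath-class] or n x 2 (row, col) matrix forming a
#'   valid 8-connected chain.
#' @return nonnegative path cost.
#' @export
pathCost <- function(edgeMap, nodes, params = edgeWeightParams(),
                     prior = NULL) {
  m <- .mags(edgeMap)
  n <- .nodes(nodes)
  if (min(n) < 1L || max(n[, 1]) > nrow(m) || max(n[, 2]) > ncol(m))
    stop("path leaves the image")
  if (nrow(n) == 1L) return(0)
  d <- abs(diff(n))
  if (any(pmax(d[, 1], d[, 2]) != 1L))
    stop("consecutive path nodes must be 8-adjacent and distinct")
  i <- n[-nrow(n), , drop = FALSE]
  j <- n[-1, , drop = FALSE]
  gi <- m[i]; gj <- m[j]
  g <- (gi + gj) / 2
  w <- params@alpha * exp(params@beta * (255 - g)) + params@gamma
  diag <- d[, 1] == 1L & d[, 2] == 1L
  w[diag] <- w[diag] * params@diagonalFactor
  if (!is.null(prior)) {
    pw <- .priorWeights(prior, dim(m))
    w <- w * (pw[i] + pw[j]) / 2
  }
  sum(w)
}

#' Ground-truth contour through annotated keypoints
#'
#' Chains [shortestPath()] segments start -> k1 -> ... -> kn -> end and
#' concatenates them with duplicated junction nodes removed.  This mirrors
#' the annotation procedure in which a weak annotation (endpoints plus a
#' few keypoints) is expanded into a full pixel chain over the Sobel map.
#' If consecutive segments overlap, the transient loop is erased so the
#' result remains a simple chain.  With zero keypoints this reduces to
#' `shortestPath(start, end)`.
#'
#' @inheritParams shortestPath
#' @param annotation a [ContourAnnotation-class].
#' @return A [PixelPath-class] passing through every keypoint.
#' @export
groundTruthPath <- function(edgeMap, annotation, params = edgeWeightParams(),
                            prior = NULL) {
  m <- .mags(edgeMap)
  stopifnot(is(annotation, "ContourAnnotation"))
  kp <- annotation@keypoints
  if (nrow(kp) > 0 && (min(kp) < 1L || max(kp[, 1]) > nrow(m) ||
                       max(kp[, 2]) > ncol(m)))
    stop("keypoint outside image bounds")
  pts <- rbind(annotation@start, kp, annotation@end)
  nodes <- NULL
  for (i in seq_len(nrow(pts) - 1L)) {
    seg <- shortestPath(edgeMap, pts[i, ], pts[i + 1L, ], params, prior)
    sn <- seg@nodes
    nodes <- if (is.null(nodes)) sn else rbind(nodes, sn[-1, , drop = FALSE])
  }
  nodes <- .eraseLoops(nodes)
  pixelPath(nodes, pathCost(m, nodes, params, prior))
}

# Loop erasure: when a node reappears later in the chain, the intermediate
# cycle is removed.  Keeps concatenated shortest-path segments a simple
# 8-connected chain.
#' @noRd
.eraseLoops <- function(nodes) {
  key <- paste(nodes[, 1], nodes[, 2])
  if (!anyDuplicated(key)) return(nodes)
  keep <- integer(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(nodes))) {
    k <- key[i]
    prev <- seen[[k]]
    if (is.null(prev)) {
      keep <- c(keep, i)
      seen[[k]] <- length(keep)
    } else {
      # cut back to the first visit of this node
      for (j in seq_along(keep)[-seq_len(prev)]) rm(list = key[keep[j]], envir = seen)
      keep <- keep[seq_len(prev)]
    }
  }
  nodes[keep, , drop = FALSE]
}

#' Endpoint-conditioned shape-prior mask
#'
#' Builds per-pixel arc-weight multipliers `1 + strength * (1 - P(x))`
#' where `P(x)` is a Gaussian band (scale `bandWidth`) around a
#' semicircular arc erected on the chord between the two endpoints,
#' bulging toward `bulge`.  Pixels on the arc keep multiplier 1; pixels far
#' from it approach `1 + strength`.  `strength = 0` disables the prior
#' (all-ones mask).
#'
#' @param start,end (row, col) endpoint positions, 1-based.
#' @param strength prior strength (lambda >= 0).
#' @param bandWidth Gaussian falloff scale in pixels (> 0).
#' @param shape image dimensions `c(H, W)`.
#' @param bulge side the semicircle bulges toward: `"down"` (increasing
#'   row; the usual orientation for breast contours in upright frontal
#'   photographs), `"up"`, `"left"` or `"right"`.
#' @return A [PriorMask-class].
#' @export
shapePriorMask <- function(start, end, strength = 1, bandWidth = 10,
                           shape, bulge = c("down", "up", "left", "right")) {
  bulge <- match.arg(bulge)
  if (strength < 0) stop("strength must be nonnegative")
  if (bandWidth <= 0) stop("bandWidth must be positive")
  start <- .checkPoint(start, shape, "start")
  end <- .checkPoint(end, shape, "end")
  H <- shape[1]; W <- shape[2]
  if (strength == 0)
    return(new("PriorMask", weights = matrix(1, H, W)))

  mid <- (start + end) / 2
  chord <- end - start
  R <- sqrt(sum(chord^2)) / 2
  if (R == 0) stop("degenerate chord: start equals end")
  u <- chord / (2 * R)
  nrm <- c(u[2], -u[1])  # perpendicular (row, col)
  bv <- switch(bulge, down = c(1, 0), up = c(-1, 0),
               left = c(0, -1), right = c(0, 1))
  if (sum(nrm * bv) < 0) nrm <- -nrm

  rr <- matrix(seq_len(H), H, W) - mid[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - mid[2]
  s <- rr * nrm[1] + cc * nrm[2]           # signed distance toward bulge
  rad <- sqrt(rr^2 + cc^2)
  dArc <- abs(rad - R)                     # distance to the full circle
  # on the non-bulge side the nearest arc points are the endpoints
  dEnd1 <- sqrt((rr + mid[1] - start[1])^2 + (cc + mid[2] - start[2])^2)
  dEnd2 <- sqrt((rr + mid[1] - end[1])^2 + (cc + mid[2] - end[2])^2)
  d <- ifelse(s >= 0, dArc, pmin(dEnd1, dEnd2))
  P <- exp(-d^2 / (2 * bandWidth^2))
  new("PriorMask", weights = 1 + strength * (1 - P))
}
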