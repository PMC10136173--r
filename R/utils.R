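# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Coerce an Image-like input (numeric matrix or HxWx3 array, 0-255) after
# basic validation.
#' @noRd
.checkImage <- function(img, arg = "img") {
  if (is.null(dim(img)) || !(length(dim(img)) %in% c(2L, 3L)))
    stop(sprintf("'%s' must be an HxW matrix or HxWx3 array", arg))
  if (length(img) == 0L) stop(sprintf("'%s' is empty", arg))
  if (!all(is.finite(img))) stop(sprintf("'%s' contains non-finite values", arg))
  if (min(img) < 0 || max(img) > 255)
    stop(sprintf("'%s' intensities must lie in [0, 255]", arg))
  if (nrow(img) < 2L || ncol(img) < 2L)
    stop(sprintf("'%s' must be at least 2x2", arg))
  img
}

# Accept an EdgeMap or a bare magnitude matrix.
#' @noRd
.mags <- function(edgeMap) {
  if (is(edgeMap, "EdgeMap")) edgeMap@magnitudes
  else if (is.matrix(edgeMap) && is.numeric(edgeMap)) edgeMap
  else stop("expected an EdgeMap or a numeric magnitude matrix")
}

# Accept a PixelPath or a bare n x 2 (row, col) matrix of nodes.
#' @noRd
.nodes <- function(path) {
  if (is(path, "PixelPath")) path@nodes
  else if (is.matrix(path) && ncol(path) == 2L) {
    storage.mode(path) <- "integer"
    path
  } else stop("expected a PixelPath or an n x 2 (row, col) matrix")
}

#' @noRd
.checkPoint <- function(p, shape, arg = "point") {
  p <- as.integer(round(p))
  if (length(p) != 2L || any(!is.finite(p)))
    stop(sprintf("'%s' must be a (row, col) pair", arg))
  if (p[1] < 1L || p[1] > shape[1] || p[2] < 1L || p[2] > shape[2])
    stop(sprintf("'%s' (%d, %d) is outside the %d x %d image",
                 arg, p[1], p[2], shape[1], shape[2]))
  p
}
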