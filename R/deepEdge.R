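# Sobel-skip U-Net edge detector.  The forward and backward passes are
# implemented on dense conv primitives (src/conv_ops.cpp); there is no
# external deep-learning runtime.  The Sobel pathway is fixed (non-learned):
# the input's Sobel magnitude is computed once at full resolution and
# average-pooled to each decoder scale, where it is concatenated with the
# decoded features; a final 1x1 convolution + sigmoid yields one edge
# channel.

# Channel arithmetic shared by the builder, the forward/backward passes and
# the parameter-count oracle tests.
#' @noRd
.unetChannels <- function(base, depth, inCh) {
  encOut <- base * 2L^(seq_len(depth) - 1L)
  encIn <- c(inCh, encOut[-depth])
  cb <- encOut[depth]
  convOut <- cb %/% 2L^seq_len(depth)
  tOut <- pmax(cb %/% 2L^(seq_len(depth) + 1L), base %/% 2L)
  convIn <- c(cb, tOut[-depth]) + 1L  # +1: Sobel pyramid channel
  list(encIn = encIn, encOut = encOut, bottleneck = cb,
       decIn = convIn, decOut = convOut, tOut = tOut,
       finalIn = tOut[depth] + 1L)
}

#' Build a Sobel-skip U-Net
#'
#' Constructs the model with deterministic He-style initialization given
#' the seed.  The default configuration (`baseFeatures = 32`,
#' `depth = 4`) reaches a 256-feature bottleneck and a parameter count just
#' over 1.7 million.
#'
#' @param baseFeatures channels of the first encoder block (even, >= 2).
#' @param depth number of encoder blocks / decoder iterations.
#' @param inChannels 1 (grayscale input) or 3 (RGB).
#' @param kernelSize convolution kernel size (odd; default 3).
#' @param seed integer seed for the initial parameters.
#' @return A [SobelUNet-class] in `"eval"` mode.
#' @examples
#' m <- sobelUNet(baseFeatures = 4, depth = 2, seed = 1)
#' sobelUNetParamCount(m)
#' @export
sobelUNet <- function(baseFeatures = 32, depth = 4, inChannels = 1,
                      kernelSize = 3, seed = 1) {
  depth <- as.integer(depth); baseFeatures <- as.integer(baseFeatures)
  inChannels <- as.integer(inChannels); kernelSize <- as.integer(kernelSize)
  ch <- .unetChannels(baseFeatures, depth, inChannels)
  K <- kernelSize
  .withSeed(as.integer(seed), {
    he <- function(cout, cin, k) {
      matrix(stats::rnorm(cout * cin * k * k, 0, sqrt(2 / (cin * k * k))),
             cout, cin * k * k)
    }
    heT <- function(cin, cout) {
      stats::rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin)))
    }
    enc <- lapply(seq_len(depth), function(d) list(
      w1 = he(ch$encOut[d], ch$encIn[d], K), b1 = numeric(ch$encOut[d]),
      w2 = he(ch$encOut[d], ch$encOut[d], K), b2 = numeric(ch$encOut[d])))
    dec <- lapply(seq_len(depth), function(k) list(
      w1 = he(ch$decOut[k], ch$decIn[k], K), b1 = numeric(ch$decOut[k]),
      w2 = he(ch$decOut[k], ch$decOut[k], K), b2 = numeric(ch$decOut[k]),
      tw = heT(ch$decOut[k], ch$tOut[k]), tb = numeric(ch$tOut[k])))
    final <- list(w = he(1L, ch$finalIn, 1L), b = numeric(1))
    # Warm start: the last input channel of the final 1x1 convolution is
    # the full-resolution Sobel pyramid level.  Initializing its weight and
    # the bias so the output starts as a calibrated sigmoid squashing of
    # the Sobel magnitude makes the untrained model behave like the
    # conventional operator; training then only has to learn corrections
    # where the Sobel-driven shortest path fails.
    final$w[ch$finalIn] <- 6
    final$b <- -2.5
    new("SobelUNet", depth = depth, baseFeatures = baseFeatures,
        inChannels = inChannels, kernelSize = kernelSize,
        weights = list(enc = enc, dec = dec, final = final),
        seed = as.integer(seed), mode = "eval")
  })
}

#' Number of trainable parameters
#'
#' @param model a [SobelUNet-class].
#' @return integer parameter count (a pure function of the architecture
#'   configuration).
#' @export
sobelUNetParamCount <- function(model) {
  sum(rapply(model@weights, length, how = "unlist"))
}

# Pad an H x W x C cube to spatial multiples of 2^depth by edge replication
# on the bottom/right; returns the cube and the original size.
#' @noRd
.unetPad <- function(x, depth) {
  H <- dim(x)[1]; W <- dim(x)[2]
  m <- 2L^depth
  Hp <- ceiling(H / m) * m; Wp <- ceiling(W / m) * m
  if (Hp != H) x <- x[c(seq_len(H), rep(H, Hp - H)), , , drop = FALSE]
  if (Wp != W) x <- x[, c(seq_len(W), rep(W, Wp - W)), , drop = FALSE]
  x
}

#' @noRd
.cat3 <- function(x, m) {
  array(c(x, m), dim = c(dim(x)[1], dim(x)[2], dim(x)[3] + 1L))
}

# Forward pass.  img: 0-255 matrix/array matching model@inChannels.
# Returns list(out = HxW matrix in (0,1), cache = layer caches or NULL,
# origShape).
#' @noRd
.unetForward <- function(model, img, cache = FALSE) {
  depth <- model@depth; K <- model@kernelSize
  nch <- if (length(dim(img)) == 2L) 1L else dim(img)[3]
  if (nch != model@inChannels)
    stop(sprintf("input has %d channel(s) but the model expects %d",
                 nch, model@inChannels))
  H0 <- dim(img)[1]; W0 <- dim(img)[2]
  minSide <- 2L^depth
  if (min(H0, W0) < minSide)
    stop(sprintf("input too small for depth %d: minimum size is %dx%d",
                 depth, minSide, minSide))
  x <- array(img / 255, dim = c(H0, W0, model@inChannels))
  sob <- edgeMagnitudes(sobelMagnitude(toGrayscale(img))) / 255
  x <- .unetPad(x, depth)
  sob <- .unetPad(array(sob, dim = c(H0, W0, 1L)), depth)[, , 1]

  # Sobel pyramid: element l+1 holds the map pooled l times
  pyr <- vector("list", depth + 1L)
  pyr[[1]] <- sob
  for (l in seq_len(depth)) pyr[[l + 1L]] <- .cg_avgpool2(pyr[[l]])

  cc <- if (cache) list(encIn = list(), decIn = list(), tconvIn = list(),
                        relu = list(), poolIdx = list()) else NULL
  relu <- function(a, tag) {
    a[a < 0] <- 0
    if (cache) cc$relu[[tag]] <<- a > 0
    a
  }
  wts <- model@weights
  for (d in seq_len(depth)) {
    if (cache) cc$encIn[[paste0(d, "_1")]] <- x
    x <- relu(.cg_conv2d_fwd(x, wts$enc[[d]]$w1, wts$enc[[d]]$b1, K),
              paste0("e", d, "_1"))
    if (cache) cc$encIn[[paste0(d, "_2")]] <- x
    x <- relu(.cg_conv2d_fwd(x, wts$enc[[d]]$w2, wts$enc[[d]]$b2, K),
              paste0("e", d, "_2"))
    mp <- .cg_maxpool_fwd(x)
    if (cache) cc$poolIdx[[d]] <- mp$idx
    x <- mp$y
  }
  for (k in seq_len(depth)) {
    lvl <- depth - k + 2L  # pyramid level at the current resolution
    x <- .cat3(x, pyr[[lvl]])
    if (cache) cc$decIn[[paste0(k, "_1")]] <- x
    x <- relu(.cg_conv2d_fwd(x, wts$dec[[k]]$w1, wts$dec[[k]]$b1, K),
              paste0("d", k, "_1"))
    if (cache) cc$decIn[[paste0(k, "_2")]] <- x
    x <- relu(.cg_conv2d_fwd(x, wts$dec[[k]]$w2, wts$dec[[k]]$b2, K),
              paste0("d", k, "_2"))
    if (cache) cc$tconvIn[[k]] <- x
    x <- .cg_tconv_fwd(x, wts$dec[[k]]$tw, wts$dec[[k]]$tb)
  }
  x <- .cat3(x, pyr[[1]])
  if (cache) cc$finalIn <- x
  z <- .cg_conv2d_fwd(x, wts$final$w, wts$final$b, 1L)[, , 1]
  out <- 1 / (1 + exp(-z))
  if (cache) cc$out <- out
  list(out = out, cache = cc, origShape = c(H0, W0))
}

# Backward pass: dOut is the gradient wrt the padded sigmoid output.
# Returns gradients in the same structure as model@weights.
#' @noRd
.unetBackward <- function(model, cc, dOut) {
  depth <- model@depth; K <- model@kernelSize
  wts <- model@weights
  g <- list(enc = vector("list", depth), dec = vector("list", depth),
            final = NULL)
  dz <- dOut * cc$out * (1 - cc$out)
  dz <- array(dz, dim = c(dim(dz)[1], dim(dz)[2], 1L))
  bw <- .cg_conv2d_bwd(cc$finalIn, wts$final$w, dz, 1L)
  g$final <- list(w = bw$dw, b = bw$db)
  dx <- bw$dx[, , -dim(bw$dx)[3], drop = FALSE]  # drop Sobel channel grad
  for (k in rev(seq_len(depth))) {
    tb <- .cg_tconv_bwd(cc$tconvIn[[k]], wts$dec[[k]]$tw, dx)
    dk <- list(tw = tb$dw, tb = tb$db)
    dx <- tb$dx
    dx <- dx * cc$relu[[paste0("d", k, "_2")]]
    bw <- .cg_conv2d_bwd(cc$decIn[[paste0(k, "_2")]], wts$dec[[k]]$w2, dx, K)
    dk$w2 <- bw$dw; dk$b2 <- bw$db
    dx <- bw$dx * cc$relu[[paste0("d", k, "_1")]]
    bw <- .cg_conv2d_bwd(cc$decIn[[paste0(k, "_1")]], wts$dec[[k]]$w1, dx, K)
    dk$w1 <- bw$dw; dk$b1 <- bw$db
    g$dec[[k]] <- dk
    dx <- bw$dx[, , -dim(bw$dx)[3], drop = FALSE]
  }
  for (d in rev(seq_len(depth))) {
    dx <- .cg_maxpool_bwd(dx, cc$poolIdx[[d]])
    dx <- dx * cc$relu[[paste0("e", d, "_2")]]
    bw <- .cg_conv2d_bwd(cc$encIn[[paste0(d, "_2")]], wts$enc[[d]]$w2, dx, K)
    gd <- list(w2 = bw$dw, b2 = bw$db)
    dx <- bw$dx * cc$relu[[paste0("e", d, "_1")]]
    bw <- .cg_conv2d_bwd(cc$encIn[[paste0(d, "_1")]], wts$enc[[d]]$w1, dx, K)
    gd$w1 <- bw$dw; gd$b1 <- bw$db
    g$enc[[d]] <- gd
    dx <- bw$dx
  }
  g
}

#' Predict an edge map with a Sobel-skip U-Net
#'
#' Deterministic for fixed parameters: the sigmoid output in (0, 1) is
#' scaled by 255.  Inputs whose sides are not multiples of `2^depth` are
#' padded internally and cropped back.
#'
#' @param model a [SobelUNet-class].
#' @param img image matrix/array on the 0-255 scale with the channel count
#'   the model was built for.
#' @return An [EdgeMap-class] with provenance `"learned"` and the same
#'   H x W as the input.
#' @export
predictEdgeMap <- function(model, img) {
  img <- .checkImage(img)
  fw <- .unetForward(model, img, cache = FALSE)
  out <- fw$out[seq_len(fw$origShape[1]), seq_len(fw$origShape[2])]
  edgeMap(255 * out, "learned")
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the architecture configuration, the build seed and the
#' parameter blob.
#'
#' @param model a [SobelUNet-class].
#' @param path checkpoint file path.
#' @return `loadSobelUNet` returns the restored [SobelUNet-class].
#' @export
saveSobelUNet <- function(model, path) {
  saveRDS(list(depth = model@depth, baseFeatures = model@baseFeatures,
               inChannels = model@inChannels, kernelSize = model@kernelSize,
               seed = model@seed, weights = model@weights), path)
  invisible(path)
}

#' @rdname saveSobelUNet
#' @export
loadSobelUNet <- function(path) {
  x <- readRDS(path)
  new("SobelUNet", depth = x$depth, baseFeatures = x$baseFeatures,
      inChannels = x$inChannels, kernelSize = x$kernelSize,
      weights = x$weights, seed = x$seed, mode = "eval")
}
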