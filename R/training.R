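# Structured path loss and training loop.  The loss penalises edge maps
# under which the annotated ground-truth chain is costlier than the current
# shortest path between the same endpoints:
#   L = ReLU( cost(gt) - cost(pp) ).
# Dijkstra is not differentiable; the shortest path is computed on a
# detached copy of the map and treated as constant, and the gradient flows
# only through the two path-cost sums (structured-hinge subgradient).  The
# gradient wrt the edge map is therefore sparse: only pixels on the two
# paths receive signal (+ on the ground truth, - on the prediction; shared
# pixels cancel).

#' Construct a training configuration
#'
#' @param epochs passes over the training set (default 12).
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize samples per optimizer step (default 1; the structured
#'   loss runs one Dijkstra per sample).
#' @param seed RNG seed for sample-order shuffling.
#' @param resizeLongSide images with a longer side are downscaled to this
#'   before training (default 512); annotations are rescaled with the same
#'   factor.
#' @param weightParams [EdgeWeightParams-class] used in both path costs.
#' @param priorStrength shape-prior strength inside the training-time
#'   shortest path (default 0: prior off during training).
#' @param checkpointInterval epochs between checkpoint writes when an
#'   output directory is given (0 = final only).
#' @param patience consecutive zero-loss epochs before early stop.
#' @param gradClip global L2 norm the per-step gradient is clipped to; the
#'   hinge gradient inherits the scale of the exponential arc weights, so
#'   unclipped first steps can saturate the output sigmoid.
#' @param weightDecay decoupled L2 weight decay per update.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 12, learningRate = 1e-3, batchSize = 1,
                        seed = 1, resizeLongSide = 512,
                        weightParams = edgeWeightParams(),
                        priorStrength = 0, checkpointInterval = 0,
                        patience = 3, gradClip = 1, weightDecay = 1e-4) {
  new("TrainConfig", epochs = as.integer(epochs),
      learningRate = learningRate, batchSize = as.integer(batchSize),
      seed = as.integer(seed), resizeLongSide = as.integer(resizeLongSide),
      weightParams = weightParams, priorStrength = priorStrength,
      checkpointInterval = as.integer(checkpointInterval),
      patience = as.integer(patience), gradClip = gradClip,
      weightDecay = weightDecay)
}

#' Structured shortest-path hinge loss
#'
#' `ReLU(pathCost(gtPath) - pathCost(predPath))` under the given edge map
#' and arc-weight parameters.  Zero exactly when the ground-truth chain is
#' no costlier than the predicted shortest path (in particular when the two
#' node sequences coincide).
#'
#' @inheritParams pathCost
#' @param gtPath ground-truth chain ([PixelPath-class] or node matrix).
#' @param predPath current shortest path between the same endpoints.
#' @return nonnegative scalar loss.
#' @export
structuredPathLoss <- function(edgeMap, gtPath, predPath,
                               params = edgeWeightParams(), prior = NULL) {
  g <- .nodes(gtPath); p <- .nodes(predPath)
  if (!all(g[1, ] == p[1, ]) || !all(g[nrow(g), ] == p[nrow(p), ]))
    stop("gtPath and predPath must share both endpoints")
  max(0, pathCost(edgeMap, g, params, prior) -
         pathCost(edgeMap, p, params, prior))
}

# Gradient of the (active) hinge wrt the edge-map magnitudes: for each arc
# with mean magnitude g, d f(g) / d g_i = -alpha * beta / 2 *
# exp(beta * (255 - g)) (times the diagonal factor), accumulated + over
# ground-truth arcs and - over predicted arcs.  Returns the zero matrix
# when the hinge is inactive.
#' @noRd
.pathLossGradient <- function(mag, gtNodes, predNodes, params) {
  dM <- matrix(0, nrow(mag), ncol(mag))
  lossRaw <- pathCost(mag, gtNodes, params) - pathCost(mag, predNodes, params)
  if (lossRaw <= 0) return(dM)
  acc <- function(n, sign) {
    if (nrow(n) < 2L) return()
    i <- n[-nrow(n), , drop = FALSE]
    j <- n[-1, , drop = FALSE]
    g <- (mag[i] + mag[j]) / 2
    dwdg <- -params@alpha * params@beta * exp(params@beta * (255 - g))
    d <- abs(j - i)
    diag <- d[, 1] == 1L & d[, 2] == 1L
    dwdg[diag] <- dwdg[diag] * params@diagonalFactor
    half <- sign * dwdg / 2
    # accumulate with possible repeated pixel indices
    ii <- c((i[, 2] - 1L) * nrow(mag) + i[, 1],
            (j[, 2] - 1L) * nrow(mag) + j[, 1])
    upd <- rowsum(c(half, half), ii)
    dM[as.integer(rownames(upd))] <<- dM[as.integer(rownames(upd))] + upd[, 1]
  }
  acc(gtNodes, +1)
  acc(predNodes, -1)
  dM
}

# One-sided path-cost gradient (d cost / dM for a single chain).
#' @noRd
.sideGradient <- function(mag, nodes, params) {
  dM <- matrix(0, nrow(mag), ncol(mag))
  if (nrow(nodes) < 2L) return(dM)
  i <- nodes[-nrow(nodes), , drop = FALSE]
  j <- nodes[-1, , drop = FALSE]
  g <- (mag[i] + mag[j]) / 2
  dwdg <- -params@alpha * params@beta * exp(params@beta * (255 - g))
  d <- abs(j - i)
  diag <- d[, 1] == 1L & d[, 2] == 1L
  dwdg[diag] <- dwdg[diag] * params@diagonalFactor
  half <- dwdg / 2
  ii <- c((i[, 2] - 1L) * nrow(mag) + i[, 1],
          (j[, 2] - 1L) * nrow(mag) + j[, 1])
  upd <- rowsum(c(half, half), ii)
  dM[as.integer(rownames(upd))] <- upd[, 1]
  dM
}

# Preconditioned update direction for the active hinge.  The raw
# subgradient is dominated by the ground-truth side: the annotated contour
# is longer and runs through darker pixels than the current shortest path,
# and the exponential arc weights make dark-pixel gradients orders of
# magnitude larger.  Following it drives a global brightness increase that
# saturates the output sigmoid into a useless all-edge map.  Normalizing
# the two sides to equal L1 mass removes the net DC push while preserving
# each side's direction, so the optimizer must discriminate contour pixels
# from shortcut pixels rather than brighten everything.
#' @noRd
.hingeUpdateDirection <- function(mag, gtNodes, predNodes, params) {
  gPlus <- .sideGradient(mag, gtNodes, params)
  gMinus <- .sideGradient(mag, predNodes, params)
  gPlus / max(sum(abs(gPlus)), 1e-12) -
    gMinus / max(sum(abs(gMinus)), 1e-12)
}

# One Adam update; state holds first/second moments and the step counter.
#' @noRd
.adamStep <- function(wts, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      if (is.null(m)) {
        m <- vector("list", length(w)); names(m) <- names(w); v <- m
      }
      for (nm in names(w) %||% seq_along(w)) {
        r <- walk(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        w[[nm]] <- r$w; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(w = w, m = m, v = v)
    } else {
      if (is.null(m)) { m <- w * 0; v <- w * 0 }
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      w <- w - lr * (m / corr1) / (sqrt(v / corr2) + eps)
      list(w = w, m = m, v = v)
    }
  }
  r <- walk(wts, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v; state$w <- r$w
  state
}

# Bilinear downscale of a grayscale image to a given long side.
#' @noRd
.resizeToLongSide <- function(img, longSide) {
  H <- nrow(img); W <- ncol(img)
  if (max(H, W) <= longSide) return(list(img = img, scale = 1))
  s <- longSide / max(H, W)
  h <- max(2L, round(H * s)); w <- max(2L, round(W * s))
  rs <- (seq_len(h) - 0.5) / s + 0.5  # target pixel centers in source coords
  cs <- (seq_len(w) - 0.5) / s + 0.5
  r0 <- .clamp(floor(rs), 1, H); r1 <- .clamp(r0 + 1, 1, H)
  c0 <- .clamp(floor(cs), 1, W); c1 <- .clamp(c0 + 1, 1, W)
  fr <- rs - r0; fc <- cs - c0
  a <- img[r0, c0] * outer(1 - fr, 1 - fc) + img[r1, c0] * outer(fr, 1 - fc) +
       img[r0, c1] * outer(1 - fr, fc) + img[r1, c1] * outer(fr, fc)
  list(img = .clamp(a, 0, 255), scale = s)
}

# Prepare one training sample: optional resize, then the fixed ground-truth
# chain expanded once from the annotation keypoints over the *Sobel* map
# (mirroring the annotation procedure; the ground truth never drifts with
# the learned model).
#' @noRd
.prepSample <- function(image, annotation, config) {
  image <- toGrayscale(.checkImage(image))
  rz <- .resizeToLongSide(image, config@resizeLongSide)
  if (rz$scale != 1) {
    sc <- function(p) .checkPoint(pmax(1, round(p * rz$scale)), dim(rz$img))
    kp <- annotation@keypoints
    if (nrow(kp) > 0)
      kp <- t(apply(kp, 1, function(p) sc(p)))
    annotation <- contourAnnotation(sc(annotation@start), sc(annotation@end),
                                    kp, annotation@side)
  }
  img <- rz$img
  gt <- groundTruthPath(sobelMagnitude(img), annotation,
                        config@weightParams)
  list(image = img, annotation = annotation, gt = gt@nodes)
}

#' Train a Sobel-skip U-Net with the structured path loss
#'
#' Per step: forward the image to an edge map, compute the current shortest
#' path between the annotated endpoints on a detached copy (Dijkstra),
#' evaluate `ReLU(cost(gt) - cost(pp))`, and backpropagate through the two
#' path-cost sums only.  The ground-truth chain of each sample is expanded
#' once from its annotation keypoints over the Sobel map and kept fixed.
#' Training stops early after `patience` consecutive all-zero-loss epochs
#' (the subgradient is identically zero on that plateau).
#'
#' @param model a [SobelUNet-class].
#' @param samples list of samples, each `list(image = , annotation = )`
#'   (image on the 0-255 scale, annotation a [ContourAnnotation-class]);
#'   a [SceneSample-class] contributes its two annotated contours.
#' @param config a [TrainConfig-class].
#' @param outDir optional directory for checkpoints and the JSON loss
#'   history.
#' @param verbose print per-epoch mean loss.
#' @return `list(model = trained SobelUNet, history = data.frame(epoch,
#'   meanLoss, activeFraction))`.
#' @export
trainSobelUNet <- function(model, samples, config = trainConfig(),
                           outDir = NULL, verbose = FALSE) {
  stopifnot(is(model, "SobelUNet"), is(config, "TrainConfig"))
  samples <- .expandSamples(samples)
  if (length(samples) == 0L) stop("no training samples")
  prior <- NULL  # prior applied only if configured
  prep <- lapply(samples, function(s)
    .prepSample(s$image, s$annotation, config))
  priors <- lapply(prep, function(p) {
    if (config@priorStrength > 0)
      shapePriorMask(p$annotation@start, p$annotation@end,
                     config@priorStrength, shape = dim(p$image))@weights
    else NULL
  })

  state <- list(t = 0L, m = NULL, v = NULL, w = model@weights)
  pars <- config@weightParams
  history <- data.frame(epoch = integer(0), meanLoss = numeric(0),
                        activeFraction = numeric(0))
  zeroEpochs <- 0L
  order0 <- seq_along(prep)
  .withSeed(config@seed, {
    for (ep in seq_len(config@epochs)) {
      ord <- sample(order0)
      losses <- numeric(length(ord))
      batchGrad <- NULL; inBatch <- 0L
      for (si in seq_along(ord)) {
        p <- prep[[ord[si]]]
        model@weights <- state$w
        fw <- .unetForward(model, p$image, cache = TRUE)
        Hp <- dim(fw$out)[1]; Wp <- dim(fw$out)[2]
        mag <- 255 * fw$out[seq_len(fw$origShape[1]),
                            seq_len(fw$origShape[2]), drop = FALSE]
        pred <- .cg_dijkstra(mag, p$gt[1, ], p$gt[nrow(p$gt), ],
                             pars@alpha, pars@beta, pars@gamma,
                             pars@diagonalFactor, priors[[ord[si]]])
        loss <- max(0, pathCost(mag, p$gt, pars, priors[[ord[si]]]) -
                       pathCost(mag, pred$nodes, pars, priors[[ord[si]]]))
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", ep, ", sample ", ord[si])
        losses[si] <- loss
        if (loss > 0) {
          dM <- .hingeUpdateDirection(mag, p$gt, pred$nodes, pars)
          dOut <- matrix(0, Hp, Wp)
          dOut[seq_len(nrow(dM)), seq_len(ncol(dM))] <- 255 * dM
          g <- .unetBackward(model, fw$cache, dOut)
          batchGrad <- if (is.null(batchGrad)) g else
            .accumulateGrads(batchGrad, g)
          inBatch <- inBatch + 1L
        }
        if ((si %% config@batchSize == 0L || si == length(ord)) &&
            inBatch > 0L) {
          if (inBatch > 1L)
            batchGrad <- .scaleGrads(batchGrad, 1 / inBatch)
          if (config@gradClip > 0) {
            nrm <- sqrt(sum(rapply(batchGrad, function(a) sum(a^2),
                                   how = "unlist")))
            if (nrm > config@gradClip)
              batchGrad <- .scaleGrads(batchGrad, config@gradClip / nrm)
          }
          if (config@weightDecay > 0)
            batchGrad <- .accumulateGrads(
              batchGrad, .scaleGrads(state$w, config@weightDecay))
          state <- .adamStep(state$w, batchGrad, state, config@learningRate)
          batchGrad <- NULL; inBatch <- 0L
        }
      }
      history[nrow(history) + 1L, ] <-
        list(ep, mean(losses), mean(losses > 0))
      if (verbose)
        message(sprintf("epoch %d: mean loss %.4f (%.0f%% active)",
                        ep, mean(losses), 100 * mean(losses > 0)))
      if (!is.null(outDir) && config@checkpointInterval > 0L &&
          ep %% config@checkpointInterval == 0L) {
        model@weights <- state$w
        saveSobelUNet(model, file.path(outDir, sprintf("epoch_%03d.rds", ep)))
      }
      zeroEpochs <- if (all(losses == 0)) zeroEpochs + 1L else 0L
      if (zeroEpochs >= config@patience) break
    }
  })
  model@weights <- state$w
  model@mode <- "eval"
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    saveSobelUNet(model, file.path(outDir, "model_final.rds"))
    jsonlite::write_json(
      list(seed = config@seed, epochs = nrow(history), history = history),
      file.path(outDir, "history.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
  }
  list(model = model, history = history)
}

#' @noRd
.expandSamples <- function(samples) {
  out <- list()
  for (s in samples) {
    if (is(s, "SceneSample")) {
      for (j in seq_along(s@annotations))
        out[[length(out) + 1L]] <- list(image = s@image,
                                        annotation = s@annotations[[j]])
    } else out[[length(out) + 1L]] <- s
  }
  out
}

#' @noRd
.accumulateGrads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a) %||% seq_along(a))
      a[[nm]] <- .accumulateGrads(a[[nm]], b[[nm]])
    a
  } else a + b
}

#' @noRd
.scaleGrads <- function(a, f) {
  if (is.list(a)) {
    for (nm in names(a) %||% seq_along(a)) a[[nm]] <- .scaleGrads(a[[nm]], f)
    a
  } else a * f
}
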