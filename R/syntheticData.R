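# Synthetic torso scenes with known breast contours.  A scene is a torso
# region against a background, two elliptical breast-contour arcs rendered
# as an intensity step of controllable contrast (with a soft shadow fading
# into the breast so the arc itself is the only sharp edge), optional
# distractor lines/arcs, an optional illumination ramp and Gaussian noise.
# Every stage of the pipeline is testable against the exact ground-truth
# chains without patient photographs.

# Default breast-arc geometry for an H x W scene; jitter > 0 randomizes
# centers/radii (uses the current RNG stream).
#' @noRd
.defaultArcs <- function(H, W, jitter = 0) {
  j <- function(x, s) if (jitter > 0) x * stats::runif(1, 1 - s, 1 + s) else x
  mk <- function(cx) {
    list(center = c(j(0.52 * H, jitter), j(cx * W, 0.4 * jitter)),
         radii = c(j(0.16 * H, jitter), j(0.14 * W, jitter)),
         span = c(15, 165) * pi / 180)
  }
  list(left = mk(0.32), right = mk(0.68))
}

#' Construct a synthetic scene specification
#'
#' Defaults give a clean, high-contrast scene: uniform background, torso at
#' a distinct gray level, contour step of 120 gray levels, no distractors
#' and no noise.  Lowering `contourContrast` while adding distractors and
#' noise reproduces the weak-contour/cluttered regime in which plain
#' gradient operators fail.
#'
#' @param height,width image size in pixels (>= 32).
#' @param torsoIntensity,backgroundIntensity gray levels.
#' @param contourContrast intensity step across each breast contour arc.
#' @param arcParams list of two arc descriptions (see
#'   [SceneSpec-class]); default geometry is derived from the image size.
#' @param nDistractors number of distractor edges.
#' @param distractorContrast intensity amplitude of distractor edges.
#' @param noiseSd additive Gaussian noise sd.
#' @param illuminationGradient add a multiplicative shading ramp.
#' @param seed RNG seed used by [generateScene()].
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(height = 128, width = 128,
                      torsoIntensity = 150, backgroundIntensity = 60,
                      contourContrast = 120, arcParams = NULL,
                      nDistractors = 0, distractorContrast = 130,
                      noiseSd = 0, illuminationGradient = FALSE, seed = 1) {
  if (is.null(arcParams)) arcParams <- .defaultArcs(height, width)
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      torsoIntensity = torsoIntensity,
      backgroundIntensity = backgroundIntensity,
      contourContrast = contourContrast, arcParams = arcParams,
      nDistractors = as.integer(nDistractors),
      distractorContrast = distractorContrast, noiseSd = noiseSd,
      illuminationGradient = illuminationGradient, seed = as.integer(seed))
}

#' Rasterize an elliptical arc to an 8-connected pixel chain
#'
#' Samples the arc densely, rounds to pixel centers, removes duplicates and
#' transient backtracks, and returns an ordered duplicate-free 8-connected
#' chain from the start angle to the end angle.
#'
#' @param center (row, col) ellipse center.
#' @param radii (row, col) semi-axes in pixels.
#' @param angleStart,angleEnd angles in radians, measured from the positive
#'   column axis with rows increasing downward.
#' @param shape image dimensions `c(H, W)`; the arc must lie inside.
#' @return A [PixelPath-class] with `NA` cost (geometric chain).
#' @examples
#' p <- rasterizeArc(c(20, 20), c(10, 10), 0, pi / 2, c(40, 40))
#' @export
rasterizeArc <- function(center, radii, angleStart, angleEnd, shape) {
  if (any(radii <= 0)) stop("radii must be positive")
  L <- mean(radii) * abs(angleEnd - angleStart)
  n <- max(64L, ceiling(8 * L))
  th <- seq(angleStart, angleEnd, length.out = n)
  r <- round(center[1] + radii[1] * sin(th))
  c <- round(center[2] + radii[2] * cos(th))
  if (min(r) < 1 || max(r) > shape[1] || min(c) < 1 || max(c) > shape[2])
    stop("arc leaves the image bounds")
  pts <- cbind(as.integer(r), as.integer(c))
  pts <- pts[c(TRUE, rowSums(abs(diff(pts))) > 0), , drop = FALSE]
  # dense sampling guarantees steps of Chebyshev length <= 1; drop loops
  # introduced by rounding near flat arc ends, then thin staircase corners
  # so the chain uses diagonal steps (proper 8-connected rasterization)
  pts <- .eraseLoops(pts)
  pts <- .thinChain(pts)
  d <- abs(diff(pts))
  if (nrow(pts) > 1L && any(pmax(d[, 1], d[, 2]) > 1L))
    stop("internal error: rasterized arc is not 8-connected")
  pixelPath(pts)
}

# Remove chain nodes whose removal keeps consecutive nodes 8-adjacent
# (collapses 4-connected staircase corners into diagonal steps).
#' @noRd
.thinChain <- function(pts) {
  if (nrow(pts) < 3L) return(pts)
  keep <- logical(nrow(pts))
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:(nrow(pts) - 1L)) {
    if (max(abs(pts[i + 1L, ] - pts[last, ])) > 1L) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep[nrow(pts)] <- TRUE
  pts[keep, , drop = FALSE]
}

# Elliptical coordinates of a pixel grid relative to one arc:
# rho (elliptical radius, 1 on the arc) and theta (parametric angle).
#' @noRd
.arcCoords <- function(H, W, arc) {
  rr <- matrix(seq_len(H), H, W) - arc$center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - arc$center[2]
  y <- rr / arc$radii[1]
  x <- cc / arc$radii[2]
  list(rho = sqrt(x^2 + y^2), theta = atan2(y, x))
}

#' Render a synthetic scene
#'
#' Deterministic given `spec` (all randomness is drawn from a stream seeded
#' with `spec@seed`).  The intensity immediately inside each contour arc is
#' lower than the outside by exactly `contourContrast`; the shadow then
#' fades smoothly into the breast so no second parallel edge is created.
#'
#' @param spec a [SceneSpec-class].
#' @param nKeypoints interior keypoints per annotation.
#' @return A [SceneSample-class].
#' @examples
#' s <- generateScene(sceneSpec(seed = 7))
#' @export
generateScene <- function(spec, nKeypoints = 3L) {
  stopifnot(is(spec, "SceneSpec"))
  H <- spec@height; W <- spec@width
  .withSeed(spec@seed, {
    img <- matrix(spec@backgroundIntensity, H, W)

    # torso: rounded vertical band (superellipse)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    torso <- (abs((cc - 0.5 * W) / (0.36 * W))^4 +
              (abs((rr - 0.55 * H) / (0.62 * H)))^4) <= 1
    img[torso] <- spec@torsoIntensity

    # breast contours: sharp step across the arc, shadow fading inward
    plateau <- 1.5; bandW <- 8
    for (arc in spec@arcParams) {
      co <- .arcCoords(H, W, arc)
      rbar <- mean(arc$radii)
      din <- (1 - co$rho) * rbar      # approx. pixels inside the arc
      inSpan <- co$theta >= arc$span[1] & co$theta <= arc$span[2]
      fade <- ifelse(din <= plateau, 1,
                     pmax(0, (bandW - din) / (bandW - plateau)))
      sel <- inSpan & din >= 0
      img[sel] <- img[sel] - spec@contourContrast * fade[sel]
    }

    # distractor edges: straight line bands and circular arc bands with
    # contrast at least the contour's own
    if (spec@nDistractors > 0) {
      for (k in seq_len(spec@nDistractors)) {
        amp <- sample(c(-1, 1), 1) * spec@distractorContrast
        if (stats::runif(1) < 0.5) {
          p1 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
          ang <- stats::runif(1, 0, 2 * pi)
          len <- stats::runif(1, 0.2, 0.6) * min(H, W)
          p2 <- p1 + len * c(sin(ang), cos(ang))
          v <- p2 - p1
          t <- .clamp(((rr - p1[1]) * v[1] + (cc - p1[2]) * v[2]) / sum(v^2), 0, 1)
          d <- sqrt((rr - p1[1] - t * v[1])^2 + (cc - p1[2] - t * v[2])^2)
        } else {
          ctr <- c(stats::runif(1, 0.2 * H, 0.8 * H), stats::runif(1, 0.2 * W, 0.8 * W))
          R <- stats::runif(1, 0.08, 0.3) * min(H, W)
          a0 <- stats::runif(1, 0, 2 * pi); a1 <- a0 + stats::runif(1, pi / 3, pi)
          th <- atan2(rr - ctr[1], cc - ctr[2])
          dth <- (th - a0) %% (2 * pi)
          d <- abs(sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) - R)
          d[dth > (a1 - a0)] <- Inf
        }
        img[d <= 1.2] <- img[d <= 1.2] + amp
      }
    }

    if (spec@illuminationGradient) {
      dirn <- sample(c(1, -1), 1)
      ramp <- seq(0.78, 1.12, length.out = W)
      if (dirn < 0) ramp <- rev(ramp)
      img <- img * matrix(ramp, H, W, byrow = TRUE)
    }

    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
    img <- .clamp(img, 0, 255)

    chains <- lapply(spec@arcParams, function(a)
      rasterizeArc(a$center, a$radii, a$span[1], a$span[2], c(H, W)))
    sides <- c("left", "right")
    anns <- lapply(seq_along(chains), function(i) {
      nd <- chains[[i]]@nodes
      n <- nrow(nd)
      ki <- round(seq(1, n, length.out = nKeypoints + 2L))[-c(1, nKeypoints + 2L)]
      contourAnnotation(nd[1, ], nd[n, ], nd[ki, , drop = FALSE], sides[i])
    })
    new("SceneSample", image = img, annotations = anns, gtChains = chains,
        spec = spec)
  })
}

#' Parameter ranges for the two study regimes
#'
#' `"clean"` emulates uniform-background, well-lit photographs: strong
#' contour step, no distractors, no noise.  `"cluttered"` emulates poorly
#' lit, inconsistent-background photographs: weak contour step (20-40 gray
#' levels), 4-8 distractor edges at 90-140 gray levels, noise and an
#' illumination ramp.
#'
#' @param preset `"clean"` or `"cluttered"`.
#' @return named list of ranges consumed by [generateDataset()].
#' @export
presetRanges <- function(preset = c("clean", "cluttered")) {
  preset <- match.arg(preset)
  base <- list(height = c(128L, 128L), width = c(128L, 128L),
               torsoIntensity = c(140, 165), backgroundIntensity = c(50, 75),
               arcJitter = 0.12)
  if (preset == "clean")
    c(base, list(contourContrast = c(120, 160), nDistractors = c(0L, 0L),
                 distractorContrast = c(0, 0), noiseSd = c(0, 0),
                 illuminationGradient = FALSE))
  else
    c(base, list(contourContrast = c(20, 40), nDistractors = c(4L, 8L),
                 distractorContrast = c(90, 140), noiseSd = c(3, 6),
                 illuminationGradient = TRUE))
}

#' Generate a scene dataset on disk
#'
#' Draws per-scene parameters uniformly from `ranges`, renders each scene,
#' and writes PNG images, annotation JSON files (endpoints, keypoints and
#' the true contour polyline) and a `manifest.json` linking them.
#' Byte-identical across runs with the same seed.
#'
#' @param n number of scenes (>= 1).
#' @param dir output directory (created if needed).
#' @param ranges named list of parameter ranges, see [presetRanges()].
#' @param seed integer seed.
#' @param nKeypoints interior keypoints per annotation.
#' @return invisibly, the manifest as a list (also written to
#'   `dir/manifest.json`).
#' @export
generateDataset <- function(n, dir, ranges = presetRanges("clean"), seed = 1,
                            nKeypoints = 3L) {
  if (n < 1) stop("n must be >= 1")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  specs <- drawSceneSpecs(n, ranges, seed)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    sm <- generateScene(specs[[i]], nKeypoints = nKeypoints)
    stem <- sprintf("scene_%03d", i)
    imgFile <- paste0(stem, ".png")
    png::writePNG(sm@image / 255, file.path(dir, imgFile))
    annFiles <- character(2)
    for (j in 1:2) {
      annFiles[j] <- sprintf("%s_%s.json", stem, sm@annotations[[j]]@side)
      writeAnnotation(sm@annotations[[j]], file.path(dir, annFiles[j]),
                      image = imgFile, gt = sm@gtChains[[j]])
    }
    entries[[i]] <- list(image = imgFile, annotations = annFiles,
                         seed = specs[[i]]@seed)
  }
  manifest <- list(n = n, seed = seed, entries = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Draw scene specifications from parameter ranges
#'
#' @inheritParams generateDataset
#' @return list of `n` [SceneSpec-class] objects with per-scene seeds
#'   derived deterministically from `seed`.
#' @export
drawSceneSpecs <- function(n, ranges = presetRanges("clean"), seed = 1) {
  .withSeed(seed, {
    sceneSeeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      u <- function(nm) {
        r <- ranges[[nm]]
        if (is.null(r)) stop("missing range: ", nm)
        stats::runif(1, r[1], r[2])
      }
      ui <- function(nm) {
        r <- ranges[[nm]]
        if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
      }
      H <- ui("height"); W <- ui("width")
      arcs <- .defaultArcs(H, W, jitter = ranges$arcJitter %||% 0)
      sceneSpec(height = H, width = W,
                torsoIntensity = u("torsoIntensity"),
                backgroundIntensity = u("backgroundIntensity"),
                contourContrast = u("contourContrast"), arcParams = arcs,
                nDistractors = ui("nDistractors"),
                distractorContrast = u("distractorContrast"),
                noiseSd = u("noiseSd"),
                illuminationGradient = isTRUE(ranges$illuminationGradient),
                seed = sceneSeeds[i])
    })
  })
}
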