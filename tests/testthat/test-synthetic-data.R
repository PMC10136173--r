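test_that("rasterized arcs are valid chains with correct endpoints and length", {
  # quarter circle, radius 10: between Chebyshev and Manhattan arc length
  q <- rasterizeArc(c(20, 20), c(10, 10), 0, pi / 2, c(40, 40))
  expect_true(oracleValidChain(q@nodes))
  expect_gte(nrow(q@nodes), 10)
  expect_lte(nrow(q@nodes), 16)

  # semicircle: first/last nodes are the diametral endpoints
  s <- rasterizeArc(c(25, 25), c(12, 12), 0, pi, c(50, 50))
  expect_identical(s@nodes[1, ], c(25L, 37L))
  expect_identical(s@nodes[nrow(s@nodes), ], c(25L, 13L))

  set.seed(77)
  for (rep in 1:15) {
    ctr <- c(runif(1, 30, 50), runif(1, 30, 50))
    rad <- c(runif(1, 5, 20), runif(1, 5, 20))
    a0 <- runif(1, 0, 2 * pi); a1 <- a0 + runif(1, 0.5, pi)
    p <- rasterizeArc(ctr, rad, a0, a1, c(80, 80))
    expect_true(oracleValidChain(p@nodes))
  }
  expect_error(rasterizeArc(c(5, 5), c(10, 10), 0, pi, c(20, 20)), "bounds")
})

test_that("scene rendering honors the contour-contrast contract", {
  spec <- sceneSpec(contourContrast = 120, nDistractors = 0, noiseSd = 0,
                    seed = 3)
  s <- generateScene(spec)
  img <- s@image
  # sample pixel pairs straddling each arc radially
  for (arc in spec@arcParams) {
    for (th in seq(arc$span[1] + 0.2, arc$span[2] - 0.2, length.out = 5)) {
      outP <- round(arc$center + (arc$radii + 1.8) * c(sin(th), cos(th)))
      inP <- round(arc$center + (arc$radii - 1.2) * c(sin(th), cos(th)))
      expect_equal(img[outP[1], outP[2]] - img[inP[1], inP[2]], 120)
    }
  }
})

test_that("scene generation is deterministic and annotations are consistent", {
  spec <- sceneSpec(contourContrast = 40, nDistractors = 5, noiseSd = 4,
                    illuminationGradient = TRUE, seed = 9)
  a <- generateScene(spec); b <- generateScene(spec)
  expect_identical(a@image, b@image)
  expect_identical(a@annotations[[1]]@keypoints, b@annotations[[1]]@keypoints)

  for (i in 1:2) {
    ann <- a@annotations[[i]]
    chain <- a@gtChains[[i]]@nodes
    expect_true(oracleValidChain(chain))
    expect_identical(ann@start, chain[1, ])
    expect_identical(ann@end, chain[nrow(chain), ])
    key <- paste(chain[, 1], chain[, 2])
    expect_true(all(paste(ann@keypoints[, 1], ann@keypoints[, 2]) %in% key))
  }
  expect_true(min(a@image) >= 0 && max(a@image) <= 255)
})

test_that("clean high-contrast scenes are recovered by Sobel + shortest path", {
  specs <- drawSceneSpecs(4, presetRanges("clean"), seed = 15)
  for (sp in specs) {
    s <- generateScene(sp)
    em <- sobelMagnitude(s@image)
    for (i in 1:2) {
      ann <- s@annotations[[i]]
      pred <- shortestPath(em, ann@start, ann@end)
      expect_lt(pathError(pred, s@gtChains[[i]], dim(s@image)), 0.5)
    }
  }
})

test_that("dataset generation writes a reproducible, schema-valid manifest", {
  d1 <- file.path(tempdir(), "cgds1"); d2 <- file.path(tempdir(), "cgds2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateDataset(5, d1, presetRanges("clean"), seed = 4)
  m2 <- generateDataset(5, d2, presetRanges("clean"), seed = 4)
  expect_equal(length(m1$entries), 5)
  for (e in m1$entries) {
    expect_true(file.exists(file.path(d1, e$image)))
    for (annf in unlist(e$annotations)) {
      img <- readImageGray(file.path(d1, e$image))
      expect_length(validateAnnotation(file.path(d1, annf), dim(img)), 0)
      ann <- readAnnotation(file.path(d1, annf))
      gt <- attr(ann, "gtPolyline")
      expect_false(is.null(gt))
      key <- paste(gt[, 1], gt[, 2])
      kp <- ann@keypoints
      expect_true(all(paste(kp[, 1], kp[, 2]) %in% key))
    }
  }
  # byte-identical reruns
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # degenerate ranges collapse to a shared spec
  rg <- presetRanges("clean")
  rg$contourContrast <- c(130, 130); rg$torsoIntensity <- c(150, 150)
  rg$backgroundIntensity <- c(60, 60); rg$arcJitter <- 0
  specs <- drawSceneSpecs(3, rg, seed = 2)
  expect_equal(length(unique(vapply(specs, function(s) s@contourContrast, 1))), 1)
  expect_gt(length(unique(vapply(specs, function(s) s@seed, 1L))), 1)
})

test_that("lowering contour contrast cannot improve the Sobel baseline", {
  ladder <- c(120, 60, 30)
  errs <- vapply(ladder, function(ct) {
    rg <- presetRanges("cluttered")
    rg$contourContrast <- c(ct, ct)
    specs <- drawSceneSpecs(6, rg, seed = 31)
    mean(unlist(lapply(specs, function(sp) {
      s <- generateScene(sp)
      em <- sobelMagnitude(s@image)
      vapply(1:2, function(i) {
        a <- s@annotations[[i]]
        pathError(shortestPath(em, a@start, a@end), s@gtChains[[i]],
                  dim(s@image))
      }, 1)
    })))
  }, 1)
  expect_true(all(diff(errs) >= 0))
})
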