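pDef <- edgeWeightParams()

test_that("structured loss is a hinge on the two path costs", {
  set.seed(71)
  mag <- matrix(runif(100, 0, 255), 10, 10)
  chain <- randomChain(10, 10, 8)
  expect_identical(structuredPathLoss(mag, chain, chain, pDef), 0)

  for (rep in 1:30) {
    mag <- matrix(runif(144, 0, 255), 12, 12)
    gt <- randomChain(12, 12, sample(6:12, 1))
    pred <- shortestPath(mag, gt[1, ], gt[nrow(gt), ], pDef)
    loss <- structuredPathLoss(mag, gt, pred, pDef)
    expect_gte(loss, 0)
    oracle <- max(0, oraclePathCost(mag, gt, pDef) -
                     oraclePathCost(mag, pred@nodes, pDef))
    expect_equal(loss, oracle, tolerance = 1e-9)
  }
  expect_error(structuredPathLoss(mag, randomChain(12, 12, 5),
                                  randomChain(12, 12, 5), pDef),
               "endpoints")
})

test_that("the hinge stays positive on all-edge maps unless the paths agree", {
  # gt: a bulging chain; pred: the straight chord between the same endpoints
  gt <- rbind(cbind(3L, 1:4), c(4L, 5L), cbind(3L, 6:9))
  pred <- cbind(3L, 1:9)
  for (level in c(150, 200, 255)) {   # global shifts toward saturation
    mag <- matrix(level, 6, 9)
    loss <- structuredPathLoss(mag, gt, pred, pDef)
    # both costs hit the same per-arc floor but gt takes two diagonal
    # detour arcs; the hinge stays strictly positive
    expect_gt(loss, 0)
  }
  # and the floor value at full saturation follows the arc geometry
  f <- arcWeight(255, 255, "straight", pDef)
  d <- arcWeight(255, 255, "diagonal", pDef)
  expect_equal(structuredPathLoss(matrix(255, 6, 9), gt, pred, pDef),
               (6 * f + 2 * d) - 8 * f, tolerance = 1e-12)
})

test_that("the hinge subgradient matches finite differences of the loss", {
  set.seed(73)
  mag <- matrix(runif(64, 20, 235), 8, 8)
  gt <- randomChain(8, 8, 7)
  pred <- shortestPath(mag, gt[1, ], gt[nrow(gt), ], pDef)@nodes
  raw <- pathCost(mag, gt, pDef) - pathCost(mag, pred, pDef)
  g <- contourGraph:::.pathLossGradient(mag, gt, pred, pDef)
  if (raw <= 0) {
    expect_true(all(g == 0))
  } else {
    eps <- 1e-5
    for (i in sample(64, 12)) {
      m1 <- mag; m1[i] <- mag[i] + eps
      m2 <- mag; m2[i] <- mag[i] - eps
      num <- (structuredPathLoss(m1, gt, pred, pDef) -
              structuredPathLoss(m2, gt, pred, pDef)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-6)
    }
  }
})

test_that("an already-consistent model trains with zero loss and unchanged weights", {
  # constant image: the Sobel map is all-zero, so the keypoint-derived
  # ground truth is the deterministic geodesic; the model's uniform output
  # yields the same tie-broken path, hence the hinge is zero everywhere
  img <- matrix(100, 64, 64)
  ann <- contourAnnotation(c(32, 10), c(32, 54), rbind(c(32, 32)), "left")
  m <- sobelUNet(baseFeatures = 4, depth = 2, seed = 2)
  res <- trainSobelUNet(m, list(list(image = img, annotation = ann)),
                        trainConfig(epochs = 6, patience = 2, seed = 1))
  expect_true(all(res$history$meanLoss == 0))
  expect_lte(nrow(res$history), 2)     # early stop on the zero plateau
  expect_identical(res$model@weights, m@weights)
})

test_that("seeded training is deterministic and reduces the loss", {
  rg <- presetRanges("cluttered")
  rg$height <- c(64L, 64L); rg$width <- c(64L, 64L)
  scenes <- lapply(drawSceneSpecs(6, rg, seed = 88), generateScene)
  cfg <- trainConfig(epochs = 3, seed = 5)
  r1 <- trainSobelUNet(sobelUNet(baseFeatures = 8, depth = 3, seed = 5),
                       scenes, cfg)
  r2 <- trainSobelUNet(sobelUNet(baseFeatures = 8, depth = 3, seed = 5),
                       scenes, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model@weights, r2$model@weights)
  expect_lt(r1$history$meanLoss[3], r1$history$meanLoss[1])
})

test_that("training emits checkpoints and a loss history", {
  dir <- file.path(tempdir(), "cgtrain")
  unlink(dir, recursive = TRUE); dir.create(dir)
  img <- matrix(100, 32, 32)
  ann <- contourAnnotation(c(16, 5), c(16, 28), NULL, "left")
  m <- sobelUNet(baseFeatures = 4, depth = 2, seed = 3)
  trainSobelUNet(m, list(list(image = img, annotation = ann)),
                 trainConfig(epochs = 2, patience = 5, seed = 1),
                 outDir = dir)
  expect_true(file.exists(file.path(dir, "model_final.rds")))
  h <- jsonlite::read_json(file.path(dir, "history.json"))
  expect_equal(h$seed, 1)
  expect_length(h$history$meanLoss, 2)
  m2 <- loadSobelUNet(file.path(dir, "model_final.rds"))
  expect_s4_class(m2, "SobelUNet")
})
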