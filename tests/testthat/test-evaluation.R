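test_that("path error matches closed forms and the double-loop oracle", {
  a <- cbind(5L, 1:20)
  expect_identical(pathError(a, a, c(50, 50)), 0)

  # constant row offset: 100 * d / sqrt(H^2 + W^2)
  for (d in c(1, 3, 7)) {
    b <- cbind(5L + d, 1:20)
    expect_equal(pathError(a, b, c(100, 100)), 100 * d / sqrt(2e4),
                 tolerance = 1e-12)
  }

  set.seed(19)
  for (rep in 1:10) {
    p <- randomChain(30, 30, sample(5:15, 1))
    g <- randomChain(30, 30, sample(5:15, 1))
    expect_equal(pathError(p, g, c(30, 30)), oraclePathError(p, g, c(30, 30)),
                 tolerance = 1e-12)
    # symmetry and nonnegativity
    expect_equal(pathError(p, g, c(30, 30)), pathError(g, p, c(30, 30)))
    expect_gte(pathError(p, g, c(30, 30)), 0)
  }
  expect_error(pathError(matrix(integer(0), 0, 2), a, c(50, 50)), "nonempty")
})

test_that("path error is zero iff the node sets coincide", {
  a <- cbind(3L, 1:10)
  shuffled <- a[c(5:10, 1:4), ]
  expect_identical(pathError(a, shuffled, c(20, 20)), 0)
  expect_gt(pathError(a, rbind(a, c(4L, 5L)), c(20, 20)), 0)
})

test_that("path error is scale invariant up to rasterization tolerance", {
  sc <- generateScene(sceneSpec(seed = 23))
  gt <- sc@gtChains[[1]]@nodes
  pred <- gt
  pred[, 1] <- pred[, 1] + 2L   # constant offset surrogate prediction
  base <- pathError(pred, gt, c(128, 128))
  for (s in c(2L, 3L)) {
    arc <- sc@spec@arcParams[[1]]
    gtS <- rasterizeArc(arc$center * s, arc$radii * s, arc$span[1],
                        arc$span[2], c(128 * s, 128 * s))@nodes
    predS <- gtS
    predS[, 1] <- predS[, 1] + 2L * s
    expect_lt(abs(pathError(predS, gtS, c(128 * s, 128 * s)) - base), 0.05)
  }
})

test_that("k-fold splits are disjoint, exhaustive and deterministic", {
  f <- kfoldSplit(10, 5, seed = 3)
  expect_length(f, 5)
  expect_true(all(vapply(f, function(x) length(x$test), 1L) == 2L))
  expect_identical(sort(unlist(lapply(f, `[[`, "test"))), 1:10)

  # protocol arithmetic for the 221-image cross-validation regime
  f221 <- kfoldSplit(221, 5, seed = 1)
  sizes <- sort(vapply(f221, function(x) length(x$test), 1L), decreasing = TRUE)
  expect_identical(sizes, c(45L, 44L, 44L, 44L, 44L))
  expect_identical(sort(unlist(lapply(f221, `[[`, "test"))), 1:221)
  for (x in f221) {
    expect_identical(intersect(x$train, x$test), integer(0))
    expect_identical(sort(c(x$train, x$test)), 1:221)
  }
  expect_identical(kfoldSplit(221, 5, seed = 9), kfoldSplit(221, 5, seed = 9))
  expect_error(kfoldSplit(3, 5), "k")
})

test_that("operator evaluation is self-consistent, deterministic and accurate on clean folds", {
  dir <- file.path(tempdir(), "cgeval")
  unlink(dir, recursive = TRUE)
  generateDataset(4, dir, presetRanges("clean"), seed = 8)
  mf <- file.path(dir, "manifest.json")

  res <- evaluateOperator(mf, "sobel")
  expect_length(perImageErrors(res), 8)   # two contours per scene
  expect_lt(evalSummary(res)[["mean"]], 0.5)

  s <- evalSummary(res)
  e <- perImageErrors(res)
  expect_equal(s[["mean"]], mean(e))
  expect_equal(s[["sd"]], sd(e))
  expect_equal(s[["max"]], max(e))

  res2 <- evaluateOperator(mf, "sobel")
  expect_identical(perImageErrors(res), perImageErrors(res2))

  # missing image file is named
  mfBad <- jsonlite::read_json(mf)
  mfBad$dir <- dir
  mfBad$entries[[1]]$image <- "nope.png"
  expect_error(evaluateOperator(mfBad, "sobel"), "nope.png")
})

test_that("bench table mirrors per-operator summaries", {
  dir <- file.path(tempdir(), "cgbench")
  unlink(dir, recursive = TRUE)
  generateDataset(3, dir, presetRanges("clean"), seed = 12)
  mf <- file.path(dir, "manifest.json")
  tab <- benchOperators(mf, c("sobel", "prewitt"))
  expect_identical(tab$operator, c("sobel", "prewitt"))
  expect_equal(tab$mean[1], evalSummary(evaluateOperator(mf, "sobel"))[["mean"]])
  expect_true(all(tab$n == 6))
})

test_that("cluttered weak-contrast scenes are harder for the Sobel baseline", {
  clean <- drawSceneSpecs(5, presetRanges("clean"), seed = 44)
  clut <- drawSceneSpecs(5, presetRanges("cluttered"), seed = 44)
  err <- function(specs) {
    mean(unlist(lapply(specs, function(sp) {
      s <- generateScene(sp)
      em <- sobelMagnitude(s@image)
      vapply(1:2, function(i) {
        a <- s@annotations[[i]]
        pathError(shortestPath(em, a@start, a@end), s@gtChains[[i]],
                  dim(s@image))
      }, 1)
    })))
  }
  expect_lte(err(clean), err(clut))
})
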