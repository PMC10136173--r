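pDefault <- edgeWeightParams()

test_that("arc weight follows the exponential form and its bounds", {
  p <- edgeWeightParams(alpha = 1, beta = 0.01, gamma = 0)
  expect_equal(arcWeight(255, 255, "straight", p), 1)
  expect_equal(arcWeight(255, 255, "diagonal", p), sqrt(2))
  expect_equal(arcWeight(255, 0, "straight", p), exp(0.01 * 127.5))

  set.seed(21)
  for (rep in 1:200) {
    gi <- runif(1, 0, 255); gj <- runif(1, 0, 255)
    diagonal <- runif(1) < 0.5
    pr <- edgeWeightParams(runif(1, 0.5, 2), runif(1, 0.005, 0.04),
                           runif(1, 0, 0.1), sqrt(2))
    got <- arcWeight(gi, gj, ifelse(diagonal, "diagonal", "straight"), pr)
    expect_equal(got, oracleArcWeight(gi, gj, diagonal, pr@alpha, pr@beta,
                                      pr@gamma, pr@diagonalFactor),
                 tolerance = 1e-12)
    # bounds: gamma <= f(g) <= alpha * exp(255 beta) + gamma (straight)
    base <- got / ifelse(diagonal, pr@diagonalFactor, 1)
    expect_gte(base, pr@gamma)
    expect_lte(base, pr@alpha * exp(255 * pr@beta) + pr@gamma)
  }
  expect_equal(arcWeight(255, 255, "straight", pDefault),
               pDefault@alpha + pDefault@gamma)
  expect_error(arcWeight(-1, 0), "\\[0, 255\\]")
  expect_error(arcWeight(0, 300), "\\[0, 255\\]")
})

test_that("shortest paths on uniform maps follow metric geometry", {
  p <- edgeWeightParams(alpha = 1, beta = 0.01, gamma = 0)
  em <- edgeMap(matrix(200, 8, 8), "sobel")
  f <- arcWeight(200, 200, "straight", p)

  sp <- shortestPath(em, c(1, 1), c(1, 6), p)
  expect_identical(sp@nodes, cbind(1L, 1:6))
  expect_equal(sp@cost, 5 * f)

  sp2 <- shortestPath(em, c(1, 1), c(4, 4), p)
  expect_equal(sp2@cost, 3 * sqrt(2) * f)
  expect_identical(sp2@nodes, cbind(1:4, 1:4))

  sp0 <- shortestPath(em, c(3, 3), c(3, 3), p)
  expect_identical(sp0@nodes, cbind(3L, 3L))
  expect_identical(sp0@cost, 0)

  expect_error(shortestPath(em, c(0, 1), c(2, 2), p), "outside")
})

test_that("Dijkstra equals exhaustive simple-path enumeration on small maps", {
  set.seed(33)
  for (n in c(4, 5)) {
    for (rep in 1:6) {
      mag <- matrix(runif(n * n, 0, 255), n, n)
      pts <- sample(n * n, 2)
      s <- c((pts[1] - 1) %% n + 1, (pts[1] - 1) %/% n + 1)
      e <- c((pts[2] - 1) %% n + 1, (pts[2] - 1) %/% n + 1)
      sp <- shortestPath(mag, s, e, pDefault)
      expect_equal(sp@cost, oracleShortestCost(mag, s, e, pDefault),
                   tolerance = 1e-9)
      expect_equal(sp@cost, pathCost(mag, sp@nodes, pDefault),
                   tolerance = 1e-12)  # self-consistency
    }
  }
})

test_that("Dijkstra agrees with igraph on a larger random map", {
  skip_if_not_installed("igraph")
  set.seed(17)
  H <- 12; W <- 14
  mag <- matrix(runif(H * W, 0, 255), H, W)
  edges <- NULL; weights <- NULL
  idx <- function(r, c) (c - 1) * H + r
  for (r in seq_len(H)) for (c in seq_len(W))
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      nr <- r + d[1]; nc <- c + d[2]
      if (nr < 1 || nr > H || nc < 1 || nc > W) next
      edges <- rbind(edges, c(idx(r, c), idx(nr, nc)))
      weights <- c(weights, arcWeight(mag[r, c], mag[nr, nc],
                                      ifelse(all(d != 0), "diagonal", "straight"),
                                      pDefault))
    }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ref <- igraph::distances(g, v = idx(2, 2), to = idx(11, 13),
                           weights = weights)[1, 1]
  sp <- shortestPath(mag, c(2, 2), c(11, 13), pDefault)
  expect_equal(sp@cost, ref, tolerance = 1e-9)
})

test_that("raising a magnitude never increases a shortest-path cost", {
  set.seed(29)
  mag <- matrix(runif(49, 0, 200), 7, 7)
  s <- c(1, 1); e <- c(7, 7)
  base <- shortestPath(mag, s, e, pDefault)@cost
  for (rep in 1:20) {
    m2 <- mag
    i <- sample(49, 1)
    m2[i] <- min(255, m2[i] + runif(1, 10, 55))
    expect_lte(shortestPath(m2, s, e, pDefault)@cost, base + 1e-12)
  }
})

test_that("path cost sums arcs, handles priors, and validates chains", {
  p <- edgeWeightParams(alpha = 1, beta = 0.01, gamma = 0)
  expect_identical(pathCost(matrix(255, 3, 3), cbind(2L, 2L), p), 0)
  expect_equal(pathCost(matrix(255, 3, 3), rbind(c(1, 1), c(1, 2)), p), 1)

  set.seed(41)
  for (rep in 1:20) {
    mag <- matrix(runif(100, 0, 255), 10, 10)
    chain <- randomChain(10, 10, 10)
    expect_equal(pathCost(mag, chain, pDefault),
                 oraclePathCost(mag, chain, pDefault), tolerance = 1e-9)
    prior <- matrix(1 + runif(100, 0, 2), 10, 10)
    expect_equal(pathCost(mag, chain, pDefault, prior),
                 oraclePathCost(mag, chain, pDefault, prior),
                 tolerance = 1e-9)
  }
  expect_error(pathCost(matrix(0, 5, 5), rbind(c(1, 1), c(3, 3))), "8-adjacent")
  expect_error(pathCost(matrix(0, 5, 5), rbind(c(1, 1), c(1, 1))), "8-adjacent")
})

test_that("ground-truth path passes keypoints and reduces without them", {
  em <- edgeMap(matrix(150, 9, 9), "sobel")
  annNone <- contourAnnotation(c(5, 1), c(5, 9), NULL, "left")
  gt0 <- groundTruthPath(em, annNone, pDefault)
  sp <- shortestPath(em, c(5, 1), c(5, 9), pDefault)
  expect_identical(gt0@nodes, sp@nodes)

  # collinear keypoint on the unconstrained optimum leaves the path alone
  annK <- contourAnnotation(c(5, 1), c(5, 9), rbind(c(5, 5)), "left")
  gt1 <- groundTruthPath(em, annK, pDefault)
  expect_identical(gt1@nodes, sp@nodes)

  # off-path keypoint is visited exactly once, junctions not duplicated
  annOff <- contourAnnotation(c(5, 1), c(5, 9), rbind(c(2, 5)), "left")
  gt2 <- groundTruthPath(em, annOff, pDefault)
  nodesKey <- paste(gt2@nodes[, 1], gt2@nodes[, 2])
  expect_equal(sum(nodesKey == "2 5"), 1)
  expect_false(anyDuplicated(nodesKey) > 0)
  expect_true(oracleValidChain(gt2@nodes))
  expect_error(groundTruthPath(em, contourAnnotation(c(5, 1), c(5, 9),
                                                     rbind(c(99, 5)), "left")),
               "outside")
})

test_that("constrained ground-truth cost is never below the unconstrained optimum", {
  set.seed(55)
  for (rep in 1:10) {
    mag <- matrix(runif(144, 0, 255), 12, 12)
    s <- c(sample(12, 1), 1); e <- c(sample(12, 1), 12)
    kp <- cbind(sample(12, 2), sample(2:11, 2))
    kp <- kp[order(kp[, 2]), , drop = FALSE]
    gt <- groundTruthPath(mag, contourAnnotation(s, e, kp, "left"), pDefault)
    sp <- shortestPath(mag, s, e, pDefault)
    expect_gte(gt@cost, sp@cost - 1e-9)
  }
})

test_that("identical inputs give identical node sequences", {
  set.seed(61)
  mag <- matrix(sample(0:255, 100, TRUE), 10, 10)  # many exact ties
  a <- shortestPath(mag, c(1, 1), c(10, 10), pDefault)
  b <- shortestPath(mag, c(1, 1), c(10, 10), pDefault)
  expect_identical(a@nodes, b@nodes)
  u <- shortestPath(matrix(100, 10, 10), c(1, 1), c(10, 10), pDefault)
  v <- shortestPath(matrix(100, 10, 10), c(1, 1), c(10, 10), pDefault)
  expect_identical(u@nodes, v@nodes)
})

test_that("shape prior mask is 1 on the arc, 1+lambda far away, all-ones when off", {
  shape <- c(101, 101)
  s <- c(50, 21); e <- c(50, 81)
  expect_true(all(shapePriorMask(s, e, 0, 10, shape)@weights == 1))

  lam <- 2; sig <- 5
  pm <- shapePriorMask(s, e, lam, sig, shape, bulge = "down")@weights
  mid <- (s + e) / 2; R <- sqrt(sum((e - s)^2)) / 2
  onArc <- c(mid[1] + R, mid[2])   # bottom of the semicircle
  expect_equal(pm[onArc[1], onArc[2]], 1, tolerance = 1e-6)
  expect_equal(pm[1, 1], 1 + lam, tolerance = 1e-3)   # far corner
  expect_equal(pm[s[1], s[2]], 1, tolerance = 1e-6)   # endpoints on the arc
  expect_true(all(pm >= 1))

  # prior steers the path toward the configured bulge on a uniform map
  mag <- matrix(100, 101, 101)
  free <- shortestPath(mag, s, e, pDefault)
  steered <- shortestPath(mag, s, e, pDefault,
                          shapePriorMask(s, e, 5, 8, shape, "down"))
  expect_gt(mean(steered@nodes[, 1]), mean(free@nodes[, 1]))
  expect_error(shapePriorMask(s, e, 1, -2, shape), "bandWidth")
})
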