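# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain double loops, exhaustive enumeration and
# closed forms.

# Arc weight recomputed directly from its definition.
oracleArcWeight <- function(gi, gj, diagonal, alpha, beta, gamma, diagFactor) {
  g <- (gi + gj) / 2
  w <- alpha * exp(beta * (255 - g)) + gamma
  if (diagonal) w <- w * diagFactor
  w
}

# Path cost as an arc-by-arc sum.
oraclePathCost <- function(mag, nodes, params, priorW = NULL) {
  if (nrow(nodes) < 2) return(0)
  tot <- 0
  for (i in seq_len(nrow(nodes) - 1)) {
    a <- nodes[i, ]; b <- nodes[i + 1, ]
    diagonal <- abs(a[1] - b[1]) == 1 && abs(a[2] - b[2]) == 1
    w <- oracleArcWeight(mag[a[1], a[2]], mag[b[1], b[2]], diagonal,
                         params@alpha, params@beta, params@gamma,
                         params@diagonalFactor)
    if (!is.null(priorW))
      w <- w * (priorW[a[1], a[2]] + priorW[b[1], b[2]]) / 2
    tot <- tot + w
  }
  tot
}

# Exhaustive minimum cost over all simple 8-connected paths (depth-first
# search with branch-and-bound pruning: partial costs are monotone since
# all arc weights are positive, so pruned branches cannot contain the
# optimum).
oracleShortestCost <- function(mag, start, end, params) {
  H <- nrow(mag); W <- ncol(mag)
  best <- Inf
  visited <- matrix(FALSE, H, W)
  steps <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  a <- params@alpha; b <- params@beta; gm <- params@gamma
  df <- params@diagonalFactor
  dfs <- function(r, c, cost) {
    if (cost >= best) return(invisible())
    if (r == end[1] && c == end[2]) { best <<- cost; return(invisible()) }
    for (k in 1:8) {
      nr <- r + steps[k, 1]; nc <- c + steps[k, 2]
      if (nr < 1 || nr > H || nc < 1 || nc > W || visited[nr, nc]) next
      g <- (mag[r, c] + mag[nr, nc]) / 2
      w <- a * exp(b * (255 - g)) + gm
      if (steps[k, 1] != 0 && steps[k, 2] != 0) w <- w * df
      visited[nr, nc] <<- TRUE
      dfs(nr, nc, cost + w)
      visited[nr, nc] <<- FALSE
    }
    invisible()
  }
  visited[start[1], start[2]] <- TRUE
  dfs(start[1], start[2], 0)
  best
}

# Brute-force valid-chain check.
oracleValidChain <- function(nodes) {
  if (nrow(nodes) == 1) return(TRUE)
  for (i in seq_len(nrow(nodes) - 1)) {
    d <- abs(nodes[i + 1, ] - nodes[i, ])
    if (max(d) != 1) return(FALSE)
  }
  !anyDuplicated(paste(nodes[, 1], nodes[, 2]))
}

# Double-loop symmetric mean nearest-neighbour distance (percent of the
# diagonal).
oraclePathError <- function(p, g, shape) {
  dmin <- function(x, ys) {
    best <- Inf
    for (i in seq_len(nrow(ys)))
      best <- min(best, sqrt(sum((x - ys[i, ])^2)))
    best
  }
  dpg <- mean(vapply(seq_len(nrow(p)), function(i) dmin(p[i, ], g), 1))
  dgp <- mean(vapply(seq_len(nrow(g)), function(i) dmin(g[i, ], p), 1))
  100 * (dpg + dgp) / 2 / sqrt(sum(shape^2))
}

# Direct 3x3 correlation with symmetric reflect padding.
oracleConvolve3 <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  refl <- function(i, n) if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (dy in -1:1) for (dx in -1:1)
      acc <- acc + img[refl(i + dy, H), refl(j + dx, W)] *
        kernel[dy + 2, dx + 2]
    out[i, j] <- acc
  }
  out
}

sobelKernelX <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
prewittKernelX <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)

# Architecture arithmetic oracle: parameter count computed directly from
# the layer shapes (conv k x k: cout*cin*k^2 + cout; tconv 2x2:
# 4*cin*cout + cout; final 1x1 conv over tOut+1 channels).
oracleParamCount <- function(base, depth, inCh = 1) {
  encOut <- base * 2^(seq_len(depth) - 1)
  encIn <- c(inCh, encOut[-depth])
  n <- sum(9 * encIn * encOut + encOut + 9 * encOut * encOut + encOut)
  cb <- encOut[depth]
  convOut <- cb / 2^seq_len(depth)
  tOut <- pmax(cb / 2^(seq_len(depth) + 1), base / 2)
  convIn <- c(cb, tOut[-depth]) + 1
  n <- n + sum(9 * convIn * convOut + convOut +
               9 * convOut * convOut + convOut +
               4 * convOut * tOut + tOut)
  as.integer(n + (tOut[depth] + 1) + 1)
}

# Random 8-connected chain for fuzzing path costs.
randomChain <- function(H, W, n) {
  r <- sample(H, 1); c <- sample(W, 1)
  nodes <- matrix(c(r, c), 1)
  seen <- paste(r, c)
  for (i in seq_len(n - 1)) {
    cand <- expand.grid(dr = -1:1, dc = -1:1)
    cand <- cand[!(cand$dr == 0 & cand$dc == 0), ]
    cand <- cand[sample(nrow(cand)), ]
    placed <- FALSE
    for (k in seq_len(nrow(cand))) {
      nr <- r + cand$dr[k]; nc <- c + cand$dc[k]
      if (nr >= 1 && nr <= H && nc >= 1 && nc <= W &&
          !(paste(nr, nc) %in% seen)) {
        nodes <- rbind(nodes, c(nr, nc)); seen <- c(seen, paste(nr, nc))
        r <- nr; c <- nc; placed <- TRUE; break
      }
    }
    if (!placed) break
  }
  nodes
}
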