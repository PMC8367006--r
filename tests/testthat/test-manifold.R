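test_that("union k-NN graph matches hand-worked and brute-force oracles", {
  g <- buildKnnGraph(cbind(c(0, 1, 3)), 1)
  expect_identical(g@edges[order(g@edges[, 1]), , drop = FALSE],
                   cbind(i = c(1L, 2L), j = c(2L, 3L)))
  expect_true(g@connected)
  # complete graph when every point neighbours every other
  set.seed(1); X <- matrix(rnorm(12 * 2), 12)
  expect_equal(nrow(buildKnnGraph(X, 11)@edges), choose(12, 2))
  # brute-force union rule on 20 random points in R^5
  set.seed(2); X <- matrix(rnorm(20 * 5), 20)
  k <- 4
  D <- as.matrix(dist(X)); diag(D) <- Inf
  A <- matrix(FALSE, 20, 20)
  for (i in 1:20) A[i, order(D[i, ])[1:k]] <- TRUE
  A <- A | t(A)
  g <- buildKnnGraph(X, k)
  B <- matrix(FALSE, 20, 20)
  B[g@edges] <- TRUE; B <- B | t(B)
  expect_identical(B, A)
  expect_equal(g@distances, D[g@edges])
  expect_error(buildKnnGraph(X, 20), "more points")
})

test_that("weight matrices follow the heat-kernel and simple-minded rules", {
  X <- cbind(c(0, sqrt(2), 10))          # edge 1-2 has squared length 2
  g <- buildKnnGraph(X, 1)
  W <- weightMatrix(g, "heat", sigma = 1)
  expect_equal(W[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(W, Matrix::t(W))
  expect_error(weightMatrix(g, "heat", sigma = 0), "sigma")
  # simple-minded weights and degrees on the 3-point path
  g2 <- buildKnnGraph(cbind(c(0, 1, 3)), 1)
  Ws <- weightMatrix(g2, "simple")
  expect_equal(unname(Matrix::rowSums(Ws)), c(1, 2, 1))
  # sigma -> infinity converges to simple-minded
  Whuge <- weightMatrix(g2, "heat", sigma = 1e6)
  expect_lt(max(abs(Whuge - Ws)), 1e-6)
})

test_that("generalized eigenpairs match closed forms on tiny graphs", {
  # two nodes, one edge: eigenvalues {0, 2}; f proportional to (1, -1)
  W2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1)
  d2 <- spectralEmbed(W2, 1)
  expect_equal(d2$values, 2, tolerance = 1e-12)
  expect_equal(abs(d2$vectors[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_gt(d2$vectors[which.max(abs(d2$vectors[, 1])), 1], 0)  # sign rule
  # 3-node path: eigenvalues {0, 1, 2}; lambda = 1 has f prop. (1, 0, -1)
  W3 <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1)
  d3 <- spectralEmbed(W3, 2)
  expect_equal(d3$values, c(1, 2), tolerance = 1e-12)
  expect_equal(abs(d3$vectors[, 1]), abs(c(1, 0, -1)) / sqrt(2),
               tolerance = 1e-10)
  expect_lt(d3$vectors[1, 1] * d3$vectors[3, 1], 0)
  # f' D f = 1 for every retained eigenvector
  D3 <- diag(d3$degrees)
  for (j in 1:2)
    expect_equal(as.numeric(t(d3$vectors[, j]) %*% D3 %*% d3$vectors[, j]),
                 1, tolerance = 1e-12)
})

test_that("the spectral solve matches a dense generalized eigensolver", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30)
  for (scheme in c("simple", "heat")) {
    fit <- laplacianEigenmaps(X, nNeighbors = 5, m = 6, scheme = scheme,
                              sigma = if (scheme == "heat") 2 else NULL)
    W <- as.matrix(fit@W)
    d <- rowSums(W)
    L <- diag(d) - W
    # independent oracle: eigen of D^{-1} L (non-symmetric route)
    e <- eigen(diag(1 / d) %*% L)
    vals <- sort(Re(e$values))
    expect_lt(abs(vals[1]), 1e-10)
    expect_equal(fit@eigenvalues, vals[2:7], tolerance = 1e-8)
    # eigenvectors agree up to sign after D-normalization
    for (j in 1:6) {
      lam <- fit@eigenvalues[j]
      k <- which.min(abs(Re(e$values) - lam))
      v <- Re(e$vectors[, k])
      v <- v / sqrt(sum(d * v^2))
      f <- fit@vectors[, j]
      expect_lt(min(max(abs(f - v)), max(abs(f + v))), 1e-6)
    }
    # structural invariants: L rows sum to zero, lambda in (0, 2]
    expect_lt(max(abs(rowSums(L))), 1e-12)
    expect_true(all(fit@eigenvalues > 0 & fit@eigenvalues <= 2 + 1e-12))
  }
})

test_that("disconnected graphs are a hard error with guidance", {
  X <- rbind(matrix(rnorm(10 * 2, 0, 0.1), 10),
             matrix(rnorm(10 * 2, 50, 0.1), 10))
  expect_error(laplacianEigenmaps(X, nNeighbors = 3, m = 2),
               "not fully connected")
  g <- buildKnnGraph(X, 3)
  expect_false(g@connected)
  expect_error(spectralEmbed(weightMatrix(g, "simple"), 2), "connected")
})

test_that("embedding dimension bounds are enforced", {
  W3 <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1)
  expect_error(spectralEmbed(W3, 3), "m <= N - 1")
  expect_error(spectralEmbed(W3, 0), "1 <= m")
})

test_that("row permutation permutes the embedding without changing geometry", {
  set.seed(6)
  X <- matrix(rnorm(25 * 3), 25)
  fit <- laplacianEigenmaps(X, nNeighbors = 4, m = 3)
  set.seed(7); perm <- sample(25)
  fitP <- laplacianEigenmaps(X[perm, ], nNeighbors = 4, m = 3)
  expect_equal(fitP@eigenvalues, fit@eigenvalues, tolerance = 1e-10)
  Y <- embedCoords(fit); YP <- embedCoords(fitP)
  for (j in 1:3) {
    a <- Y[perm, j]; b <- YP[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  expect_equal(as.matrix(dist(YP)), as.matrix(dist(Y[perm, ])),
               tolerance = 1e-8)
})

test_that("heat-kernel embeddings converge to simple-minded as sigma grows", {
  set.seed(9)
  X <- matrix(rnorm(30 * 3), 30)
  fs <- laplacianEigenmaps(X, 5, 3, "simple")
  fh <- laplacianEigenmaps(X, 5, 3, "heat", sigma = 1e6)
  for (j in 1:3) {
    a <- embedCoords(fs)[, j]; b <- embedCoords(fh)[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-4)
  }
})
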