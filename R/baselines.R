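#' @include manifold.R
NULL

# Baseline embeddings compared against Laplacian Eigenmaps. PCA and LDA are
# library-backed (stats::prcomp, MASS::lda); LLE and ISOMAP are implemented
# here because no installed package offers them with an out-of-sample
# transform. Each fit returns an S4 model supporting embedCoords() and
# extendEmbedding().

setClass("PcaModel", slots = c(center = "numeric", rotation = "matrix",
                               coords = "matrix", m = "integer"))
setClass("LdaModel", slots = c(fit = "ANY", coords = "matrix", m = "integer"))
setClass("LleModel", slots = c(X = "matrix", nNeighbors = "integer",
                               coords = "matrix", m = "integer"))
setClass("IsomapModel", slots = c(X = "matrix", graph = "NeighborGraph",
                                  geo = "matrix", colMeansG2 = "numeric",
                                  eigenvalues = "numeric", vectors = "matrix",
                                  coords = "matrix", m = "integer"))

#' Principal-component embedding
#'
#' @param X points x features matrix (or \code{\linkS4class{FeatureMatrix}}).
#' @param m number of components.
#' @return a \code{PcaModel}.
#' @export
pcaEmbed <- function(X, m) {
  if (is(X, "FeatureMatrix")) X <- X@values
  m <- as.integer(m)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = m)
  new("PcaModel", center = p$center, rotation = p$rotation[, seq_len(m), drop = FALSE],
      coords = p$x[, seq_len(m), drop = FALSE], m = m)
}

#' Linear-discriminant embedding
#'
#' Supervised baseline; for c classes at most c - 1 discriminant axes exist,
#' so \code{m} may not exceed the number of classes minus one.
#'
#' @param X points x features matrix.
#' @param labels per-row class labels.
#' @param m number of discriminant axes.
#' @return an \code{LdaModel}.
#' @export
ldaEmbed <- function(X, labels, m) {
  if (is(X, "FeatureMatrix")) { labels <- X@labels; X <- X@values }
  m <- as.integer(m)
  nc <- length(unique(labels))
  if (m > nc - 1L)
    stop("ldaEmbed: the maximal dimension for LDA is equal to the number of ",
         "classes minus one (", nc - 1L, ")")
  fit <- MASS::lda(X, grouping = factor(labels))
  sc <- stats::predict(fit, X)$x[, seq_len(m), drop = FALSE]
  new("LdaModel", fit = fit, coords = sc, m = m)
}

#' Locally linear embedding
#'
#' Standard LLE: each point is reconstructed from its nNeighbors nearest
#' neighbours with weights summing to one (regularized local Gram solve);
#' the embedding is given by the bottom nonconstant eigenvectors of
#' (I - W)'(I - W). Out-of-sample points are mapped through their
#' reconstruction weights over the training set.
#'
#' @param X points x features matrix.
#' @param nNeighbors neighbourhood size.
#' @param m embedding dimension.
#' @return an \code{LleModel}.
#' @export
lleEmbed <- function(X, nNeighbors = 8, m = 2) {
  if (is(X, "FeatureMatrix")) X <- X@values
  X <- as.matrix(X); n <- nrow(X)
  nNeighbors <- as.integer(nNeighbors); m <- as.integer(m)
  if (n <= nNeighbors) stop("lleEmbed: need more points than neighbours")
  D <- .crossDist(X, X)
  Wm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- (seq_len(n))[-i][order(D[i, -i])[seq_len(nNeighbors)]]
    Wm[i, nb] <- .lleWeights(X[i, ], X[nb, , drop = FALSE])
  }
  M <- crossprod(diag(n) - Wm)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- rev(seq_len(n))[-1][seq_len(m)]      # skip the ~constant bottom vector
  Y <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(m)) if (Y[which.max(abs(Y[, j])), j] < 0) Y[, j] <- -Y[, j]
  new("LleModel", X = X, nNeighbors = nNeighbors, coords = Y, m = m)
}

.lleWeights <- function(x, nbX) {
  Z <- sweep(nbX, 2, x)
  G <- tcrossprod(Z)
  G <- G + diag(nrow(G)) * (1e-3 * sum(diag(G)) / nrow(G) + 1e-12)
  w <- solve(G, rep(1, nrow(G)))
  w / sum(w)
}

#' ISOMAP embedding
#'
#' Geodesic distances over the union k-NN graph (shortest paths) followed by
#' classical MDS of the squared geodesic distance matrix. Out-of-sample
#' points use the landmark formula: geodesics to the new point are estimated
#' through its nearest training neighbours and projected onto the MDS axes.
#'
#' @param X points x features matrix.
#' @param nNeighbors neighbourhood size for the graph.
#' @param m embedding dimension.
#' @return an \code{IsomapModel}.
#' @export
isomapEmbed <- function(X, nNeighbors = 8, m = 2) {
  if (is(X, "FeatureMatrix")) X <- X@values
  X <- as.matrix(X); m <- as.integer(m)
  graph <- buildKnnGraph(X, nNeighbors)
  if (!graph@connected) .connectivityError("isomapEmbed")
  g <- igraph::graph_from_edgelist(graph@edges, directed = FALSE)
  igraph::E(g)$weight <- graph@distances
  G <- igraph::distances(g)
  G2 <- G^2
  n <- nrow(G2)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% G2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- e$values[seq_len(m)]
  if (any(vals <= 0)) stop("isomapEmbed: fewer than m positive MDS eigenvalues")
  V <- e$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  Y <- V %*% diag(sqrt(vals), m)
  new("IsomapModel", X = X, graph = graph, geo = G,
      colMeansG2 = colMeans(G2), eigenvalues = vals, vectors = V,
      coords = Y, m = m)
}

#' @rdname embedCoords
#' @export
setMethod("embedCoords", "PcaModel", function(x) x@coords)
#' @rdname embedCoords
#' @export
setMethod("embedCoords", "LdaModel", function(x) x@coords)
#' @rdname embedCoords
#' @export
setMethod("embedCoords", "LleModel", function(x) x@coords)
#' @rdname embedCoords
#' @export
setMethod("embedCoords", "IsomapModel", function(x) x@coords)

#' @rdname extendEmbedding
#' @export
setMethod("extendEmbedding", "PcaModel", function(model, newX) {
  sweep(as.matrix(newX), 2, model@center) %*% model@rotation
})

#' @rdname extendEmbedding
#' @export
setMethod("extendEmbedding", "LdaModel", function(model, newX) {
  stats::predict(model@fit, as.matrix(newX))$x[, seq_len(model@m), drop = FALSE]
})

#' @rdname extendEmbedding
#' @export
setMethod("extendEmbedding", "LleModel", function(model, newX) {
  newX <- as.matrix(newX)
  D <- .crossDist(newX, model@X)
  Y <- matrix(0, nrow(newX), model@m)
  dupTol <- 1e-5 * (1 + max(abs(model@X)))
  for (i in seq_len(nrow(newX))) {
    if (min(D[i, ]) <= dupTol) {     # duplicate of a training point
      Y[i, ] <- model@coords[which.min(D[i, ]), ]
      next
    }
    nb <- order(D[i, ])[seq_len(model@nNeighbors)]
    w <- .lleWeights(newX[i, ], model@X[nb, , drop = FALSE])
    Y[i, ] <- w %*% model@coords[nb, , drop = FALSE]
  }
  Y
})

#' @rdname extendEmbedding
#' @export
setMethod("extendEmbedding", "IsomapModel", function(model, newX) {
  newX <- as.matrix(newX)
  D <- .crossDist(newX, model@X)
  k <- model@graph@nNeighbors
  Y <- matrix(0, nrow(newX), model@m)
  for (i in seq_len(nrow(newX))) {
    nb <- order(D[i, ])[seq_len(k)]
    gx <- apply(model@geo[nb, , drop = FALSE] + D[i, nb], 2, min)
    b <- 0.5 * (model@colMeansG2 - gx^2)
    Y[i, ] <- as.numeric(b %*% model@vectors) / sqrt(model@eigenvalues)
  }
  Y
})

#' Fit any of the package's embeddings by name
#'
#' Dispatcher used by the evaluation protocol. \code{"le"} is the bespoke
#' Laplacian Eigenmaps; \code{"pca"}, \code{"lda"}, \code{"lle"},
#' \code{"isomap"} are the baselines.
#'
#' @param X points x features matrix.
#' @param method one of "le", "pca", "lda", "lle", "isomap".
#' @param m embedding dimension.
#' @param nNeighbors graph neighbourhood size (le/lle/isomap).
#' @param scheme,sigma Laplacian Eigenmaps weight scheme.
#' @param labels class labels (required for "lda").
#' @return a fitted model supporting \code{embedCoords} and
#'   \code{extendEmbedding}.
#' @export
fitEmbedding <- function(X, method = c("le", "pca", "lda", "lle", "isomap"),
                         m = 2, nNeighbors = 8, scheme = "simple",
                         sigma = NULL, labels = NULL) {
  method <- match.arg(method)
  switch(method,
    le = laplacianEigenmaps(X, nNeighbors, m, scheme, sigma),
    pca = pcaEmbed(X, m),
    lda = {
      if (is.null(labels) && !is(X, "FeatureMatrix"))
        stop("fitEmbedding: lda requires labels")
      if (is(X, "FeatureMatrix")) ldaEmbed(X, m = m) else ldaEmbed(X, labels, m)
    },
    lle = lleEmbed(X, nNeighbors, m),
    isomap = isomapEmbed(X, nNeighbors, m))
}
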