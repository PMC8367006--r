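#' @include AllClasses.R AllGenerics.R utils.R
#' @importFrom Matrix sparseMatrix rowSums Diagonal
NULL

#' Build the union k-nearest-neighbour graph
#'
#' Nodes i and j are connected when i is among the \code{nNeighbors} nearest
#' neighbours of j or j is among the \code{nNeighbors} nearest neighbours of
#' i (Euclidean distance, ties broken towards the lower index). Connectivity
#' is computed and stored; downstream operations decide how to react to a
#' disconnected graph.
#'
#' @param X numeric matrix (points x features) or a
#'   \code{\linkS4class{FeatureMatrix}}.
#' @param nNeighbors neighbourhood size (the protocol's graph parameter k).
#' @return a \code{\linkS4class{NeighborGraph}}.
#' @export
buildKnnGraph <- function(X, nNeighbors) {
  if (is(X, "FeatureMatrix")) X <- X@values
  X <- as.matrix(X)
  n <- nrow(X)
  nNeighbors <- as.integer(nNeighbors)
  if (n <= nNeighbors)
    stop("buildKnnGraph: need more points (", n, ") than neighbours (",
         nNeighbors, ")")
  D <- .crossDist(X, X)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n)) {
    o <- order(D[i, -i])[seq_len(nNeighbors)]   # stable: ties -> lower index
    nb <- (seq_len(n))[-i][o]
    ei <- c(ei, rep.int(i, nNeighbors)); ej <- c(ej, nb)
  }
  a <- pmin(ei, ej); b <- pmax(ei, ej)
  keep <- !duplicated(cbind(a, b))
  edges <- cbind(i = a[keep], j = b[keep])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  conn <- igraph::components(g)$no == 1L && igraph::vcount(g) == n
  new("NeighborGraph", n = n, nNeighbors = nNeighbors, edges = edges,
      distances = D[cbind(edges[, 1], edges[, 2])], connected = conn)
}

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d nodes, %d edges (nNeighbors = %d), %s\n",
              object@n, nrow(object@edges), object@nNeighbors,
              if (object@connected) "connected" else "NOT connected"))
})

#' Edge weight matrix for a neighbour graph
#'
#' Simple-minded weights set W_ij = 1 on every edge; the heat kernel sets
#' W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2)) (an RBF kernel with
#' gamma = 1/(2 sigma^2)). As sigma grows the heat kernel converges to the
#' simple-minded scheme. Duplicate points (edge length 0) get heat weight 1.
#'
#' @param graph a \code{\linkS4class{NeighborGraph}}.
#' @param scheme "simple" or "heat".
#' @param sigma heat-kernel bandwidth, required (and > 0) for "heat".
#' @return symmetric sparse weight matrix (dgCMatrix).
#' @export
weightMatrix <- function(graph, scheme = c("simple", "heat"), sigma = NULL) {
  scheme <- match.arg(scheme)
  E <- graph@edges
  if (scheme == "heat") {
    if (is.null(sigma) || sigma <= 0)
      stop("weightMatrix: heat kernel requires sigma > 0")
    w <- exp(-graph@distances^2 / (2 * sigma^2))
  } else w <- rep(1, nrow(E))
  sparseMatrix(i = c(E[, 1], E[, 2]), j = c(E[, 2], E[, 1]),
               x = c(w, w), dims = c(graph@n, graph@n))
}

.connectivityError <- function(where) {
  stop(where, ": the neighbour graph is not fully connected. The spectral ",
       "embedding requires a connected graph (below ~100 ms windows the ",
       "adjacency graph of this kind of data stops being connected); ",
       "increase nNeighbors or use longer windows.", call. = FALSE)
}

#' Generalized spectral decomposition of a graph Laplacian
#'
#' Solves L f = lambda D f with L = D - W and D_ii = sum_j W_ji, drops the
#' zero eigenvalue (constant eigenvector), and returns the next \code{m}
#' eigenpairs in increasing eigenvalue order. Eigenvectors are normalized to
#' f' D f = 1 with the largest-magnitude entry positive, making the result
#' deterministic. The solve is performed on the symmetrically normalized
#' Laplacian I - D^{-1/2} W D^{-1/2}, whose eigenvalues lie in [0, 2].
#'
#' @param W symmetric (sparse or dense) weight matrix of a connected graph.
#' @param m number of embedding dimensions (1 <= m <= N - 1).
#' @return list with \code{values} (length m), \code{vectors} (N x m) and
#'   \code{degrees}.
#' @export
spectralEmbed <- function(W, m) {
  W <- methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix")
  n <- nrow(W)
  m <- as.integer(m)
  if (m < 1L || m >= n) stop("spectralEmbed: need 1 <= m <= N - 1")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::components(g)$no != 1L) .connectivityError("spectralEmbed")
  d <- as.numeric(rowSums(W))
  s <- 1 / sqrt(d)
  Ws <- as.matrix(W) * outer(s, s)
  Lsym <- diag(n) - Ws
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  ord <- rev(seq_len(n))                       # ascending eigenvalues
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (vals[1] > 1e-8)
    warning("spectralEmbed: smallest eigenvalue ", signif(vals[1], 3),
            " is not numerically zero")
  vals <- vals[-1][seq_len(m)]
  F_ <- vecs[, -1, drop = FALSE][, seq_len(m), drop = FALSE] * s
  # f' D f = 1 holds because the normalized eigenvectors u satisfy u'u = 1;
  # fix signs deterministically
  for (j in seq_len(m)) {
    i0 <- which.max(abs(F_[, j]))
    if (F_[i0, j] < 0) F_[, j] <- -F_[, j]
  }
  list(values = pmax(vals, 0), vectors = F_, degrees = d)
}

#' Fit a Laplacian Eigenmaps embedding
#'
#' The pipeline's core dimensionality reduction: build the union k-NN graph
#' on the feature vectors, weight it (simple-minded or heat kernel), and
#' solve the generalized eigenproblem L f = lambda D f, keeping the m
#' eigenvectors after the zero eigenvalue as embedding coordinates
#' x_i -> (f_1(i), ..., f_m(i)).
#'
#' @param X numeric matrix (points x features) or
#'   \code{\linkS4class{FeatureMatrix}}.
#' @param nNeighbors graph neighbourhood size (study default 8).
#' @param m embedding dimension.
#' @param scheme "simple" (default) or "heat".
#' @param sigma heat-kernel bandwidth when \code{scheme = "heat"}.
#' @return a \code{\linkS4class{SpectralModel}}.
#' @examples
#' X <- cbind(seq(0, 1, length.out = 30), 0)
#' fit <- laplacianEigenmaps(X, nNeighbors = 3, m = 2)
#' dim(embedCoords(fit))
#' @export
laplacianEigenmaps <- function(X, nNeighbors = 8, m = 2,
                               scheme = c("simple", "heat"), sigma = NULL) {
  scheme <- match.arg(scheme)
  if (is(X, "FeatureMatrix")) X <- X@values
  X <- as.matrix(X)
  graph <- buildKnnGraph(X, nNeighbors)
  if (!graph@connected) .connectivityError("laplacianEigenmaps")
  W <- weightMatrix(graph, scheme, sigma)
  dec <- spectralEmbed(W, m)
  new("SpectralModel", X = X, graph = graph, scheme = scheme,
      sigma = if (is.null(sigma)) NA_real_ else sigma, W = W,
      degrees = dec$degrees, eigenvalues = dec$values,
      vectors = dec$vectors, m = as.integer(m))
}

#' @rdname embedCoords
#' @export
setMethod("embedCoords", "SpectralModel", function(x) x@vectors)

setMethod("show", "SpectralModel", function(object) {
  cat(sprintf("SpectralModel: %d points -> %d dims, %s weights%s, nNeighbors = %d\n",
              nrow(object@X), object@m, object@scheme,
              if (object@scheme == "heat") sprintf(" (sigma = %g)", object@sigma)
              else "", object@graph@nNeighbors))
  cat(sprintf("  eigenvalues in [%.3g, %.3g]\n",
              min(object@eigenvalues), max(object@eigenvalues)))
})

#' Nystrom out-of-sample extension
#'
#' Maps new points into a fitted Laplacian Eigenmaps space without
#' re-solving the eigenproblem. Each new point x is connected to its
#' \code{nNeighbors} nearest training points with weights w_i under the
#' model's scheme; with d(x) = sum_i w_i, its j-th coordinate is
#' sum_i w_i f_j(i) / (d(x) (1 - lambda_j)). This row-identity form
#' reproduces a training point's own coordinate exactly when fed its stored
#' graph row, because W f = (1 - lambda) D f. A new point that coincides
#' exactly with a training point is assigned that point's coordinates (the
#' consistent limit of the extension; ties go to the lowest index).
#'
#' @param model a fitted \code{\linkS4class{SpectralModel}}.
#' @param newX numeric matrix of new points (rows), feature dimension
#'   matching the training data.
#' @return numeric matrix, rows are embedded coordinates in R^m.
#' @export
nystromExtend <- function(model, newX) {
  newX <- as.matrix(newX)
  if (ncol(newX) != ncol(model@X))
    stop("nystromExtend: new points have feature dimension ", ncol(newX),
         ", model was fitted on ", ncol(model@X))
  if (any(abs(1 - model@eigenvalues) < 1e-10))
    stop("nystromExtend: an eigenvalue equals 1; the extension is singular")
  k <- model@graph@nNeighbors
  D <- .crossDist(newX, model@X)
  nNew <- nrow(newX)
  Y <- matrix(0, nNew, model@m)
  dupTol <- 1e-5 * (1 + max(abs(model@X)))
  for (i in seq_len(nNew)) {
    if (min(D[i, ]) <= dupTol) {      # duplicate of a training point
      Y[i, ] <- model@vectors[which.min(D[i, ]), ]
      next
    }
    o <- order(D[i, ])[seq_len(k)]
    w <- if (model@scheme == "heat")
      exp(-D[i, o]^2 / (2 * model@sigma^2)) else rep(1, k)
    dx <- sum(w)
    if (dx == 0) stop("nystromExtend: zero total weight (isolated point)")
    Y[i, ] <- (w %*% model@vectors[o, , drop = FALSE]) /
      (dx * (1 - model@eigenvalues))
  }
  Y
}

#' @rdname extendEmbedding
#' @export
setMethod("extendEmbedding", "SpectralModel",
          function(model, newX) nystromExtend(model, newX))
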