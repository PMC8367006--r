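#' @include utils.R
NULL

#' Maximum-likelihood intrinsic dimension (Levina-Bickel)
#'
#' For each point, with T_j its distance to the j-th nearest neighbour, the
#' k-neighbour estimate is
#' \deqn{\hat m_k(x) = \left[\frac{1}{k-2}\sum_{j=1}^{k-1}
#'   \log\frac{T_k(x)}{T_j(x)}\right]^{-1}}
#' (the asymptotically unbiased normalization of the maximum-likelihood
#' estimator). Estimates are averaged over all points and then over
#' k in [nNeighbors - 2, nNeighbors], which stabilises the estimate against
#' the choice of neighbourhood size. Zero distances from duplicate points
#' are floored at a small epsilon (with a message).
#'
#' @param X points x features matrix.
#' @param nNeighbors largest neighbourhood size used (>= 2; at least 3 for
#'   the averaging window to span three values of k).
#' @return the estimated intrinsic dimension (positive real).
#' @examples
#' line <- cbind(seq(0, 1, length.out = 200), 0, 0)
#' estimateIntrinsicDim(line, 10)   # close to 1
#' @export
estimateIntrinsicDim <- function(X, nNeighbors = 10) {
  if (is(X, "FeatureMatrix")) X <- X@values
  X <- as.matrix(X)
  n <- nrow(X)
  nNeighbors <- as.integer(nNeighbors)
  if (nNeighbors < 2L || n <= nNeighbors)
    stop("estimateIntrinsicDim: need n > nNeighbors >= 2")
  D <- .crossDist(X, X)
  diag(D) <- Inf
  sortedD <- apply(D, 1, function(r) sort(r)[seq_len(nNeighbors)])  # k x n
  if (any(sortedD == 0)) {
    message("estimateIntrinsicDim: zero neighbour distances (duplicate ",
            "points) floored at epsilon")
    eps <- max(sortedD) * 1e-12
    sortedD[sortedD == 0] <- eps
  }
  logD <- log(sortedD)
  ks <- max(2L, nNeighbors - 2L):nNeighbors
  est <- vapply(ks, function(k) {
    # sum_j log(T_k/T_j), with the asymptotically unbiased k-2 normalization
    S <- (k - 1) * logD[k, ] - colSums(logD[seq_len(k - 1L), , drop = FALSE])
    mean((k - 2) / S)
  }, numeric(1))
  mean(est)
}
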