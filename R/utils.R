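# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code does not disturb user RNG.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# All-pairs Euclidean cross-distances, rows of A vs rows of B.
.crossDist <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Sample index from an event time, rounding half-up (1-based).
.eventIndex <- function(timeS, rateHz) as.integer(floor(timeS * rateHz + 0.5)) + 1L

# Stratified assignment of indices to nFolds folds (or a single test split
# when testFraction is given). Returns a list of integer index vectors.
.stratifiedFolds <- function(labels, nFolds) {
  folds <- vector("list", nFolds)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    bins <- rep_len(seq_len(nFolds), length(idx))
    for (f in seq_len(nFolds))
      folds[[f]] <- c(folds[[f]], idx[bins == f])
  }
  lapply(folds, sort)
}

.stratifiedTestSplit <- function(labels, testFraction) {
  test <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTest <- max(1L, round(length(idx) * testFraction))
    if (nTest >= length(idx))
      stop("class ", cl, " too small for a ", testFraction, " test split")
    test <- c(test, sample(idx, nTest))
  }
  sort(test)
}
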