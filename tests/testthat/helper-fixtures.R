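# shared fixture builders; everything is generated in code at test time

# Three well-separated Gaussian blobs as a FeatureMatrix (one "subject"),
# labelled with the weight classes. Separable by construction.
blobFeatures <- function(nPer = c(23, 31, 19), d = 6, sep = 10, sd = 0.3,
                         seed = 1, subject = "s1") {
  set.seed(seed)
  centers <- matrix(rnorm(3 * d), 3, d)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  labs <- rep(c(165L, 330L, 660L), nPer)
  X <- centers[rep(1:3, nPer), ] + matrix(rnorm(sum(nPer) * d, 0, sd),
                                          sum(nPer), d)
  new("FeatureMatrix", values = X, labels = labs,
      subjectIds = rep(subject, sum(nPer)), layout = list())
}

# Small synthetic cohort at reduced rate/duration for unit tests.
tinyCohort <- function(nSubjects = 1, counts = c(7L, 9L, 6L), rate = 1200,
                       dur = 2.5, noiseSd = 0.05, seed = 1, ...) {
  simulateCohort(simConfig(
    nSubjects = nSubjects,
    classCounts = matrix(rep(counts, each = nSubjects), nSubjects),
    samplingRate = rate, trialDuration = dur, noiseSd = noiseSd,
    seed = seed, ...))
}

# A single valid trial with chosen dimensions.
mkTrial <- function(nCh = 2, n = 300, rate = 100, weight = 330, seed = 1,
                    events = NULL, subjectId = "s1", trialIndex = 0L) {
  set.seed(seed)
  dur <- n / rate
  if (is.null(events))
    events <- c(led_on = 0.05 * dur, touch_onset = 0.3 * dur,
                led_off = 0.8 * dur)
  EmgTrial(matrix(rnorm(nCh * n), nCh), rate, weight, events,
           subjectId = subjectId, trialIndex = trialIndex)
}

# 2-D point-in-convex-hull with a relative tolerance (fraction of the
# embedding diameter); tol = 0 is strict membership.
inHull2d <- function(p, H, tol = 0) {
  ch <- chull(H)
  P <- H[ch, , drop = FALSE]
  n <- nrow(P)
  if (n < 3) return(TRUE)
  cen <- colMeans(P)
  for (i in seq_len(n)) {
    a <- P[i, ]; b <- P[if (i == n) 1 else i + 1, ]
    e <- b - a
    nrm <- c(e[2], -e[1])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-300) next
    nrm <- nrm / len
    if (sum((cen - a) * nrm) > 0) nrm <- -nrm
    if (sum((p - a) * nrm) > tol) return(FALSE)
  }
  TRUE
}

# Trustworthiness of an embedding (rank-based neighbourhood preservation).
trustworthiness <- function(X, Y, k = 8) {
  n <- nrow(X)
  DX <- as.matrix(dist(X)); DY <- as.matrix(dist(Y))
  diag(DX) <- Inf; diag(DY) <- Inf
  rankX <- t(apply(DX, 1, rank))
  s <- 0
  for (i in seq_len(n)) {
    nbY <- order(DY[i, ])[seq_len(k)]
    nbX <- order(DX[i, ])[seq_len(k)]
    U <- setdiff(nbY, nbX)
    if (length(U)) s <- s + sum(rankX[i, U] - k)
  }
  1 - 2 * s / (n * k * (2 * n - 3 * k - 1))
}

macroF1of <- function(rep) unname(rep@scores$macro["f1"])
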