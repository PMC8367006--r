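#' @include classify.R baselines.R
NULL

.fitBySpec <- function(X, labels, embedding) {
  fitEmbedding(X, method = embedding$method,
               m = min(embedding$m, nrow(X) - 2L),
               nNeighbors = embedding$nNeighbors,
               scheme = if (is.null(embedding$scheme)) "simple" else embedding$scheme,
               sigma = embedding$sigma, labels = labels)
}

#' Embedding specification used by the evaluation protocol
#'
#' @param method "le", "pca", "lda", "lle" or "isomap".
#' @param nNeighbors graph neighbourhood size.
#' @param m embedding dimension (clamped to N - 2 at fit time).
#' @param scheme,sigma Laplacian Eigenmaps weighting.
#' @return a plain list understood by \code{\link{evaluateSubject}}.
#' @export
embeddingSpec <- function(method = "le", nNeighbors = 8, m = 10,
                          scheme = "simple", sigma = NULL) {
  list(method = method, nNeighbors = as.integer(nNeighbors),
       m = as.integer(m), scheme = scheme, sigma = sigma)
}

#' Evaluate one subject under the study protocol
#'
#' Stratified 90/10 train/test split; optional grid search by stratified
#' 10-fold cross-validation on the training set only; final embedding fitted
#' on the full training set; test trials mapped through the embedding's
#' out-of-sample transform (Nystrom for LE) and classified; per-class and
#' macro F1 on the held-out 10%. An audit log records which row indices each
#' stage touched, so absence of test-set leakage is checkable.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}} holding one
#'   subject's trials (>= 20).
#' @param embedding an \code{\link{embeddingSpec}}.
#' @param classifier a \code{\linkS4class{ClassifierSpec}}.
#' @param testFraction held-out fraction (study value 0.1).
#' @param nFolds cross-validation folds (study value 10).
#' @param grid optional grid axes for \code{\link{gridSearch}}; when given,
#'   the selected cell overrides \code{embedding}'s nNeighbors/sigma/m.
#' @param seed integer controlling the split and folds.
#' @return an \code{\linkS4class{EvalReport}}.
#' @export
evaluateSubject <- function(features, embedding = embeddingSpec(),
                            classifier = classifierSpec("knn"),
                            testFraction = 0.1, nFolds = 10, grid = NULL,
                            seed = 1) {
  if (length(unique(features@subjectIds)) != 1L)
    stop("evaluateSubject: features must hold exactly one subject")
  n <- nrow(features@values)
  if (n < 20L) stop("evaluateSubject: need at least 20 trials, got ", n)
  labels <- features@labels
  testIdx <- .withSeed(seed, .stratifiedTestSplit(labels, testFraction))
  trainIdx <- setdiff(seq_len(n), testIdx)
  audit <- list(train = trainIdx, test = testIdx, gridRows = integer(0))
  gridTab <- data.frame()
  if (!is.null(grid)) {
    gs <- gridSearch(features, rows = trainIdx, embedding = embedding,
                     classifier = classifier, nNeighborsGrid = grid$nNeighbors,
                     sigmaGrid = grid$sigma, mGrid = grid$m,
                     nFolds = nFolds, seed = seed + 1L)
    embedding$nNeighbors <- gs@best$nNeighbors
    embedding$m <- gs@best$m
    if (classifier@kind == "knn")   # one k drives graph and classifier alike
      classifier@knnK <- as.integer(gs@best$nNeighbors)
    if (!is.null(gs@best$sigma) && !is.na(gs@best$sigma))
      embedding$sigma <- gs@best$sigma
    gridTab <- gs@table
    audit$gridRows <- trainIdx
  }
  Xtr <- features@values[trainIdx, , drop = FALSE]
  fit <- .fitBySpec(Xtr, labels[trainIdx], embedding)
  Ytr <- embedCoords(fit)
  Yte <- extendEmbedding(fit, features@values[testIdx, , drop = FALSE])
  pred <- classify(Ytr, labels[trainIdx], Yte, classifier)
  sc <- f1Scores(labels[testIdx], pred, classes = sort(unique(labels)))
  new("EvalReport", subjectId = features@subjectIds[1], scores = sc,
      params = list(embedding = embedding, classifier = classifier@kind),
      protocol = list(trainFraction = 1 - testFraction,
                      testFraction = testFraction, nFolds = nFolds),
      audit = audit, grid = gridTab)
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport %s: macro F1 = %.3f (P %.3f, R %.3f), %s + %s\n",
              object@subjectId, object@scores$macro["f1"],
              object@scores$macro["precision"], object@scores$macro["recall"],
              object@params$embedding$method, object@params$classifier))
})

#' Grid search over embedding hyperparameters
#'
#' Exhaustive evaluation of (nNeighbors, sigma, m) cells by mean
#' cross-validated macro F1 on the supplied rows. For each
#' (nNeighbors, sigma) the embedding is solved once per fold at the largest
#' m and truncated for smaller m. Cells whose neighbour graph is
#' disconnected in some fold are recorded as failed and excluded from the
#' argmax. Ties prefer smaller m, then smaller nNeighbors, then smaller
#' sigma.
#'
#' The default axes follow the study protocol: nNeighbors 4..20, sigma in
#' {0.1, 1, 10, 100, 1000} (heat kernel only), m in 1, 5, 10, ...
#'
#' @param features a \code{\linkS4class{FeatureMatrix}}.
#' @param rows row indices to use (training set); defaults to all rows.
#' @param embedding base \code{\link{embeddingSpec}} (method and scheme).
#' @param classifier a \code{\linkS4class{ClassifierSpec}}.
#' @param nNeighborsGrid,sigmaGrid,mGrid grid axes; \code{sigmaGrid} is
#'   ignored unless the embedding scheme is "heat".
#' @param nFolds stratified CV folds.
#' @param seed integer seed for the folds.
#' @return a \code{GridResult} with slots \code{table} (all cells) and
#'   \code{best} (selected cell as a list).
#' @export
gridSearch <- function(features, rows = NULL, embedding = embeddingSpec(),
                       classifier = classifierSpec("knn"),
                       nNeighborsGrid = 4:20, sigmaGrid = NULL,
                       mGrid = c(1, seq(5, 30, by = 5)), nFolds = 10,
                       seed = 1) {
  if (is.null(rows)) rows <- seq_len(nrow(features@values))
  X <- features@values[rows, , drop = FALSE]
  labels <- features@labels[rows]
  useSigma <- identical(embedding$scheme, "heat")
  if (!useSigma) sigmaGrid <- NA_real_
  if (is.null(sigmaGrid)) sigmaGrid <- c(0.1, 1, 10, 100, 1000)
  folds <- .withSeed(seed, .stratifiedFolds(labels, nFolds))
  sizes <- vapply(folds, length, integer(1))
  if (any(vapply(folds, function(f) length(unique(labels[f])), integer(1)) <
          length(unique(labels))))
    warning("gridSearch: some folds miss a class; macro F1 uses present classes")
  mGrid <- sort(unique(pmin(mGrid, length(labels) - max(sizes) - 2L)))
  cells <- expand.grid(nNeighbors = nNeighborsGrid, sigma = sigmaGrid,
                       m = NA_real_)
  tab <- NULL
  for (ci in seq_len(nrow(cells))) {
    k <- cells$nNeighbors[ci]; sg <- cells$sigma[ci]
    foldF1 <- matrix(NA_real_, nFolds, length(mGrid))
    failed <- FALSE; reason <- ""
    for (f in seq_len(nFolds)) {
      hold <- folds[[f]]
      tri <- setdiff(seq_along(labels), hold)
      res <- tryCatch({
        fit <- .fitBySpec(X[tri, , drop = FALSE], labels[tri],
                          list(method = embedding$method, nNeighbors = k,
                               m = max(mGrid), scheme = embedding$scheme,
                               sigma = if (useSigma) sg else NULL))
        Yh <- extendEmbedding(fit, X[hold, , drop = FALSE])
        Yt <- embedCoords(fit)
        clf <- classifier
        if (clf@kind == "knn")      # the search couples both uses of k
          clf@knnK <- as.integer(min(k, length(tri)))
        vapply(seq_along(mGrid), function(mi) {
          mm <- min(mGrid[mi], ncol(Yt))
          pred <- classify(Yt[, seq_len(mm), drop = FALSE], labels[tri],
                           Yh[, seq_len(mm), drop = FALSE], clf)
          unname(f1Scores(labels[hold], pred)$macro["f1"])
        }, numeric(1))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- TRUE; reason <- conditionMessage(res); break
      }
      foldF1[f, ] <- res
    }
    tab <- rbind(tab, data.frame(
      nNeighbors = k, sigma = sg, m = mGrid,
      meanF1 = if (failed) NA_real_ else colMeans(foldF1),
      failed = failed, reason = reason))
  }
  ok <- tab[!tab$failed, , drop = FALSE]
  if (nrow(ok) == 0) stop("gridSearch: every grid cell failed")
  ok <- ok[order(-ok$meanF1, ok$m, ok$nNeighbors, ok$sigma), ]
  new("GridResult", table = tab, best = as.list(ok[1, ]))
}

setClass("GridResult", slots = c(table = "data.frame", best = "list"))
setMethod("show", "GridResult", function(object) {
  b <- object@best
  cat(sprintf("GridResult: %d cells; best nNeighbors=%d sigma=%s m=%d (mean CV F1 %.3f)\n",
              nrow(object@table), b$nNeighbors,
              if (is.na(b$sigma)) "-" else format(b$sigma), b$m, b$meanF1))
})

#' Evaluate every subject of a feature matrix
#'
#' Runs \code{\link{evaluateSubject}} per subject and aggregates macro F1 as
#' mean and standard error over subjects (SE = sd/sqrt(n)).
#'
#' @param features a multi-subject \code{\linkS4class{FeatureMatrix}}.
#' @inheritParams evaluateSubject
#' @return list with \code{perSubject} data.frame (subject, macroF1) and
#'   \code{meanF1}, \code{seF1}.
#' @export
evaluateCohort <- function(features, embedding = embeddingSpec(),
                           classifier = classifierSpec("knn"),
                           testFraction = 0.1, nFolds = 10, grid = NULL,
                           seed = 1) {
  ids <- unique(features@subjectIds)
  f1 <- vapply(seq_along(ids), function(i) {
    keep <- features@subjectIds == ids[i]
    sub <- new("FeatureMatrix", values = features@values[keep, , drop = FALSE],
               labels = features@labels[keep],
               subjectIds = features@subjectIds[keep],
               layout = features@layout)
    rep <- evaluateSubject(sub, embedding, classifier, testFraction, nFolds,
                           grid, seed = seed + i)
    unname(rep@scores$macro["f1"])
  }, numeric(1))
  list(perSubject = data.frame(subject = ids, macroF1 = f1),
       meanF1 = mean(f1), seF1 = stats::sd(f1) / sqrt(length(f1)))
}

#' Compare decoding methods across subjects
#'
#' One-way repeated-measures ANOVA (subjects as blocks) on a complete
#' subjects x methods score matrix, all pairwise paired t-tests, and
#' Shapiro-Wilk normality checks of the pairwise differences.
#'
#' @param scores numeric matrix, subjects x methods, no missing cells.
#' @return list with \code{anova} (F, df, p), \code{pairwise} (data.frame of
#'   paired t-tests) and \code{shapiro} (data.frame of normality tests).
#' @export
compareMethods <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L || nrow(scores) < 3L)
    stop("compareMethods: need >= 2 methods and >= 3 subjects")
  if (any(!is.finite(scores)))
    stop("compareMethods: missing cells are not allowed (no imputation)")
  methods_ <- colnames(scores)
  if (is.null(methods_)) methods_ <- paste0("m", seq_len(ncol(scores)))
  long <- data.frame(
    score = as.numeric(scores),
    method = factor(rep(methods_, each = nrow(scores))),
    subject = factor(rep(seq_len(nrow(scores)), ncol(scores))))
  fit <- stats::aov(score ~ method + Error(subject), data = long)
  s <- summary(fit)[["Error: Within"]][[1]]
  anova <- list(F = s["method", "F value"], df1 = s["method", "Df"],
                df2 = s["Residuals", "Df"], p = s["method", "Pr(>F)"])
  pw <- NULL; sh <- NULL
  for (a in seq_len(ncol(scores) - 1)) for (b in (a + 1):ncol(scores)) {
    tt <- stats::t.test(scores[, a], scores[, b], paired = TRUE)
    pw <- rbind(pw, data.frame(method1 = methods_[a], method2 = methods_[b],
                               t = unname(tt$statistic),
                               df = unname(tt$parameter),
                               p = tt$p.value))
    d <- scores[, a] - scores[, b]
    shp <- if (stats::sd(d) > 0) stats::shapiro.test(d)
           else list(statistic = NA_real_, p.value = NA_real_)
    sh <- rbind(sh, data.frame(pair = paste(methods_[a], methods_[b], sep = "-"),
                               W = unname(shp$statistic), p = shp$p.value))
  }
  list(anova = anova, pairwise = pw, shapiro = sh)
}
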