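#' @include AllClasses.R utils.R
NULL

#' Construct a classifier specification
#'
#' @param kind "knn", "linear_svm", "rbf_svm" or "random_forest".
#' @param knnK neighbours for k-NN (study value 8).
#' @param svmC SVM cost parameter (study value 32).
#' @param svmGamma RBF-SVM kernel gamma (study value 0.01).
#' @param rfTrees number of random-forest trees.
#' @param seed integer seed controlling classifier randomness.
#' @return a \code{\linkS4class{ClassifierSpec}}.
#' @export
classifierSpec <- function(kind = c("knn", "linear_svm", "rbf_svm",
                                    "random_forest"),
                           knnK = 8, svmC = 32, svmGamma = 0.01,
                           rfTrees = 100, seed = 1) {
  new("ClassifierSpec", kind = match.arg(kind), knnK = as.integer(knnK),
      svmC = as.numeric(svmC), svmGamma = as.numeric(svmGamma),
      rfTrees = as.integer(rfTrees), seed = as.integer(seed))
}

#' Per-class and macro precision, recall and F1
#'
#' One-vs-rest TP/FP/FN per class; per-class F1 is the harmonic mean
#' 2 P R / (P + R) with precision = TP/(TP+FP) and recall = TP/(TP+FN).
#' The macro scores are unweighted means over classes, the standard choice
#' for imbalanced multiclass problems. A class absent from both the true and
#' the predicted labels has no defined F1 and is excluded from the macro
#' average with a message.
#'
#' @param trueLabels,predictedLabels equal-length label vectors.
#' @param classes optional class set; defaults to the classes present.
#' @return list with \code{perClass} (data.frame: class, tp, fp, fn,
#'   precision, recall, f1, support) and \code{macro} (named numeric:
#'   precision, recall, f1).
#' @examples
#' f1Scores(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
f1Scores <- function(trueLabels, predictedLabels, classes = NULL) {
  if (length(trueLabels) != length(predictedLabels))
    stop("f1Scores: label vectors must have equal length")
  if (is.null(classes))
    classes <- sort(unique(c(trueLabels, predictedLabels)))
  tab <- data.frame(class = classes, tp = NA_real_, fp = NA_real_,
                    fn = NA_real_, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, support = NA_real_)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(trueLabels == cl & predictedLabels == cl)
    fp <- sum(trueLabels != cl & predictedLabels == cl)
    fn <- sum(trueLabels == cl & predictedLabels != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tab[i, -1] <- c(tp, fp, fn, prec, rec, f1, tp + fn)
    if (tp + fp + fn == 0) {
      message("f1Scores: class ", cl, " absent from both label sets; ",
              "excluded from the macro average")
      tab[i, c("precision", "recall", "f1")] <- NA_real_
    }
  }
  keep <- !is.na(tab$f1)
  list(perClass = tab,
       macro = c(precision = mean(tab$precision[keep]),
                 recall = mean(tab$recall[keep]),
                 f1 = mean(tab$f1[keep])))
}

#' Bespoke k-nearest-neighbour classifier
#'
#' Euclidean majority vote over the k nearest training points. Vote ties are
#' broken towards the tied label with the smallest summed neighbour
#' distance, then towards the lower label; the result is deterministic.
#'
#' @param trainX,trainY training coordinates and labels.
#' @param testX points to classify.
#' @param k number of neighbours.
#' @return vector of predicted labels (same type as \code{trainY}).
#' @export
knnClassify <- function(trainX, trainY, testX, k = 8) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  if (nrow(trainX) < k)
    stop("knnClassify: fewer training points (", nrow(trainX),
         ") than neighbours (", k, ")")
  D <- .crossDist(testX, trainX)
  lv <- sort(unique(trainY))
  pred <- vapply(seq_len(nrow(testX)), function(i) {
    o <- order(D[i, ])[seq_len(k)]
    labs <- trainY[o]
    votes <- vapply(lv, function(l) sum(labs == l), numeric(1))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      sums <- vapply(lv[top], function(l) sum(D[i, o][labs == l]), numeric(1))
      top <- top[order(sums, lv[top])][1]      # distance sum, then lower label
    }
    which(lv == lv[top[1]])
  }, integer(1))
  lv[pred]
}

#' Classify embedded trials
#'
#' k-NN is the package's own implementation; linear/RBF SVM are backed by
#' e1071 (cost and gamma defaults follow the study: C = 32, gamma = 0.01)
#' and random forest by randomForest, both seeded for determinism.
#'
#' @param trainX,trainY training coordinates and labels.
#' @param testX points to classify.
#' @param spec a \code{\linkS4class{ClassifierSpec}}.
#' @return predicted labels.
#' @export
classify <- function(trainX, trainY, testX, spec = classifierSpec("knn")) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  if (ncol(trainX) != ncol(testX))
    stop("classify: coordinate dimensions differ between train and test")
  y <- factor(trainY)
  out <- switch(spec@kind,
    knn = return(knnClassify(trainX, trainY, testX, spec@knnK)),
    linear_svm = {
      fit <- e1071::svm(trainX, y, kernel = "linear", cost = spec@svmC,
                        scale = FALSE)
      stats::predict(fit, testX)
    },
    rbf_svm = {
      fit <- e1071::svm(trainX, y, kernel = "radial", cost = spec@svmC,
                        gamma = spec@svmGamma, scale = FALSE)
      stats::predict(fit, testX)
    },
    random_forest = .withSeed(spec@seed, {
      fit <- randomForest::randomForest(trainX, y, ntree = spec@rfTrees)
      stats::predict(fit, testX)
    }))
  lv <- as.character(out)
  if (is.numeric(trainY)) as(lv, class(trainY)) else lv
}
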