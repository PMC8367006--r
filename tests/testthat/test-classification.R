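test_that("F1 scores match the hand-evaluated confusion oracle", {
  # perfect predictions
  y <- rep(c(165, 330, 660), times = c(5, 4, 3))
  expect_equal(unname(f1Scores(y, y)$macro["f1"]), 1)
  # binary confusion: true A -> 5 A + 1 B; true B -> 2 A + 4 B
  ytrue <- c(rep("A", 6), rep("B", 6))
  ypred <- c(rep("A", 5), "B", "A", "A", rep("B", 4))
  sc <- f1Scores(ytrue, ypred)
  expect_equal(sc$perClass$f1[sc$perClass$class == "A"], 50 / 65)
  expect_equal(sc$perClass$f1[sc$perClass$class == "B"], 8 / 11)
  expect_equal(unname(sc$macro["f1"]), mean(c(50 / 65, 8 / 11)))
  # precision = recall = p for every class implies macro F1 = p
  yt <- rep(1:3, each = 10)
  yp <- yt
  yp[c(1, 11, 21)] <- c(2, 3, 1)     # symmetric confusion, P = R = 0.9
  sc2 <- f1Scores(yt, yp)
  expect_equal(unname(sc2$macro["f1"]), 0.9)
  # class absent from both sides is excluded with a message
  expect_message(sc3 <- f1Scores(c(1, 1, 2), c(1, 1, 2), classes = 1:3),
                 "absent")
  expect_true(is.na(sc3$perClass$f1[3]))
  expect_equal(unname(sc3$macro["f1"]), 1)
})

test_that("macro F1 is invariant to class relabelling", {
  set.seed(2)
  yt <- sample(c(165, 330, 660), 60, replace = TRUE)
  yp <- sample(c(165, 330, 660), 60, replace = TRUE)
  m <- c(`165` = "x", `330` = "y", `660` = "z")
  a <- f1Scores(yt, yp)$macro["f1"]
  b <- f1Scores(m[as.character(yt)], m[as.character(yp)])$macro["f1"]
  expect_equal(unname(a), unname(b))
})

test_that("k-NN votes match a brute-force oracle and break ties stably", {
  # k = 1 on a training point returns that point's label
  X <- matrix(c(0, 0, 1, 1, 5, 5), 3, byrow = TRUE)
  expect_equal(knnClassify(X, c(165L, 330L, 660L), X[2, , drop = FALSE], 1),
               330L)
  # two well-separated blobs: zero test errors
  set.seed(3)
  tr <- rbind(matrix(rnorm(100, 0, 0.1), 50), matrix(rnorm(100, 10, 0.1), 50))
  y <- rep(c(1L, 2L), each = 50)
  te <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 10, 0.1), 20))
  expect_equal(knnClassify(tr, y, te, 8), rep(c(1L, 2L), each = 20))
  # brute-force majority vote on 50 random points
  set.seed(4)
  Xtr <- matrix(rnorm(50 * 3), 50)
  ytr <- sample(c(165L, 330L, 660L), 50, replace = TRUE)
  Xte <- matrix(rnorm(20 * 3), 20)
  pred <- knnClassify(Xtr, ytr, Xte, 5)
  for (i in 1:20) {
    d <- sqrt(colSums((t(Xtr) - Xte[i, ])^2))
    nb <- order(d)[1:5]
    votes <- table(ytr[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) expect_equal(as.character(pred[i]), top)
    else expect_true(as.character(pred[i]) %in% top)
  }
  # vote tie resolved by smaller summed distance, then lower label
  trX <- rbind(c(0, 0), c(0.4, 0), c(10, 0), c(10.1, 0))
  trY <- c(165L, 165L, 330L, 330L)
  # at x = 5 the 165-pair is nearer in total (5 + 4.6 < 5 + 5.1)
  expect_equal(knnClassify(trX, trY, rbind(c(5, 0)), 4), 165L)
  # at x = 5.2 the 330-pair is nearer in total
  expect_equal(knnClassify(trX, trY, rbind(c(5.2, 0)), 4), 330L)
  expect_error(knnClassify(trX, trY, rbind(c(0, 0)), 9), "fewer training")
})

test_that("SVM and random-forest backends separate blobs deterministically", {
  fm <- blobFeatures(nPer = c(20, 20, 20), d = 4, sep = 8, seed = 5)
  set.seed(6)
  teIdx <- unlist(lapply(split(seq_len(60), fm@labels), sample, size = 5))
  trIdx <- setdiff(seq_len(60), teIdx)
  for (kind in c("linear_svm", "rbf_svm", "random_forest")) {
    spec <- classifierSpec(kind, seed = 7)
    p1 <- classify(fm@values[trIdx, ], fm@labels[trIdx],
                   fm@values[teIdx, ], spec)
    p2 <- classify(fm@values[trIdx, ], fm@labels[trIdx],
                   fm@values[teIdx, ], spec)
    expect_identical(p1, p2)
    expect_gte(mean(p1 == fm@labels[teIdx]), 0.9)
  }
  expect_error(classifierSpec("knn", svmC = -1), "positive")
})
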