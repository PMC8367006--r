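test_that("the subject protocol scores a separable fixture perfectly", {
  fm <- blobFeatures(nPer = c(23, 31, 19), d = 8, sep = 12, sd = 0.3,
                     seed = 1)
  rep <- evaluateSubject(fm, embeddingSpec("le", 35, 2),
                         classifierSpec("knn", 8), seed = 2)
  expect_equal(macroF1of(rep), 1)
  expect_equal(rep@protocol$trainFraction, 0.9)
  expect_equal(rep@protocol$testFraction, 0.1)
  expect_equal(rep@protocol$nFolds, 10)
  # audit: train and test are disjoint and cover all rows
  expect_length(intersect(rep@audit$train, rep@audit$test), 0)
  expect_setequal(c(rep@audit$train, rep@audit$test), seq_len(73))
  expect_error(evaluateSubject(blobFeatures(nPer = c(3, 3, 3))), "20 trials")
})

test_that("label shuffling drops scores into the chance band", {
  fm <- blobFeatures(nPer = c(23, 31, 19), d = 6, sep = 10, seed = 3)
  set.seed(4)
  f1s <- vapply(1:20, function(i) {
    sh <- fm
    sh@labels <- sample(fm@labels)
    macroF1of(evaluateSubject(sh, embeddingSpec("le", 35, 2),
                              classifierSpec("knn", 8), seed = i))
  }, numeric(1))
  expect_gte(mean(f1s), 0.15)
  expect_lte(mean(f1s), 0.55)
})

test_that("grid search selects sensibly and audits cleanly", {
  fm <- blobFeatures(nPer = c(12, 12, 12), d = 5, sep = 10, seed = 5)
  # single-cell grid returns that cell
  gs1 <- gridSearch(fm, embedding = embeddingSpec("le", 8, 2),
                    nNeighborsGrid = 20, mGrid = 2, nFolds = 5, seed = 1)
  expect_equal(gs1@best$nNeighbors, 20)
  expect_equal(gs1@best$m, 2)
  expect_equal(nrow(gs1@table), 1)
  # grid-driven evaluation touches only training rows before scoring
  rep <- evaluateSubject(blobFeatures(nPer = c(10, 12, 9), seed = 6),
                         embeddingSpec("le", 15, 2), classifierSpec("knn", 5),
                         grid = list(nNeighbors = c(15, 18), sigma = NULL,
                                     m = c(1, 2)),
                         nFolds = 5, seed = 7)
  expect_length(intersect(rep@audit$gridRows, rep@audit$test), 0)
  expect_gt(nrow(rep@grid), 0)
})

test_that("grid argmax lands at the smallest neighbourhood when larger ones degrade", {
  # labels in contiguous blocks along a chain: growing neighbourhoods pull
  # in ever more cross-block votes, so CV F1 degrades with nNeighbors
  set.seed(8)
  X <- cbind(c(0:8, 10.5 + 0:8, 21 + 0:8),
             matrix(rnorm(27 * 2, 0, 0.05), 27))
  fm <- new("FeatureMatrix", values = X,
            labels = rep(c(165L, 330L, 660L), each = 9),
            subjectIds = rep("s1", 27), layout = list())
  gs <- gridSearch(fm, embedding = embeddingSpec("le", 8, 2),
                   nNeighborsGrid = c(4, 8, 14), mGrid = 2, nFolds = 3,
                   seed = 9)
  ok <- gs@table[!gs@table$failed, ]
  expect_equal(gs@best$nNeighbors, min(ok$nNeighbors))
  expect_true(all(diff(ok$meanF1[order(ok$nNeighbors)]) <= 0))
})

test_that("failed grid cells are recorded and excluded from the argmax", {
  # two far-apart clusters per class make small-k graphs disconnected
  set.seed(10)
  X <- rbind(matrix(rnorm(30 * 3, 0, 0.05), 30),
             matrix(rnorm(30 * 3, 100, 0.05), 30))
  fm <- new("FeatureMatrix", values = X,
            labels = rep(c(165L, 330L, 660L), 20),
            subjectIds = rep("s1", 60), layout = list())
  gs <- gridSearch(fm, embedding = embeddingSpec("le", 8, 1),
                   nNeighborsGrid = c(4, 25), mGrid = 1, nFolds = 3,
                   seed = 11)
  expect_true(any(gs@table$failed))
  expect_false(gs@best$nNeighbors %in% gs@table$nNeighbors[gs@table$failed])
})

test_that("cohort aggregation reproduces per-subject scores exactly", {
  fms <- do.call(rbind, lapply(1:3, function(s)
    cbind(s, blobFeatures(nPer = c(8, 10, 7), seed = s)@values)))
  labs <- rep(blobFeatures(nPer = c(8, 10, 7))@labels, 3)
  fm <- new("FeatureMatrix", values = fms[, -1], labels = labs,
            subjectIds = paste0("s", fms[, 1]), layout = list())
  res <- evaluateCohort(fm, embeddingSpec("le", 12, 2),
                        classifierSpec("knn", 5), seed = 3)
  expect_equal(res$meanF1, mean(res$perSubject$macroF1))
  expect_equal(res$seF1, sd(res$perSubject$macroF1) / sqrt(3))
})

test_that("repeated-measures comparison matches its textbook identities", {
  set.seed(12)
  # two methods: F equals the squared paired-t statistic
  sc2 <- cbind(a = runif(8, 0.6, 0.9), b = runif(8, 0.5, 0.8))
  cm <- compareMethods(sc2)
  tt <- t.test(sc2[, 1], sc2[, 2], paired = TRUE)
  expect_equal(cm$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cm$pairwise$t[1], unname(tt$statistic))
  # methods identical up to a per-subject offset: F = 0, p = 1
  base <- runif(6, 0.5, 0.9)
  d <- rep(c(0.01, -0.01), 3)
  sc0 <- cbind(m1 = base + d, m2 = base - d)   # equal column means
  cm0 <- compareMethods(sc0)
  expect_lt(cm0$anova$F, 1e-20)
  expect_equal(cm0$anova$p, 1, tolerance = 1e-6)
  # planted effect: F matches the sums-of-squares decomposition oracle
  subjEff <- rnorm(12, 0, 0.05)
  methEff <- c(0, 0.05, 0.1, 0.2)
  sc4 <- outer(subjEff, methEff, "+") + 0.7 +
    matrix(rnorm(48, 0, 0.02), 12)
  colnames(sc4) <- paste0("m", 1:4)
  cm4 <- compareMethods(sc4)
  gm <- mean(sc4)
  ssM <- 12 * sum((colMeans(sc4) - gm)^2)
  ssS <- 4 * sum((rowMeans(sc4) - gm)^2)
  ssT <- sum((sc4 - gm)^2)
  ssE <- ssT - ssM - ssS
  Fo <- (ssM / 3) / (ssE / 33)
  expect_equal(cm4$anova$F, Fo, tolerance = 1e-8)
  expect_equal(cm4$anova$df1, 3)
  expect_equal(cm4$anova$df2, 33)
  expect_equal(nrow(cm4$pairwise), 6)
  expect_true(all(is.finite(cm4$shapiro$p)))
  # missing cells are refused
  sc4[1, 1] <- NA
  expect_error(compareMethods(sc4), "missing")
})
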