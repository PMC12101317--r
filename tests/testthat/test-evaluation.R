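test_that("balanced class weights follow w_c = N / (K n_c)", {
  counts <- c(16018, 38394, 55055)
  w <- computeClassWeights(rep(0:2, counts))
  expect_equal(unname(w), sum(counts) / (3 * counts), tolerance = 1e-12)
  expect_equal(unname(computeClassWeights(rep(0:2, each = 10))), c(1, 1, 1))
  expect_equal(unname(computeClassWeights(rep(0:2, c(1, 1, 4)))),
               c(2, 2, 0.5))
  expect_error(computeClassWeights(c(0, 0, 2)), "empty class")
  # weighted class counts sum back to N for any composition
  set.seed(3)
  for (i in 1:10) {
    y <- sample(0:2, sample(30:200, 1), replace = TRUE)
    if (length(unique(y)) < 3) next
    w <- computeClassWeights(y)
    expect_equal(sum(w * tabulate(y + 1, 3)), length(y))
  }
})

test_that("k-fold splits partition the rows with near-equal sizes", {
  folds <- kfoldSplit(10, 10, seed = 1)
  expect_equal(lengths(folds), rep(1L, 10))
  folds <- kfoldSplit(103, 10, seed = 2)
  expect_equal(sort(unlist(folds)), 1:103)
  expect_lte(diff(range(lengths(folds))), 1)
  expect_identical(kfoldSplit(103, 10, seed = 2), folds)
  expect_false(identical(kfoldSplit(103, 10, seed = 3), folds))
  expect_error(kfoldSplit(5, 10), "n >= k")
  # fold class proportions fluctuate around the global ones
  y <- rep(0:2, c(150, 350, 500))
  folds <- kfoldSplit(1000, 10, seed = 4)
  props <- vapply(folds, function(ix) mean(y[ix] == 0), numeric(1))
  expect_true(all(abs(props - 0.15) < 0.12))   # ~>5 sd hypergeometric
  strat <- kfoldSplit(1000, 10, seed = 4, stratifyBy = y)
  propsS <- vapply(strat, function(ix) mean(y[ix] == 0), numeric(1))
  expect_true(all(abs(propsS - 0.15) < 0.006))
})

test_that("confusion counts equal brute-force pair counting", {
  expect_equal(unname(confusionCounts(0:2, 0:2)), diag(3) * 1L)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    yt <- sample(0:2, n, TRUE); yp <- sample(0:2, n, TRUE)
    cm <- confusionCounts(yt, yp)
    for (a in 0:2) for (b in 0:2)
      expect_equal(cm[a + 1, b + 1], sum(yt == a & yp == b))
  }
  expect_error(confusionCounts(c(0, 3), c(0, 1)), "0:2")
})

test_that("accuracy, precision and recall read off the confusion matrix", {
  expect_equal(overallAccuracy(diag(3) * 5), 1)
  off <- matrix(1, 3, 3) - diag(3)
  expect_equal(overallAccuracy(off), 0)
  cm <- matrix(c(8, 1, 1, 2, 5, 0, 0, 4, 9), 3, 3, byrow = TRUE)
  pr <- classPrecisionRecall(cm, 0)
  expect_equal(pr$precision, 8 / (8 + 2 + 0))
  expect_equal(pr$recall, 8 / 10)
  # a class never predicted has undefined precision, flagged not zeroed
  cm2 <- matrix(c(0, 5, 0, 0, 5, 0, 0, 5, 0), 3, 3, byrow = TRUE)
  pr2 <- classPrecisionRecall(cm2, 0)
  expect_true(is.na(pr2$precision))
  expect_false(pr2$defined[["precision"]])
})

test_that("micro precision/recall at threshold 0.5 match hand counting", {
  proba <- rbind(c(0.7, 0.2, 0.1),
                 c(0.4, 0.5, 0.1),
                 c(0.3, 0.3, 0.4),
                 c(0.1, 0.6, 0.3))
  y <- c(0L, 2L, 2L, 1L)
  # predicted positives: (1,0)=TP, (2,1)=FP, (4,1)=TP; positives missed:
  # rows 2 and 3 for class 2 -> TP=2, FP=1, FN=2
  pr <- microPrecisionRecall(y, proba)
  expect_equal(unname(pr["precision"]), 2 / 3)
  expect_equal(unname(pr["recall"]), 2 / 4)
})

test_that("one-vs-rest AUC matches the U statistic and pROC", {
  # perfect separation
  y <- c(rep(0L, 5), rep(1L, 5))
  proba <- cbind(c(runif(5, 0.8, 1), runif(5, 0, 0.2)),
                 c(runif(5, 0, 0.2), runif(5, 0.8, 1)), 0)
  proba <- proba / rowSums(proba)
  suppressWarnings(r <- rocAucOvr(y, proba))
  expect_equal(r$perClass[[1]]$auc, 1)
  expect_equal(r$perClass[[2]]$auc, 1)
  set.seed(11)
  for (i in 1:15) {
    n <- sample(8:40, 1)
    y <- sample(0:2, n, TRUE)
    if (length(unique(y)) < 3) next
    sc <- matrix(runif(3 * n), n, 3)
    sc[sample(n * 3, 5)] <- sc[sample(n * 3, 5)]   # allow ties via rounding
    sc <- round(sc, 1)
    proba <- sc / rowSums(sc)
    r <- rocAucOvr(y, proba)
    for (c in 0:2) {
      expect_equal(r$perClass[[c + 1]]$auc,
                   uStatisticAuc(as.integer(y == c), proba[, c + 1]),
                   tolerance = 1e-12)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = as.integer(y == c), predictor = proba[, c + 1],
        quiet = TRUE, direction = "<")))
      expect_equal(r$perClass[[c + 1]]$auc, ref, tolerance = 1e-12)
    }
  }
})

test_that("AUC is invariant under monotone score transforms and ~0.5 when
          scores carry no signal", {
  set.seed(13)
  y <- sample(0:2, 2000, TRUE)
  proba <- matrix(runif(6000), 2000, 3)
  proba <- proba / rowSums(proba)
  r <- rocAucOvr(y, proba)
  for (c in 1:3) expect_lt(abs(r$perClass[[c]]$auc - 0.5), 0.05)
  # monotone transform of one class's scores
  s <- proba[, 1]
  a1 <- rocAucOvr(y, proba)$perClass[[1]]$auc
  proba2 <- proba; proba2[, 1] <- exp(3 * s)
  suppressWarnings(a2 <- rocAucOvr(y, proba2)$perClass[[1]]$auc)
  expect_equal(a1, a2)
})

test_that("cross-validation aggregates every row exactly once", {
  fs <- tinyFeatureSet(seed = 19, nSamples = c(2, 2, 2))
  res <- crossValidate(fs, fnnTrainConfig(epochs = 2), k = 3, seed = 7)
  expect_s4_class(res, "CrossValResult")
  expect_equal(sum(cvConfusion(res)), ncol(fs))
  expect_equal(unname(rowSums(cvConfusion(res))),
               as.numeric(table(factor(classIndices(fs), levels = 0:2))))
  expect_equal(nrow(cvFolds(res)), 3)
  # the report schema carries the five metrics for train and test
  wanted <- c("trainLoss", "testLoss", "trainAccuracy", "testAccuracy",
              "trainPrecision", "testPrecision", "trainRecall",
              "testRecall", "trainAuc", "testAuc")
  expect_true(all(wanted %in% cvSummary(res)$metric))
  expect_true(all(wanted %in% colnames(cvFolds(res))))
  rng <- cvSummary(res)
  m <- rng$mean[rng$metric %in% wanted[-(1:2)]]
  # thresholded precision/recall may be undefined (NA, never 0) for an
  # undertrained model; defined metrics stay in [0, 1]
  expect_true(all(is.na(m) | (m >= 0 & m <= 1)))
  expect_false(anyNA(rng$mean[rng$metric %in%
                                c("testAccuracy", "testAuc")]))
  # reproducible bit-for-bit from the same seed
  res2 <- crossValidate(fs, fnnTrainConfig(epochs = 2), k = 3, seed = 7)
  expect_identical(cvFolds(res), cvFolds(res2))
})

test_that("mixture evaluation estimates proportions and their deviation", {
  expect_equal(mixtureError(c(0, 0.6, 0.4)), 0.1)
  expect_equal(mixtureError(c(0, 0.5, 0.5)), 0)
  expect_equal(mixtureError(c(0.1, 0.57, 0.43)), 0.07)
  expect_equal(mean(c(0.1, 0.07, 0.05, 0.1, 0.03)), 0.07)

  # end-to-end: a goat/sheep mixture scored by a trained model gives a
  # 3-vector of proportions summing to ~1 with little bovine mass
  fs <- tinyFeatureSet(seed = 23, nSamples = c(3, 4, 4))
  sc <- fitRobustScaler(fs)
  fit <- fnnTrain(applyRobustScaler(sc, fs),
                  cfg = fnnTrainConfig(epochs = 8, seed = 1,
                    classWeights = computeClassWeights(classIndices(fs))))
  sigs <- defaultSignatures(23, nMasses = c(6, 6, 6), overlap = 0,
                            minSep = 150)
  mixes <- lapply(1:3, function(i)
    generateMixtureSample(sigs[2:3], c(0.5, 0.5), nRuns = 3,
                          sampleId = paste0("m", i), seed = 100 + i))
  res <- evaluateMixture(fit$model, sc, mixes)
  expect_equal(nrow(res$perSample), 3)
  tot <- rowSums(res$perSample[, c("bovine", "goat", "sheep")])
  expect_equal(unname(tot), rep(1, 3), tolerance = 1e-6)
  expect_true(all(res$perSample$error >= 0 & res$perSample$error <= 0.5))
  expect_equal(res$averageError, mean(res$perSample$error))
})
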