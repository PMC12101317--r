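test_that("one-hot encoding follows the class mapping", {
  expect_equal(oneHot(0L)[1, ], c(1, 0, 0))   # Bovine_Milk
  expect_equal(oneHot(1L)[1, ], c(0, 1, 0))   # Goat_Milk
  expect_equal(oneHot(2L)[1, ], c(0, 0, 1))   # Sheep_Milk
  expect_equal(dim(oneHot(c(0, 2, 1))), c(3, 3))
  expect_true(all(rowSums(oneHot(c(0, 1, 2, 2))) == 1))
  expect_error(oneHot(3L), "0:2")
  expect_error(oneHot(-1L), "0:2")
})

test_that("relu and softmax behave analytically", {
  expect_equal(relu(c(-3, 0, 2.5)), c(0, 0, 2.5))
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  # stabilised: huge logits neither overflow nor change relative order
  p <- softmax(c(1000, 0, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p, c(1, 0, 0), tolerance = 1e-12)
  # shift invariance on random logits (matrix rows too)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(3) * 10
    expect_equal(softmax(x), softmax(x + rnorm(1) * 100))
  }
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(softmax(X), t(apply(X, 1, softmax)))
  expect_equal(unname(rowSums(softmax(X))), rep(1, 5))
})

test_that("forward pass is a probability distribution and batches agree", {
  model <- initFnn(seed = 2)
  zero <- model
  zero@weights <- lapply(zero@weights, function(w) w * 0)
  expect_equal(fnnForward(zero, rnorm(8)), rep(1 / 3, 3))
  X <- matrix(rnorm(40), 5, 8)
  P <- fnnForward(model, X)
  expect_equal(unname(rowSums(P)), rep(1, 5))
  for (i in 1:5) expect_equal(P[i, ], fnnForward(model, X[i, ]))
  # permuting rows permutes predictions identically
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predictProba(model, X[perm, ]), P[perm, ])
  expect_error(fnnForward(model, rnorm(5)), "8 features")
})

test_that("categorical cross-entropy matches closed forms", {
  expect_equal(categoricalCrossEntropy(c(0, 1, 0), c(0.25, 0.5, 0.25)),
               log(2))
  expect_equal(categoricalCrossEntropy(c(1, 0, 0), c(1, 0, 0)), 0)
  for (y in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
    expect_equal(categoricalCrossEntropy(y, rep(1 / 3, 3)), log(3))
  # clipping keeps a confidently wrong prediction finite
  expect_true(is.finite(categoricalCrossEntropy(c(1, 0, 0), c(0, 1, 0))))
})

test_that("class weights scale per-sample losses linearly", {
  model <- initFnn(seed = 3)
  X <- matrix(rnorm(48), 6, 8)
  y <- c(0L, 0L, 1L, 1L, 2L, 2L)
  base <- weightedBatchLoss(model, X, y, c(1, 1, 1))
  expect_equal(base, mean(categoricalCrossEntropy(oneHot(y),
                                                  fnnForward(model, X))))
  # doubling one class's weight adds exactly that class's mean contribution
  per <- categoricalCrossEntropy(oneHot(y), fnnForward(model, X))
  expect_equal(weightedBatchLoss(model, X, y, c(2, 1, 1)),
               base + mean(per * (y == 0)))
  # a 1-sample bovine batch with imbalance weights
  w <- c(2.278, 0.950, 0.663)
  x1 <- matrix(rnorm(8), 1)
  expect_equal(weightedBatchLoss(model, x1, 0L, w),
               2.278 * categoricalCrossEntropy(c(1, 0, 0),
                                               fnnForward(model, x1[1, ])))
  expect_error(weightedBatchLoss(model, X[0, , drop = FALSE], integer(0)),
               "non-empty")
})

test_that("analytic gradients match central finite differences", {
  model <- initFnn(c(4L, 6L, 5L, 3L), seed = 8)
  set.seed(8)
  X <- matrix(rnorm(12), 3, 4)
  y <- c(0L, 1L, 2L)
  w <- c(2.3, 0.9, 0.7)
  g <- maldiMilk:::fnnGradient(model, X, y, w)
  h <- 1e-5
  maxRel <- 0
  for (l in seq_along(model@weights)) {
    for (pick in seq_len(min(10, length(model@weights[[l]])))) {
      mp <- model; mm <- model
      mp@weights[[l]][pick] <- mp@weights[[l]][pick] + h
      mm@weights[[l]][pick] <- mm@weights[[l]][pick] - h
      fd <- (weightedBatchLoss(mp, X, y, w) -
             weightedBatchLoss(mm, X, y, w)) / (2 * h)
      rel <- abs(fd - g$weights[[l]][pick]) /
        max(abs(fd), abs(g$weights[[l]][pick]), 1e-8)
      maxRel <- max(maxRel, rel)
    }
    mp <- model; mm <- model
    mp@biases[[l]][1] <- mp@biases[[l]][1] + h
    mm@biases[[l]][1] <- mm@biases[[l]][1] - h
    fd <- (weightedBatchLoss(mp, X, y, w) -
           weightedBatchLoss(mm, X, y, w)) / (2 * h)
    maxRel <- max(maxRel, abs(fd - g$biases[[l]][1]) /
                    max(abs(fd), abs(g$biases[[l]][1]), 1e-8))
  }
  expect_lt(maxRel, 1e-4)
})

test_that("training is deterministic given the seed", {
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- rep(0:2, length.out = 200)
  cfg <- fnnTrainConfig(epochs = 2, seed = 11)
  f1 <- fnnTrain(X, y, cfg)
  f2 <- fnnTrain(X, y, cfg)
  expect_identical(f1$model@weights, f2$model@weights)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 2)
  # with unit weights and balanced data the weighted loss equals unweighted
  cfgW <- fnnTrainConfig(epochs = 2, seed = 11, classWeights = c(1, 1, 1))
  expect_identical(fnnTrain(X, y, cfgW)$model@weights, f1$model@weights)
})

test_that("the network learns a separable problem", {
  set.seed(5)
  n <- 120
  y <- rep(0:2, each = n / 3)
  X <- matrix(rnorm(n * 8, sd = 0.3), n, 8)
  X[, 1] <- X[, 1] + c(-3, 0, 3)[y + 1]
  fit <- fnnTrain(X, y, fnnTrainConfig(epochs = 30, seed = 2))
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_gte(tail(fit$history$accuracy, 1), 0.95)
  expect_gte(mean(hardPredictions(predictProba(fit$model, X)) == y), 0.95)
})

test_that("training aborts on a non-finite loss with a diagnostic", {
  X <- matrix(c(1e300, rep(0, 7)), 1, 8)[rep(1, 40), ]
  y <- rep(0:2, length.out = 40)
  expect_error(fnnTrain(X, y, fnnTrainConfig(epochs = 1, seed = 1,
                                             learningRate = 1e10)),
               "non-finite")
})
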