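#' @include AllClasses.R AllGenerics.R
NULL

CCE_EPS <- 1e-7   # probability clipping floor in the cross-entropy

#' One-hot encode a class index
#'
#' Class 0 = Bovine_Milk -> (1,0,0); 1 = Goat_Milk -> (0,1,0);
#' 2 = Sheep_Milk -> (0,0,1).
#'
#' @param label integer class index in 0:2, or a vector of them.
#' @param nClasses number of classes.
#' @return binary matrix, one row per label (a single label gives a 1 x 3
#'   matrix).
#' @export
oneHot <- function(label, nClasses = 3L) {
  label <- as.integer(label)
  if (any(is.na(label)) || any(label < 0L | label >= nClasses))
    stop("class labels must lie in 0:", nClasses - 1L)
  m <- matrix(0, length(label), nClasses)
  m[cbind(seq_along(label), label + 1L)] <- 1
  m
}

#' Rectified linear unit
#' @param x numeric vector or matrix.
#' @return element-wise max(0, x).
#' @export
relu <- function(x) pmax(x, 0)

#' Numerically stable softmax
#'
#' Normalises logits to a probability distribution, row-wise for matrices,
#' with max-subtraction so that adding a constant to all logits leaves the
#' result unchanged and large logits do not overflow.
#'
#' @param x numeric vector of logits, or a matrix with one logit row per
#'   observation.
#' @return probabilities of the same shape; each row sums to 1.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

#' Initialise a feedforward network
#'
#' Glorot-uniform weight initialisation (limit sqrt(6 / (fan_in + fan_out))),
#' zero biases, deterministic given `seed`. The default architecture is the
#' milk classifier: 8 inputs, four hidden layers of 64 ReLU units, 3 softmax
#' outputs.
#'
#' @param layerSizes integer vector of layer widths, input first.
#' @param seed integer initialisation seed.
#' @return an [FnnModel-class].
#' @export
initFnn <- function(layerSizes = c(8L, 64L, 64L, 64L, 64L, 3L), seed = 1L) {
  layerSizes <- as.integer(layerSizes)
  withSeed(seed, {
    L <- length(layerSizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fanIn <- layerSizes[l]; fanOut <- layerSizes[l + 1L]
      lim <- sqrt(6 / (fanIn + fanOut))
      W[[l]] <- matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
      b[[l]] <- rep(0, fanOut)
    }
    new("FnnModel", weights = W, biases = b, layerSizes = layerSizes,
        seed = as.integer(seed))
  })
}

# Forward pass keeping pre-activations; X is n x inputSize.
fnnForwardCache <- function(model, X) {
  L <- length(model@weights)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% model@weights[[l]], 2, model@biases[[l]], "+")
    A[[l + 1L]] <- if (l < L) relu(Z) else softmax(Z)
  }
  A
}

#' Forward pass of the classifier
#'
#' @param model an [FnnModel-class].
#' @param x numeric vector of length 8 (one scaled consensus vector) or an
#'   n x 8 matrix of them.
#' @return probability vector of length 3, or an n x 3 matrix; rows sum
#'   to 1.
#' @export
fnnForward <- function(model, x) {
  stopifnot(is(model, "FnnModel"))
  single <- !is.matrix(x)
  X <- if (single) matrix(x, 1) else x
  if (ncol(X) != model@layerSizes[1])
    stop("input must have ", model@layerSizes[1], " features")
  P <- fnnForwardCache(model, X)[[length(model@weights) + 1L]]
  if (single) drop(P) else P
}

#' @describeIn predictProba on a matrix of scaled feature vectors
#' @export
setMethod("predictProba", signature("FnnModel", "matrix"),
  function(object, x) fnnForward(object, x))

#' @describeIn predictProba on a scaled [MilkFeatureSet-class]
#' @export
setMethod("predictProba", signature("FnnModel", "MilkFeatureSet"),
  function(object, x) fnnForward(object, featureMatrix(x)))

#' Categorical cross-entropy
#'
#' H(y, yhat) = -sum_i y_i log(yhat_i), with predicted probabilities clipped
#' to \[1e-7, 1\] so a confident wrong prediction cannot produce -log 0.
#'
#' @param y one-hot vector/matrix of true labels.
#' @param yhat predicted probability vector/matrix of the same shape.
#' @return per-observation loss (scalar for vectors, numeric vector for
#'   matrices).
#' @export
categoricalCrossEntropy <- function(y, yhat) {
  yhat <- pmin(pmax(yhat, CCE_EPS), 1)
  if (is.matrix(y)) -rowSums(y * log(yhat)) else -sum(y * log(yhat))
}

#' Class-weighted mean batch loss
#'
#' Mean over the batch of w_c(y) x H(y, yhat), the per-sample loss multiplied
#' by the weight of the sample's true class. With all weights 1 this is the
#' unweighted mean cross-entropy.
#'
#' @param model an [FnnModel-class].
#' @param X n x 8 matrix of scaled inputs.
#' @param yIdx integer class indices in 0:2.
#' @param classWeights positive numeric of length 3.
#' @return scalar loss.
#' @export
weightedBatchLoss <- function(model, X, yIdx, classWeights = c(1, 1, 1)) {
  if (length(yIdx) == 0) stop("batch must be non-empty")
  P <- fnnForward(model, X)
  if (!is.matrix(P)) P <- matrix(P, 1)
  Y <- oneHot(yIdx)
  mean(classWeights[yIdx + 1L] * categoricalCrossEntropy(Y, P))
}

# Analytic gradient of the weighted batch loss w.r.t. all parameters.
# Softmax + cross-entropy collapse to dZ_L = (P - Y) * w / n.
fnnGradient <- function(model, X, yIdx, classWeights = c(1, 1, 1)) {
  L <- length(model@weights)
  n <- nrow(X)
  A <- fnnForwardCache(model, X)
  Y <- oneHot(yIdx)
  w <- classWeights[yIdx + 1L]
  dZ <- (A[[L + 1L]] - Y) * w / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, model@weights[[l]])
      dZ <- dA * (A[[l]] > 0)
    }
  }
  list(weights = gW, biases = gb)
}

#' Construct a training configuration
#'
#' @param epochs training epochs (default 25).
#' @param batchSize mini-batch size (default 32).
#' @param learningRate,beta1,beta2,epsilon Adam hyper-parameters (defaults
#'   1e-3, 0.9, 0.999, 1e-7).
#' @param classWeights per-class loss multipliers, typically from
#'   [computeClassWeights()]; default all 1.
#' @param seed seed controlling initialisation and epoch shuffling.
#' @return an [FnnTrainConfig-class].
#' @export
fnnTrainConfig <- function(epochs = 25L, batchSize = 32L,
                           learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           epsilon = 1e-7, classWeights = c(1, 1, 1),
                           seed = 1L) {
  new("FnnTrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      beta1 = beta1, beta2 = beta2, epsilon = epsilon,
      classWeights = as.numeric(classWeights), seed = as.integer(seed))
}

#' Train the feedforward classifier
#'
#' Mini-batch Adam on the class-weighted categorical cross-entropy: each
#' epoch shuffles the training rows (reproducibly from `cfg@seed`), splits
#' them into batches of `cfg@batchSize`, and applies one Adam update per
#' batch. The per-epoch history records the running mean of the weighted
#' batch loss and of batch accuracy, as streaming training frameworks do.
#'
#' @param X n x 8 matrix of robust-scaled feature vectors, or a scaled
#'   [MilkFeatureSet-class].
#' @param yIdx integer class indices in 0:2 (taken from the feature set when
#'   `X` is one).
#' @param cfg an [FnnTrainConfig-class].
#' @param model optional starting [FnnModel-class]; a fresh Glorot
#'   initialisation with `cfg@seed` is used when absent.
#' @return list with elements `model` (the trained [FnnModel-class]) and
#'   `history` (data.frame epoch/loss/accuracy).
#' @examples
#' X <- matrix(rnorm(60 * 8), 60, 8)
#' y <- rep(0:2, each = 20)
#' fit <- fnnTrain(X, y, fnnTrainConfig(epochs = 2, seed = 1))
#' fit$history
#' @export
fnnTrain <- function(X, yIdx = NULL, cfg = fnnTrainConfig(), model = NULL) {
  if (is(X, "MilkFeatureSet")) {
    if (is.null(yIdx)) yIdx <- classIndices(X)
    X <- featureMatrix(X)
  }
  X <- as.matrix(X)
  yIdx <- as.integer(yIdx)
  stopifnot(nrow(X) == length(yIdx))
  validObject(cfg)
  if (is.null(model)) model <- initFnn(c(ncol(X), 64L, 64L, 64L, 64L, 3L),
                                       seed = cfg@seed)
  L <- length(model@weights)
  mW <- lapply(model@weights, function(w) w * 0)
  vW <- mW
  mb <- lapply(model@biases, function(b) b * 0)
  vb <- mb
  t <- 0L
  n <- nrow(X)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  withSeed(cfg@seed, {
    for (ep in seq_len(cfg@epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batchSize)
      epLoss <- 0; epAcc <- 0; epN <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg@batchSize - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- yIdx[idx]
        A <- fnnForwardCache(model, Xb)
        P <- A[[L + 1L]]
        Y <- oneHot(yb)
        w <- cfg@classWeights[yb + 1L]
        loss <- mean(w * categoricalCrossEntropy(Y, P))
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep,
               "; check input scaling and learning rate")
        acc <- mean(max.col(P, ties.method = "first") - 1L == yb)
        epLoss <- epLoss + loss * length(idx)
        epAcc <- epAcc + acc * length(idx)
        epN <- epN + length(idx)
        # backward
        dZ <- (P - Y) * w / length(idx)
        t <- t + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], dZ)
          gb <- colSums(dZ)
          if (l > 1L) {
            dA <- tcrossprod(dZ, model@weights[[l]])
            dZ <- dA * (A[[l]] > 0)
          }
          mW[[l]] <- cfg@beta1 * mW[[l]] + (1 - cfg@beta1) * gW
          vW[[l]] <- cfg@beta2 * vW[[l]] + (1 - cfg@beta2) * gW^2
          mb[[l]] <- cfg@beta1 * mb[[l]] + (1 - cfg@beta1) * gb
          vb[[l]] <- cfg@beta2 * vb[[l]] + (1 - cfg@beta2) * gb^2
          mHatW <- mW[[l]] / (1 - cfg@beta1^t)
          vHatW <- vW[[l]] / (1 - cfg@beta2^t)
          mHatB <- mb[[l]] / (1 - cfg@beta1^t)
          vHatB <- vb[[l]] / (1 - cfg@beta2^t)
          model@weights[[l]] <- model@weights[[l]] -
            cfg@learningRate * mHatW / (sqrt(vHatW) + cfg@epsilon)
          model@biases[[l]] <- model@biases[[l]] -
            cfg@learningRate * mHatB / (sqrt(vHatB) + cfg@epsilon)
        }
      }
      history[ep, ] <- list(ep, epLoss / epN, epAcc / epN)
    }
  })
  list(model = model, history = history)
}
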