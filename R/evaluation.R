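#' @include AllClasses.R fnn.R preprocessing.R
NULL

#' Balanced class weights
#'
#' w_c = N / (K * n_c) for K classes, computed on training labels only: each
#' class's weight is inversely proportional to its frequency, and the
#' weighted class counts satisfy sum_c w_c * n_c = N exactly. Applied as
#' per-sample loss multipliers during training to counter the bovine class's
#' under-representation.
#'
#' @param yIdx integer class indices in 0:2 (training rows only).
#' @param nClasses number of classes K.
#' @return named positive numeric of length `nClasses`.
#' @examples
#' computeClassWeights(rep(0:2, c(16018, 38394, 55055)))
#' @export
computeClassWeights <- function(yIdx, nClasses = 3L) {
  yIdx <- as.integer(yIdx)
  if (any(is.na(yIdx)) || any(yIdx < 0L | yIdx >= nClasses))
    stop("class labels must lie in 0:", nClasses - 1L)
  counts <- tabulate(yIdx + 1L, nbins = nClasses)
  if (any(counts == 0))
    stop("every class must be represented; empty class(es): ",
         paste(which(counts == 0) - 1L, collapse = ", "))
  w <- length(yIdx) / (nClasses * counts)
  names(w) <- MILK_SPECIES[seq_len(nClasses)]
  w
}

#' k-fold partition of row indices
#'
#' Uniformly shuffled, non-stratified partition of `1:n` into `k` folds of
#' sizes differing by at most one; every index appears in exactly one fold.
#' Reproducible from `seed`.
#'
#' @param n number of rows.
#' @param k number of folds (default 10).
#' @param seed shuffle seed.
#' @param stratifyBy optional vector of length `n`; when given, the shuffle
#'   is performed within each stratum so fold class proportions match the
#'   global ones.
#' @return list of `k` integer index vectors, with attributes `seed` and `k`.
#' @export
kfoldSplit <- function(n, k = 10L, seed = 1L, stratifyBy = NULL) {
  if (n < k) stop("need at least as many rows as folds (n >= k)")
  folds <- withSeed(seed, {
    if (is.null(stratifyBy)) {
      perm <- sample.int(n)
      # cycling 1..k over the shuffled indices keeps fold sizes within 1
      split(perm, rep_len(seq_len(k), n))
    } else {
      stopifnot(length(stratifyBy) == n)
      assign <- integer(n)
      for (s in unique(stratifyBy)) {
        rows <- which(stratifyBy == s)
        assign[rows[sample.int(length(rows))]] <-
          rep_len(seq_len(k), length(rows))
      }
      split(seq_len(n), assign)
    }
  })
  folds <- unname(lapply(folds, function(ix) sort(as.integer(ix))))
  attr(folds, "seed") <- as.integer(seed)
  attr(folds, "k") <- as.integer(k)
  folds
}

#' Confusion matrix of hard predictions
#'
#' @param yTrue,yPred integer class indices in 0:2 of equal length.
#' @param nClasses number of classes.
#' @return `nClasses` x `nClasses` integer matrix; entry (i, j) counts rows
#'   with true class i predicted as class j.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses = 3L) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (any(c(yTrue, yPred) < 0L) || any(c(yTrue, yPred) >= nClasses))
    stop("class labels must lie in 0:", nClasses - 1L)
  lv <- 0:(nClasses - 1L)
  cm <- table(factor(yTrue, levels = lv), factor(yPred, levels = lv))
  m <- matrix(as.integer(cm), nClasses, nClasses,
              dimnames = list(true = lv, predicted = lv))
  m
}

#' Hard class predictions from probabilities
#' @param proba N x 3 probability matrix.
#' @return integer class indices (argmax; ties go to the lowest index).
#' @export
hardPredictions <- function(proba) {
  max.col(proba, ties.method = "first") - 1L
}

#' Overall (categorical) accuracy from a confusion matrix
#' @param cm square confusion matrix (rows true, columns predicted).
#' @return trace / total, in \[0, 1\].
#' @export
overallAccuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' One-vs-rest precision and recall of one class
#'
#' Precision = TP / (TP + FP) = cm\[c,c\] / column sum; recall =
#' TP / (TP + FN) = cm\[c,c\] / row sum. An undefined ratio (zero
#' denominator) is reported as `NA` with a `defined` flag, not as 0.
#'
#' @param cm square confusion matrix.
#' @param class class index in 0:2.
#' @return list with `precision`, `recall` and logical `defined` (length 2:
#'   precision, recall).
#' @export
classPrecisionRecall <- function(cm, class) {
  c1 <- class + 1L
  tp <- cm[c1, c1]
  colSum <- sum(cm[, c1]); rowSum <- sum(cm[c1, ])
  list(precision = if (colSum > 0) tp / colSum else NA_real_,
       recall = if (rowSum > 0) tp / rowSum else NA_real_,
       defined = c(precision = colSum > 0, recall = rowSum > 0))
}

#' Thresholded micro-averaged one-vs-rest precision and recall
#'
#' Pools the three one-vs-rest binary problems: an entry (i, c) is a
#' predicted positive when proba\[i, c\] >= `threshold`. This is the metric
#' semantics of streaming training frameworks, and unlike argmax-based micro
#' averaging it does not force precision = recall = accuracy.
#'
#' @param yIdx integer true class indices in 0:2.
#' @param proba N x 3 probability matrix.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric: precision, recall.
#' @export
microPrecisionRecall <- function(yIdx, proba, threshold = 0.5) {
  Y <- oneHot(yIdx, ncol(proba))
  pos <- proba >= threshold
  tp <- sum(pos & Y == 1)
  fp <- sum(pos & Y == 0)
  fn <- sum(!pos & Y == 1)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# ROC points for one binary problem: threshold sweep over the distinct
# scores in decreasing order, tied scores grouped, trapezoidal AUC.
binaryRoc <- function(labels, scores) {
  if (length(unique(labels)) < 2)
    return(list(points = NULL, auc = NA_real_))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  nPos <- sum(lab); nNeg <- length(lab) - nPos
  grp <- !duplicated(sc)                 # group equal scores
  cumTp <- cumsum(lab); cumFp <- cumsum(!lab)
  last <- c(which(grp[-1]) , length(sc)) # last index of each tie group
  tpr <- c(0, cumTp[last] / nPos)
  fpr <- c(0, cumFp[last] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(threshold = c(Inf, sc[last]), fpr = fpr,
                           tpr = tpr),
       auc = auc)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class c the score proba\[, c\] is swept against the binary labels
#' 1(true == c), giving TPR/FPR points (ties grouped) and the trapezoidal
#' AUC. Classes absent from `yIdx` get `NA` AUC with a warning; the macro
#' summary averages the defined AUCs.
#'
#' @param yIdx integer true class indices in 0:2.
#' @param proba N x 3 probability matrix (rows summing to ~1).
#' @return list with `perClass` (list of `points`, `auc` per class) and
#'   `macroAuc`.
#' @export
rocAucOvr <- function(yIdx, proba) {
  stopifnot(is.matrix(proba), length(yIdx) == nrow(proba))
  if (any(abs(rowSums(proba) - 1) > 1e-6))
    warning("probability rows do not sum to 1")
  perClass <- lapply(seq_len(ncol(proba)) - 1L, function(c) {
    binaryRoc(as.integer(yIdx == c), proba[, c + 1L])
  })
  names(perClass) <- MILK_SPECIES[seq_len(ncol(proba))]
  aucs <- vapply(perClass, `[[`, numeric(1), "auc")
  if (anyNA(aucs))
    warning("AUC undefined for class(es) absent from the labels")
  list(perClass = perClass, macroAuc = mean(aucs, na.rm = TRUE))
}

#' k-fold cross-validated training and evaluation
#'
#' For each fold: fit the robust scaler on the training rows only, scale
#' both splits, compute balanced class weights on the training labels, train
#' the network, and evaluate train/test unweighted mean cross-entropy,
#' categorical accuracy, thresholded micro one-vs-rest precision/recall, and
#' macro one-vs-rest AUC. Test-fold hard predictions are aggregated into a
#' single confusion matrix covering every row of the dataset once. A fold
#' whose training split misses a class is skipped with a warning.
#'
#' @param x a [MilkFeatureSet-class] of *unscaled* consensus vectors.
#' @param cfg an [FnnTrainConfig-class]; its `classWeights` are overridden
#'   per fold by [computeClassWeights()] unless `useClassWeights = FALSE`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed (per-fold training seeds derive from it).
#' @param stratified stratify the folds by class (default FALSE: uniform
#'   shuffle).
#' @param useClassWeights apply balanced class weights during training.
#' @param verbose print per-fold progress.
#' @return a [CrossValResult-class].
#' @export
crossValidate <- function(x, cfg = fnnTrainConfig(), k = 10L, seed = 1L,
                          stratified = FALSE, useClassWeights = TRUE,
                          verbose = FALSE) {
  stopifnot(is(x, "MilkFeatureSet"))
  M <- featureMatrix(x)
  y <- classIndices(x)
  folds <- kfoldSplit(nrow(M), k = k, seed = seed,
                      stratifyBy = if (stratified) y else NULL)
  foldSeeds <- deriveSeeds(seed, k)
  rows <- list()
  yPredAll <- rep(NA_integer_, nrow(M))
  for (f in seq_len(k)) {
    testIdx <- folds[[f]]
    trainIdx <- setdiff(seq_len(nrow(M)), testIdx)
    yTr <- y[trainIdx]; yTe <- y[testIdx]
    if (length(unique(yTr)) < 3) {
      warning("fold ", f, " misses a class in training; skipped")
      next
    }
    scaler <- fitRobustScaler(M[trainIdx, , drop = FALSE])
    XTr <- applyRobustScaler(scaler, M[trainIdx, , drop = FALSE])
    XTe <- applyRobustScaler(scaler, M[testIdx, , drop = FALSE])
    cw <- if (useClassWeights) computeClassWeights(yTr) else c(1, 1, 1)
    foldCfg <- cfg
    foldCfg@classWeights <- as.numeric(cw)
    foldCfg@seed <- foldSeeds[f]
    fit <- fnnTrain(XTr, yTr, foldCfg)
    pTr <- predictProba(fit$model, XTr)
    pTe <- predictProba(fit$model, XTe)
    yPredAll[testIdx] <- hardPredictions(pTe)
    prTr <- microPrecisionRecall(yTr, pTr)
    prTe <- microPrecisionRecall(yTe, pTe)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f,
      trainLoss = mean(categoricalCrossEntropy(oneHot(yTr), pTr)),
      testLoss = mean(categoricalCrossEntropy(oneHot(yTe), pTe)),
      trainAccuracy = mean(hardPredictions(pTr) == yTr),
      testAccuracy = mean(hardPredictions(pTe) == yTe),
      trainPrecision = prTr[["precision"]],
      testPrecision = prTe[["precision"]],
      trainRecall = prTr[["recall"]],
      testRecall = prTe[["recall"]],
      trainAuc = rocAucOvr(yTr, pTr)$macroAuc,
      testAuc = rocAucOvr(yTe, pTe)$macroAuc,
      wBovine = cw[[1]], wGoat = cw[[2]], wSheep = cw[[3]])
    if (verbose)
      message(sprintf("fold %d/%d: test accuracy %.3f", f, k,
                      rows[[length(rows)]]$testAccuracy))
  }
  if (!length(rows)) stop("no fold could be evaluated")
  foldsDf <- do.call(rbind, rows)
  metricCols <- setdiff(colnames(foldsDf),
                        c("fold", "wBovine", "wGoat", "wSheep"))
  summary <- data.frame(
    metric = metricCols,
    mean = vapply(foldsDf[metricCols], mean, numeric(1)),
    sd = vapply(foldsDf[metricCols], sd, numeric(1)),
    row.names = NULL)
  evaluated <- !is.na(yPredAll)
  cm <- confusionCounts(y[evaluated], yPredAll[evaluated])
  new("CrossValResult", folds = foldsDf, summary = summary, confusion = cm,
      k = as.integer(k), seed = as.integer(seed))
}

#' Estimate mixture proportions with a trained classifier
#'
#' For each mixture sample the runs are QC-filtered, collapsed to consensus
#' vectors, scaled with the *training* scaler, and pushed through the
#' classifier; the sample's estimated composition is the mean predicted
#' probability vector. The per-sample error is the largest deviation of the
#' nominal mixture classes' estimated proportions from their nominal values
#' (for a 50/50 goat/sheep mixture: max over goat and sheep of
#' |p_hat - 0.5|), and the average error is the mean over samples.
#'
#' @param model a trained [FnnModel-class].
#' @param scaler the [RobustScaler-class] fitted on the training data.
#' @param mixtureSamples list of mixture samples, each a list of
#'   [SpectrumRun-class] replicate runs (e.g. from
#'   [generateMixtureSample()]).
#' @param thresholds QC thresholds.
#' @param tol consensus tolerance in Da.
#' @param nominal named numeric of the nominal proportions of the mixture's
#'   component classes (default 50/50 goat/sheep).
#' @return list with `perSample` (data.frame: sample, the three estimated
#'   proportions, nVectors, error) and `averageError`.
#' @export
evaluateMixture <- function(model, scaler, mixtureSamples,
                            thresholds = qcThresholds(), tol = 2.0,
                            nominal = c(Goat_Milk = 0.5, Sheep_Milk = 0.5)) {
  stopifnot(is(model, "FnnModel"), is(scaler, "RobustScaler"))
  nomIdx <- speciesToIndex(names(nominal))
  rows <- lapply(seq_along(mixtureSamples), function(i) {
    runs <- lapply(mixtureSamples[[i]], qcFilter, thresholds = thresholds)
    cv <- consensusVectors(runs, tol = tol)
    if (nrow(cv) == 0)
      stop("no consensus vectors survive QC for mixture sample ", i)
    Xs <- applyRobustScaler(scaler, as.matrix(cv[, PEAK_COLUMNS]))
    p <- colMeans(fnnForward(model, Xs))
    err <- max(abs(p[nomIdx + 1L] - nominal))
    data.frame(sample = i, bovine = p[1], goat = p[2], sheep = p[3],
               nVectors = nrow(cv), error = err)
  })
  perSample <- do.call(rbind, rows)
  rownames(perSample) <- NULL
  list(perSample = perSample, averageError = mean(perSample$error))
}

#' Mixture deviation rule
#'
#' The error assigned to one mixture sample given its estimated class
#' proportions: the maximum absolute deviation of the nominal component
#' classes from their nominal proportions.
#'
#' @param proportions numeric of length 3 (bovine, goat, sheep estimates).
#' @param nominalIdx class indices of the mixture's components (default
#'   goat = 1, sheep = 2).
#' @param nominalProportions their nominal values (default 0.5, 0.5).
#' @return scalar error.
#' @examples
#' mixtureError(c(0, 0.6, 0.4))   # 0.1
#' @export
mixtureError <- function(proportions, nominalIdx = c(1L, 2L),
                         nominalProportions = c(0.5, 0.5)) {
  max(abs(proportions[nominalIdx + 1L] - nominalProportions))
}
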