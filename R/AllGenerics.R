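#' @include AllClasses.R
NULL

#' Number of runs in a dataset
#' @param x a [MilkDataset-class] or [SpectrumRun-class] list holder.
#' @return integer count of acquisition runs.
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' Sample identifiers
#' @param x a [MilkDataset-class] or [MilkFeatureSet-class].
#' @return character vector of sample ids (unique for datasets, per-column
#'   for feature sets).
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Species labels
#' @param x a [MilkDataset-class] (one label per run) or
#'   [MilkFeatureSet-class] (one label per consensus vector).
#' @return character vector of species labels.
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' Consensus feature matrix
#' @param x a [MilkFeatureSet-class].
#' @return numeric N x 8 matrix, one consensus vector per row, the eight
#'   peak features as columns.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Quality-control filtering of peak rows
#'
#' Remove every peak row that falls below any QC threshold (intensity >= 1000,
#' S/N >= 5, resolution >= 400 by default; all inclusive) or that contains a
#' missing value in any of the eight features. Row order is preserved and the
#' operation is idempotent.
#'
#' @param x a [SpectrumRun-class] or [MilkDataset-class].
#' @param thresholds a list from [qcThresholds()].
#' @return object of the same class with failing rows removed; the number of
#'   removed rows is recorded in `attr(, "nRemoved")` for runs and in the
#'   dataset provenance for datasets.
#' @examples
#' run <- generateRun(defaultSignatures(1)[[1]], seed = 1)
#' qcFilter(run)
#' @export
setGeneric("qcFilter",
           function(x, thresholds = qcThresholds()) standardGeneric("qcFilter"))

#' Class-probability predictions
#'
#' Forward-propagate feature vectors through a trained [FnnModel-class] and
#' return the softmax probability of each of the three species.
#'
#' @param object a trained [FnnModel-class].
#' @param x numeric matrix (rows = vectors, 8 columns, already scaled) or a
#'   [MilkFeatureSet-class] holding scaled features.
#' @return numeric N x 3 matrix of class probabilities; rows sum to 1.
#' @export
setGeneric("predictProba", function(object, x) standardGeneric("predictProba"))

#' Apply a fitted robust scaler
#'
#' Transform features by x' = (x - median) / IQR using parameters fitted on
#' training data ([fitRobustScaler()]).
#'
#' @param scaler a [RobustScaler-class].
#' @param x numeric N x 8 matrix or [MilkFeatureSet-class].
#' @return object of the same class as `x`, feature-wise scaled.
#' @export
setGeneric("applyRobustScaler",
           function(scaler, x) standardGeneric("applyRobustScaler"))

#' Invert a robust scaling transform
#'
#' Recover original features from scaled ones: x = x' * IQR + median.
#' @inheritParams applyRobustScaler
#' @return object of the same class as `x` on the original feature scale.
#' @export
setGeneric("invertRobustScaler",
           function(scaler, x) standardGeneric("invertRobustScaler"))
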