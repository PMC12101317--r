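#' @import methods
#' @include utils-internal.R
NULL

#' SpectrumRun: one acquisition run's peak table
#'
#' A `SpectrumRun` holds the tabular reduction of a single MALDI-TOF
#' acquisition to its detected peaks, together with the sample metadata needed
#' to group replicate runs. Each peak row carries eight quality-annotated
#' features in fixed order: m/z (Da), acquisition time, intensity (a.u.),
#' signal-to-noise ratio, resolution, peak area, relative intensity (in
#' \[0, 1\]) and FWHM (Da). Cells may be `NA` when the export contained a
#' blank or unparseable value; QC filtering removes such rows.
#'
#' @slot peaks data.frame with the eight peak columns, one row per peak.
#' @slot farmId character scalar, the producing farm.
#' @slot sampleId character scalar identifying the milk sample; replicate
#'   runs of the same sample share it.
#' @slot runIndex integer >= 1, the replicate index within the sample.
#' @slot species one of `"Bovine_Milk"`, `"Goat_Milk"`, `"Sheep_Milk"` or
#'   `"Unknown"`.
#'
#' @seealso [readPeakTable()], [qcFilter()], [consensusVectors()]
#' @export
setClass("SpectrumRun",
  representation(peaks = "data.frame", farmId = "character",
                 sampleId = "character", runIndex = "integer",
                 species = "character"),
  prototype(peaks = data.frame(), farmId = NA_character_,
            sampleId = NA_character_, runIndex = 1L, species = "Unknown"))

setValidity("SpectrumRun", function(object) {
  msg <- character()
  pk <- object@peaks
  if (nrow(pk) > 0 || ncol(pk) > 0) {
    if (!identical(colnames(pk), PEAK_COLUMNS))
      msg <- c(msg, sprintf("peaks must have columns %s in order",
                            paste(PEAK_COLUMNS, collapse = ", ")))
  }
  if (length(object@species) != 1L ||
      !object@species %in% c(MILK_SPECIES, "Unknown"))
    msg <- c(msg, "species must be one of the three milk labels or 'Unknown'")
  if (length(object@runIndex) != 1L || is.na(object@runIndex) ||
      object@runIndex < 1L)
    msg <- c(msg, "runIndex must be a single integer >= 1")
  if (nrow(pk) > 0 && identical(colnames(pk), PEAK_COLUMNS)) {
    bad <- function(x, cond) any(!is.na(x) & cond)
    if (bad(pk$mz, pk$mz <= 0)) msg <- c(msg, "mz must be > 0")
    if (bad(pk$snr, pk$snr < 0)) msg <- c(msg, "snr must be >= 0")
    if (bad(pk$resolution, pk$resolution < 0))
      msg <- c(msg, "resolution must be >= 0")
    if (bad(pk$fwhm, pk$fwhm < 0)) msg <- c(msg, "fwhm must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' MilkDataset: a labelled collection of spectrum runs
#'
#' Container for the full folder-tree dataset the pipeline consumes: every
#' run of every sample, each carrying its species label, plus provenance
#' (source path or generator configuration digest, file/row counts).
#'
#' @slot runs list of [SpectrumRun-class] objects.
#' @slot provenance named list describing where the runs came from.
#' @export
setClass("MilkDataset",
  representation(runs = "list", provenance = "list"),
  prototype(runs = list(), provenance = list()))

setValidity("MilkDataset", function(object) {
  if (!all(vapply(object@runs, is, logical(1), "SpectrumRun")))
    return("all elements of 'runs' must be SpectrumRun objects")
  sp <- vapply(object@runs, slot, character(1), "species")
  sid <- vapply(object@runs, slot, character(1), "sampleId")
  per <- tapply(sp, sid, function(s) length(unique(s)))
  if (length(per) && any(per > 1))
    return("all runs of a sample must share one species label")
  TRUE
})

#' MilkFeatureSet: consensus feature vectors with species labels
#'
#' The N x 8 matrix of consensus feature vectors produced by
#' [buildFeatureMatrix()], stored as a [SummarizedExperiment::SummarizedExperiment]
#' with the eight features as assay rows and one column per consensus vector.
#' Column data carry `sample`, `species` and the 0/1/2 `classIndex`
#' (0 = Bovine_Milk, 1 = Goat_Milk, 2 = Sheep_Milk).
#'
#' @seealso [featureMatrix()], [speciesLabels()], [fitRobustScaler()]
#' @export
#' @import SummarizedExperiment
setClass("MilkFeatureSet", contains = "SummarizedExperiment")

setValidity("MilkFeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  a <- SummarizedExperiment::assay(object, "features")
  if (!identical(rownames(a), PEAK_COLUMNS))
    msg <- c(msg, "assay rows must be the eight peak features in order")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample", "species") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'sample' and 'species'")
  else if (!all(cd$species %in% MILK_SPECIES))
    msg <- c(msg, "species labels must be the three milk classes")
  if (ncol(object) > 0 && any(!is.finite(a)))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' RobustScaler: per-feature median/IQR scaling parameters
#'
#' Parameters of the robust scaling transform x' = (x - median(x)) / IQR(x),
#' fitted on training rows only. Features whose IQR is zero are flagged and
#' given divisor 1 so the transform stays defined on degenerate columns.
#'
#' @slot center named numeric, per-feature medians.
#' @slot scale named numeric, per-feature IQRs (1 where the IQR was 0).
#' @slot zeroIqr logical, which features had IQR exactly 0.
#' @slot fittedOn character digest of the training data the fit saw.
#' @export
setClass("RobustScaler",
  representation(center = "numeric", scale = "numeric",
                 zeroIqr = "logical", fittedOn = "character"))

setValidity("RobustScaler", function(object) {
  if (length(object@center) != length(object@scale) ||
      length(object@center) != length(object@zeroIqr))
    return("center, scale and zeroIqr must have equal length")
  if (any(object@scale <= 0)) return("scale entries must be > 0")
  TRUE
})

#' FnnModel: weights of the feedforward classifier
#'
#' Parameters of the fully connected network used for milk classification:
#' layer sizes 8, 64, 64, 64, 64, 3 by default, ReLU activations on the four
#' hidden layers and a softmax output over the three species.
#'
#' @slot weights list of weight matrices, `weights[[l]]` of dim
#'   (size l) x (size l+1).
#' @slot biases list of bias vectors.
#' @slot layerSizes integer vector of layer widths, input first.
#' @slot seed integer seed used for Glorot-uniform initialisation.
#' @export
setClass("FnnModel",
  representation(weights = "list", biases = "list",
                 layerSizes = "integer", seed = "integer"))

setValidity("FnnModel", function(object) {
  L <- length(object@layerSizes) - 1L
  if (length(object@weights) != L || length(object@biases) != L)
    return("need one weight matrix and bias vector per layer transition")
  for (l in seq_len(L)) {
    if (!identical(dim(object@weights[[l]]),
                   c(object@layerSizes[l], object@layerSizes[l + 1L])))
      return(sprintf("weights[[%d]] has wrong dimensions", l))
    if (length(object@biases[[l]]) != object@layerSizes[l + 1L])
      return(sprintf("biases[[%d]] has wrong length", l))
    if (any(!is.finite(object@weights[[l]])) ||
        any(!is.finite(object@biases[[l]])))
      return("all parameters must be finite")
  }
  TRUE
})

#' FnnTrainConfig: training hyper-parameters
#'
#' Mini-batch Adam configuration: 25 epochs and batch size 32 by default,
#' Adam step size 1e-3 with moment decays 0.9/0.999 and epsilon 1e-7, and
#' per-class loss weights (all 1 unless set, typically from
#' [computeClassWeights()]).
#'
#' @slot epochs integer >= 1.
#' @slot batchSize integer >= 1.
#' @slot learningRate,beta1,beta2,epsilon Adam hyper-parameters.
#' @slot classWeights positive numeric of length 3, loss multiplier per class.
#' @slot seed integer controlling initialisation and batch shuffling.
#' @export
setClass("FnnTrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", beta1 = "numeric",
                 beta2 = "numeric", epsilon = "numeric",
                 classWeights = "numeric", seed = "integer"))

setValidity("FnnTrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (any(object@classWeights <= 0)) msg <- c(msg, "classWeights must be > 0")
  if (length(object@classWeights) != 3L)
    msg <- c(msg, "classWeights must have length 3")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' CrossValResult: k-fold cross-validation report
#'
#' Per-fold and aggregate metrics from [crossValidate()]: train/test loss,
#' categorical accuracy, thresholded micro one-vs-rest precision and recall,
#' macro one-vs-rest AUC, the mean +/- sd summary, and the confusion matrix
#' aggregated over all test folds.
#'
#' @slot folds data.frame, one row per evaluated fold.
#' @slot summary data.frame with columns metric, mean, sd.
#' @slot confusion 3 x 3 integer matrix (rows true, columns predicted).
#' @slot k,seed the cross-validation design.
#' @export
setClass("CrossValResult",
  representation(folds = "data.frame", summary = "data.frame",
                 confusion = "matrix", k = "integer", seed = "integer"))

#' SpeciesSignature: generative fingerprint of one species
#'
#' The synthetic-data generator's model of one species' casein fingerprint:
#' a set of base peak masses inside the 3,000-10,000 Da acquisition window,
#' a base intensity per mass, a per-run mass jitter (ppm) emulating the
#' instrument's calibration accuracy, and an intensity coefficient of
#' variation.
#'
#' @slot species species label.
#' @slot baseMasses numeric, peak centres in Da within \[3000, 10000\],
#'   at least three.
#' @slot baseIntensities positive numeric, one per mass.
#' @slot massJitterPpm standard deviation of the per-run relative mass error,
#'   in parts per million.
#' @slot intensityCv coefficient of variation of peak intensity across runs.
#' @export
setClass("SpeciesSignature",
  representation(species = "character", baseMasses = "numeric",
                 baseIntensities = "numeric", massJitterPpm = "numeric",
                 intensityCv = "numeric"))

setValidity("SpeciesSignature", function(object) {
  msg <- character()
  if (length(object@baseMasses) < 3L)
    msg <- c(msg, "need at least 3 base masses")
  if (any(object@baseMasses < MZ_WINDOW[1] | object@baseMasses > MZ_WINDOW[2]))
    msg <- c(msg, "base masses must lie in [3000, 10000] Da")
  if (length(object@baseIntensities) != length(object@baseMasses))
    msg <- c(msg, "one base intensity per base mass")
  if (any(object@baseIntensities <= 0))
    msg <- c(msg, "base intensities must be > 0")
  if (object@massJitterPpm < 0) msg <- c(msg, "massJitterPpm must be >= 0")
  if (object@intensityCv < 0) msg <- c(msg, "intensityCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic dataset design
#'
#' Configuration of the synthetic peak-list generator: the three species
#' signatures, samples per species, replicate runs per sample (triplicate by
#' default), the probability that a generated peak row is degraded below one
#' QC threshold, an optional mixture design, and the master seed.
#'
#' @slot signatures list of three [SpeciesSignature-class] objects.
#' @slot nSamplesPerSpecies named integer, samples per species.
#' @slot runsPerSample integer >= 2.
#' @slot qcFailRate probability in \[0, 1\] that a row fails QC.
#' @slot classMix optional named numeric of mixture proportions (sums to 1).
#' @slot seed integer master seed.
#' @export
setClass("SimConfig",
  representation(signatures = "list", nSamplesPerSpecies = "integer",
                 runsPerSample = "integer", qcFailRate = "numeric",
                 classMix = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@signatures, is, logical(1), "SpeciesSignature")))
    msg <- c(msg, "signatures must be SpeciesSignature objects")
  if (object@qcFailRate < 0 || object@qcFailRate > 1)
    msg <- c(msg, "qcFailRate must be in [0, 1]")
  if (object@runsPerSample < 2L)
    msg <- c(msg, "runsPerSample must be >= 2")
  if (length(object@classMix) &&
      abs(sum(object@classMix) - 1) > 1e-8)
    msg <- c(msg, "classMix proportions must sum to 1")
  if (length(msg)) msg else TRUE
})
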