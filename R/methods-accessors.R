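#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SpectrumRun
#'
#' @param peaks data.frame with the eight peak columns (`mz`, `time`,
#'   `intensity`, `snr`, `resolution`, `area`, `rel_intensity`, `fwhm`).
#' @param farmId,sampleId character metadata.
#' @param runIndex integer replicate index (>= 1).
#' @param species species label or `"Unknown"`.
#' @return a [SpectrumRun-class].
#' @export
SpectrumRun <- function(peaks, farmId = NA_character_,
                        sampleId = NA_character_, runIndex = 1L,
                        species = "Unknown") {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0 && ncol(peaks) == 0)
    peaks <- emptyPeakFrame()
  new("SpectrumRun", peaks = peaks, farmId = as.character(farmId),
      sampleId = as.character(sampleId), runIndex = as.integer(runIndex),
      species = species)
}

emptyPeakFrame <- function() {
  as.data.frame(setNames(rep(list(numeric(0)), length(PEAK_COLUMNS)),
                         PEAK_COLUMNS))
}

#' Construct a MilkDataset
#' @param runs list of [SpectrumRun-class] objects.
#' @param provenance named list of provenance fields.
#' @return a [MilkDataset-class].
#' @export
MilkDataset <- function(runs = list(), provenance = list()) {
  new("MilkDataset", runs = runs, provenance = provenance)
}

#' @describeIn nRuns number of peaks in the run
#' @export
setMethod("nRuns", "MilkDataset", function(x) length(x@runs))

#' Runs stored in a dataset
#' @param x a [MilkDataset-class].
#' @param sampleId optional; restrict to one sample's runs.
#' @return list of [SpectrumRun-class] objects.
#' @export
datasetRuns <- function(x, sampleId = NULL) {
  stopifnot(is(x, "MilkDataset"))
  if (is.null(sampleId)) return(x@runs)
  x@runs[vapply(x@runs, slot, character(1), "sampleId") == sampleId]
}

#' Dataset provenance
#' @param x a [MilkDataset-class].
#' @return the provenance list recorded at load/generation time.
#' @export
datasetProvenance <- function(x) x@provenance

#' @describeIn sampleIds unique sample ids across the dataset's runs
#' @export
setMethod("sampleIds", "MilkDataset", function(x)
  unique(vapply(x@runs, slot, character(1), "sampleId")))

#' @describeIn speciesLabels one label per run
#' @export
setMethod("speciesLabels", "MilkDataset", function(x)
  vapply(x@runs, slot, character(1), "species"))

#' Peak table of a run
#' @param run a [SpectrumRun-class].
#' @return data.frame of peaks with the eight fixed columns.
#' @export
peakTable <- function(run) {
  stopifnot(is(run, "SpectrumRun"))
  run@peaks
}

#' Construct a MilkFeatureSet
#'
#' @param features numeric N x 8 matrix of consensus vectors (columns are the
#'   eight peak features, in order).
#' @param species character of length N, species label per vector.
#' @param sample character of length N, source sample per vector.
#' @param metadata optional list stored in the object metadata.
#' @return a [MilkFeatureSet-class].
#' @export
MilkFeatureSet <- function(features, species, sample, metadata = list()) {
  features <- as.matrix(features)
  if (ncol(features) != length(PEAK_COLUMNS))
    stop("'features' must have 8 columns")
  colnames(features) <- PEAK_COLUMNS
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)),
    colData = S4Vectors::DataFrame(
      sample = as.character(sample),
      species = as.character(species),
      classIndex = speciesToIndex(species)),
    metadata = metadata)
  new("MilkFeatureSet", se)
}

#' @describeIn featureMatrix vectors as rows, features as columns
#' @export
setMethod("featureMatrix", "MilkFeatureSet", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @describeIn speciesLabels one label per consensus vector
#' @export
setMethod("speciesLabels", "MilkFeatureSet", function(x)
  SummarizedExperiment::colData(x)$species)

#' @describeIn sampleIds source sample of each consensus vector
#' @export
setMethod("sampleIds", "MilkFeatureSet", function(x)
  SummarizedExperiment::colData(x)$sample)

#' Class indices (0 = bovine, 1 = goat, 2 = sheep)
#' @param x a [MilkFeatureSet-class].
#' @return integer vector in 0:2, one per consensus vector.
#' @export
classIndices <- function(x) {
  stopifnot(is(x, "MilkFeatureSet"))
  SummarizedExperiment::colData(x)$classIndex
}

setMethod("show", "SpectrumRun", function(object) {
  cat(sprintf("SpectrumRun: sample %s (farm %s), run %d, species %s\n",
              object@sampleId, object@farmId, object@runIndex,
              object@species))
  cat(sprintf("  %d peaks", nrow(object@peaks)))
  if (nrow(object@peaks))
    cat(sprintf(", m/z %.1f-%.1f Da", min(object@peaks$mz, na.rm = TRUE),
                max(object@peaks$mz, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "MilkDataset", function(object) {
  sp <- speciesLabels(object)
  cat(sprintf("MilkDataset: %d runs, %d samples\n", length(object@runs),
              length(sampleIds(object))))
  if (length(sp)) {
    tab <- table(factor(sp, levels = c(MILK_SPECIES, "Unknown")))
    tab <- tab[tab > 0]
    cat("  runs per species:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(object@provenance$source))
    cat("  source:", object@provenance$source, "\n")
})

setMethod("show", "MilkFeatureSet", function(object) {
  cat(sprintf("MilkFeatureSet: %d consensus vectors x %d features\n",
              ncol(object), nrow(object)))
  tab <- table(factor(speciesLabels(object), levels = MILK_SPECIES))
  cat("  per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(S4Vectors::metadata(object)$scaled))
    cat("  robust-scaled:", S4Vectors::metadata(object)$scaled, "\n")
})

setMethod("show", "RobustScaler", function(object) {
  cat("RobustScaler (median/IQR per feature)\n")
  print(round(rbind(median = object@center, IQR_divisor = object@scale), 4))
  if (any(object@zeroIqr))
    cat("  zero-IQR features (divisor 1):",
        paste(names(object@center)[object@zeroIqr], collapse = ", "), "\n")
})

setMethod("show", "FnnModel", function(object) {
  cat(sprintf("FnnModel: layers %s (ReLU hidden, softmax output)\n",
              paste(object@layerSizes, collapse = "-")))
  np <- sum(vapply(object@weights, length, numeric(1))) +
    sum(vapply(object@biases, length, numeric(1)))
  cat(sprintf("  %d parameters, init seed %d\n", np, object@seed))
})

setMethod("show", "CrossValResult", function(object) {
  cat(sprintf("CrossValResult: %d-fold cross-validation (seed %d)\n",
              object@k, object@seed))
  print(transform(object@summary, mean = round(mean, 4), sd = round(sd, 4)),
        row.names = FALSE)
  cat("Aggregated test confusion matrix (rows = true):\n")
  print(object@confusion)
})

setMethod("show", "SpeciesSignature", function(object) {
  cat(sprintf("SpeciesSignature: %s, %d base masses (%.0f-%.0f Da)\n",
              object@species, length(object@baseMasses),
              min(object@baseMasses), max(object@baseMasses)))
  cat(sprintf("  mass jitter %.0f ppm, intensity CV %.2f\n",
              object@massJitterPpm, object@intensityCv))
})

#' Per-fold metric table of a cross-validation result
#' @param x a [CrossValResult-class].
#' @return data.frame with one row per evaluated fold.
#' @export
cvFolds <- function(x) { stopifnot(is(x, "CrossValResult")); x@folds }

#' Mean +/- sd metric summary of a cross-validation result
#' @param x a [CrossValResult-class].
#' @return data.frame with columns metric, mean, sd.
#' @export
cvSummary <- function(x) { stopifnot(is(x, "CrossValResult")); x@summary }

#' Aggregated test-fold confusion matrix
#' @param x a [CrossValResult-class].
#' @return 3 x 3 matrix of counts, rows = true class, columns = predicted.
#' @export
cvConfusion <- function(x) { stopifnot(is(x, "CrossValResult")); x@confusion }
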