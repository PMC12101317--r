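#' @include synthetic-data.R preprocessing.R evaluation.R
NULL

#' Default pipeline configuration
#'
#' One nested list drives every pipeline stage; [readPipelineConfig()] merges
#' a YAML file over these defaults. Sections: `simulation` (samples per
#' species, runs per sample, QC-failure rate, signature overlap), `qc`
#' (thresholds), `consensus` (matching tolerance in Da), `training` (epochs,
#' batch size, Adam settings), `evaluation` (folds), `mixture` (number of
#' samples and nominal proportions), and the master `seed`.
#'
#' @param seed master seed recorded in the config.
#' @return nested named list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(
      nSamplesPerSpecies = c(Bovine_Milk = 6L, Goat_Milk = 14L,
                             Sheep_Milk = 22L),
      runsPerSample = 3L, qcFailRate = 0.1, overlap = 0.4,
      massJitterPpm = 200, intensityCv = 0.35),
    qc = list(minIntensity = 1000, minSnr = 5, minResolution = 400),
    consensus = list(tol = 2.0),
    training = list(epochs = 25L, batchSize = 32L, learningRate = 1e-3,
                    useClassWeights = TRUE),
    evaluation = list(k = 10L, stratified = FALSE),
    mixture = list(nSamples = 5L, runsPerSample = 3L,
                   proportions = c(Goat_Milk = 0.5, Sheep_Milk = 0.5)))
}

#' Read a pipeline configuration file
#'
#' @param path YAML file; fields present override the defaults of
#'   [defaultPipelineConfig()], absent fields keep them.
#' @param seed fallback master seed when the file sets none.
#' @return nested named list.
#' @export
readPipelineConfig <- function(path = NULL, seed = 1L) {
  cfg <- defaultPipelineConfig(seed)
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  mergeList <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        mergeList(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  mergeList(cfg, user)
}

pipelineSimConfig <- function(config) {
  sim <- config$simulation
  simConfig(
    signatures = defaultSignatures(
      seed = config$seed, overlap = sim$overlap,
      massJitterPpm = sim$massJitterPpm, intensityCv = sim$intensityCv),
    nSamplesPerSpecies = unlist(sim$nSamplesPerSpecies),
    runsPerSample = sim$runsPerSample, qcFailRate = sim$qcFailRate,
    seed = config$seed)
}

stamp <- function(config) list(configDigest = configDigest(config),
                               seed = config$seed)

#' Pipeline stage: simulate a dataset to disk
#'
#' Generates the synthetic dataset described by `config$simulation` and
#' writes it as a species-labelled folder tree with a YAML manifest and a
#' JSON generation log carrying the config digest.
#'
#' @param config list from [readPipelineConfig()].
#' @param outDir output directory.
#' @param force overwrite a non-empty `outDir`.
#' @return the generated [MilkDataset-class], invisibly.
#' @export
runSimulate <- function(config, outDir, force = FALSE) {
  if (dir.exists(outDir) && length(list.files(outDir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE): ", outDir)
  ds <- generateDataset(pipelineSimConfig(config), outDir = outDir)
  log <- c(stamp(config), list(stage = "simulate", nRuns = nRuns(ds),
                               nSamples = length(sampleIds(ds))))
  jsonlite::write_json(log, file.path(outDir, "simulate_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(ds)
}

#' Pipeline stage: preprocess a dataset tree into a feature matrix
#'
#' Loads the peak-table tree, applies QC filtering and consensus extraction,
#' and writes `features.csv` (eight feature columns + sample + species) and
#' `preprocess_audit.json` with the row-count audit (rows read = rows kept +
#' rows removed, vectors emitted per sample).
#'
#' @param config list from [readPipelineConfig()].
#' @param datasetDir dataset root (as written by [runSimulate()]).
#' @param outDir output directory.
#' @return the [MilkFeatureSet-class], invisibly; zero surviving vectors is
#'   an error.
#' @export
runPreprocess <- function(config, datasetDir, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ds <- loadDatasetTree(datasetDir)
  thr <- do.call(qcThresholds, config$qc)
  fs <- buildFeatureMatrix(ds, thresholds = thr, tol = config$consensus$tol)
  if (ncol(fs) == 0)
    stop("preprocessing produced zero consensus vectors ",
         "(all rows failed QC?)")
  df <- as.data.frame(featureMatrix(fs))
  df$sample <- sampleIds(fs)
  df$species <- speciesLabels(fs)
  write.csv(df, file.path(outDir, "features.csv"), row.names = FALSE)
  audit <- c(stamp(config), list(stage = "preprocess"),
             S4Vectors::metadata(fs)$audit)
  jsonlite::write_json(audit, file.path(outDir, "preprocess_audit.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fs)
}

#' Read a features.csv back into a MilkFeatureSet
#' @param path the `features.csv` written by [runPreprocess()].
#' @return a [MilkFeatureSet-class].
#' @export
readFeatureMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  MilkFeatureSet(as.matrix(df[, PEAK_COLUMNS]), species = df$species,
                 sample = df$sample,
                 metadata = list(provenance = list(source = path)))
}

#' Pipeline stage: cross-validated evaluation
#'
#' Runs [crossValidate()] on a preprocessed feature matrix and writes
#' `cv_metrics.json` (per fold and mean +/- sd), `cv_folds.csv`,
#' `confusion_matrix.csv` and `roc_points.csv`, all stamped with the config
#' digest and seed.
#'
#' @param config list from [readPipelineConfig()].
#' @param featuresFile path to `features.csv`.
#' @param outDir output directory.
#' @return the [CrossValResult-class], invisibly.
#' @export
runEvaluate <- function(config, featuresFile, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fs <- readFeatureMatrix(featuresFile)
  tc <- fnnTrainConfig(epochs = config$training$epochs,
                       batchSize = config$training$batchSize,
                       learningRate = config$training$learningRate,
                       seed = config$seed)
  res <- crossValidate(fs, tc, k = config$evaluation$k, seed = config$seed,
                       stratified = isTRUE(config$evaluation$stratified),
                       useClassWeights =
                         isTRUE(config$training$useClassWeights))
  write.csv(cvFolds(res), file.path(outDir, "cv_folds.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(cvConfusion(res)),
            file.path(outDir, "confusion_matrix.csv"))
  jsonlite::write_json(
    c(stamp(config),
      list(stage = "evaluate", k = res@k,
           summary = cvSummary(res), folds = cvFolds(res))),
    file.path(outDir, "cv_metrics.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  # ROC points of a model trained on the full matrix, per class
  scaler <- fitRobustScaler(fs)
  fit <- fnnTrain(applyRobustScaler(scaler, fs), cfg = tc)
  roc <- rocAucOvr(classIndices(fs),
                   predictProba(fit$model, applyRobustScaler(scaler, fs)))
  pts <- do.call(rbind, lapply(names(roc$perClass), function(cl) {
    p <- roc$perClass[[cl]]$points
    if (is.null(p)) return(NULL)
    cbind(class = cl, p)
  }))
  write.csv(pts, file.path(outDir, "roc_points.csv"), row.names = FALSE)
  invisible(res)
}

#' Pipeline stage: mixture assessment
#'
#' Trains the classifier on the full feature matrix (scaler and class
#' weights fitted on it), generates the configured number of two-species
#' mixture samples, and writes `mixture_results.csv` and
#' `mixture_results.json` with per-sample estimated proportions, per-sample
#' error and the average error.
#'
#' @param config list from [readPipelineConfig()].
#' @param featuresFile path to `features.csv` of the training data.
#' @param outDir output directory.
#' @return the [evaluateMixture()] result, invisibly.
#' @export
runMixture <- function(config, featuresFile, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fs <- readFeatureMatrix(featuresFile)
  scaler <- fitRobustScaler(fs)
  tc <- fnnTrainConfig(epochs = config$training$epochs,
                       batchSize = config$training$batchSize,
                       learningRate = config$training$learningRate,
                       classWeights = computeClassWeights(classIndices(fs)),
                       seed = config$seed)
  fit <- fnnTrain(applyRobustScaler(scaler, fs), classIndices(fs), tc)
  sigs <- defaultSignatures(seed = config$seed,
                            overlap = config$simulation$overlap,
                            massJitterPpm = config$simulation$massJitterPpm,
                            intensityCv = config$simulation$intensityCv)
  prop <- unlist(config$mixture$proportions)
  comp <- sigs[names(prop)]
  mixSeeds <- deriveSeeds(config$seed + 1L, config$mixture$nSamples)
  samples <- lapply(seq_len(config$mixture$nSamples), function(i)
    generateMixtureSample(comp, unname(prop),
                          nRuns = config$mixture$runsPerSample,
                          qcFailRate = config$simulation$qcFailRate,
                          sampleId = sprintf("mix%02d", i),
                          seed = mixSeeds[i]))
  thr <- do.call(qcThresholds, config$qc)
  res <- evaluateMixture(fit$model, scaler, samples, thresholds = thr,
                         tol = config$consensus$tol, nominal = prop)
  write.csv(res$perSample, file.path(outDir, "mixture_results.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    c(stamp(config), list(stage = "mixture", perSample = res$perSample,
                          averageError = res$averageError)),
    file.path(outDir, "mixture_results.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(res)
}
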