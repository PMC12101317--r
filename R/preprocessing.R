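#' @include AllClasses.R AllGenerics.R methods-accessors.R
NULL

#' Quality-control thresholds
#'
#' Minimum peak quality required for a row to enter the analysis: intensity
#' >= 1000 a.u., signal-to-noise >= 5 and resolution >= 400, all inclusive.
#'
#' @param minIntensity,minSnr,minResolution non-negative thresholds.
#' @return named list of class `"QcThresholds"`.
#' @export
qcThresholds <- function(minIntensity = 1000, minSnr = 5,
                         minResolution = 400) {
  stopifnot(minIntensity >= 0, minSnr >= 0, minResolution >= 0)
  structure(list(minIntensity = minIntensity, minSnr = minSnr,
                 minResolution = minResolution), class = "QcThresholds")
}

#' @describeIn qcFilter filter one run's peak rows
#' @export
setMethod("qcFilter", "SpectrumRun", function(x, thresholds = qcThresholds()) {
  pk <- x@peaks
  if (nrow(pk) == 0) return(x)
  complete <- rowSums(is.na(pk[, PEAK_COLUMNS])) == 0
  keep <- complete &
    !is.na(pk$intensity) & pk$intensity >= thresholds$minIntensity &
    !is.na(pk$snr) & pk$snr >= thresholds$minSnr &
    !is.na(pk$resolution) & pk$resolution >= thresholds$minResolution
  keep[is.na(keep)] <- FALSE
  out <- x
  out@peaks <- pk[keep, , drop = FALSE]
  rownames(out@peaks) <- NULL
  attr(out@peaks, "nRemoved") <- sum(!keep)
  out
})

#' @describeIn qcFilter filter every run of a dataset; removed-row counts are
#'   accumulated into the provenance field `qcRemoved`.
#' @export
setMethod("qcFilter", "MilkDataset", function(x, thresholds = qcThresholds()) {
  runs <- lapply(x@runs, qcFilter, thresholds = thresholds)
  removed <- sum(vapply(runs, function(r)
    attr(r@peaks, "nRemoved") %||% 0L, numeric(1)))
  prov <- x@provenance
  prov$qcRemoved <- removed
  prov$qcThresholds <- unclass(thresholds)
  MilkDataset(runs, provenance = prov)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closest-mass consensus vectors across replicate runs
#'
#' Implements the cross-run consensus rule: for every surviving peak row p of
#' every run of one sample, the single closest-mass row of each *other* run
#' is located; rows within `tol` Da join p's match set, and the consensus
#' vector is the element-wise mean of all eight features over the match set
#' (which always includes p itself). The output therefore has exactly one
#' vector per input row -- n vectors for n total rows across the sample's
#' runs. A row may serve as nearest neighbour to several seed rows
#' (non-exclusive matching), and no deduplication is performed.
#'
#' @param runs list of QC-filtered [SpectrumRun-class] objects from one
#'   sample (one run is allowed: each vector is then the row itself).
#' @param tol matching tolerance in Da; the default 2.0 Da corresponds to
#'   200 ppm at the top of the 3,000-10,000 Da window.
#' @return data.frame with the eight consensus features plus `sample` and
#'   `species` columns, one row per input peak row.
#' @examples
#' sig <- defaultSignatures(1)[[1]]
#' runs <- lapply(1:3, function(r)
#'   qcFilter(generateRun(sig, sampleId = "s1", runIndex = r, seed = r)))
#' head(consensusVectors(runs))
#' @export
consensusVectors <- function(runs, tol = 2.0) {
  if (length(runs) == 0) stop("'runs' must contain at least one SpectrumRun")
  stopifnot(all(vapply(runs, is, logical(1), "SpectrumRun")), tol >= 0)
  sid <- unique(vapply(runs, slot, character(1), "sampleId"))
  spc <- unique(vapply(runs, slot, character(1), "species"))
  if (length(sid) > 1)
    stop("consensusVectors expects the runs of a single sample")
  mats <- lapply(runs, function(r) as.matrix(r@peaks[, PEAK_COLUMNS]))
  nPer <- vapply(mats, nrow, integer(1))
  out <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    if (nPer[i] == 0) { out[[i]] <- NULL; next }
    acc <- mats[[i]]
    cnt <- rep(1, nPer[i])
    mzI <- mats[[i]][, "mz"]
    for (j in seq_along(mats)) {
      if (j == i || nPer[j] == 0) next
      mzJ <- mats[[j]][, "mz"]      # generator and QC keep rows mz-sorted
      ord <- order(mzJ)
      mzS <- mzJ[ord]
      pos <- findInterval(mzI, mzS)
      lo <- pmax(pos, 1L)
      hi <- pmin(pos + 1L, length(mzS))
      dLo <- abs(mzI - mzS[lo])
      dHi <- abs(mzS[hi] - mzI)
      nearest <- ifelse(dHi < dLo, hi, lo)   # ties -> lower mass
      dist <- pmin(dLo, dHi)
      hit <- dist <= tol
      if (any(hit)) {
        acc[hit, ] <- acc[hit, , drop = FALSE] +
          mats[[j]][ord, , drop = FALSE][nearest[hit], , drop = FALSE]
        cnt[hit] <- cnt[hit] + 1
      }
    }
    out[[i]] <- acc / cnt
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(numeric(0), 0, length(PEAK_COLUMNS),
                                  dimnames = list(NULL, PEAK_COLUMNS))
  df <- as.data.frame(res)
  df$sample <- rep(if (length(sid)) sid else NA_character_, nrow(df))
  df$species <- rep(if (length(spc) == 1) spc else "Unknown", nrow(df))
  rownames(df) <- NULL
  df
}

#' Build the consensus feature matrix for a whole dataset
#'
#' Runs the full preprocessing stage: QC filtering of every run, per-sample
#' closest-mass consensus extraction, and assembly into a
#' [MilkFeatureSet-class]. The returned object's metadata holds a row-count
#' audit (`rowsRead`, `rowsRemoved`, `vectorsPerSample`).
#'
#' @param dataset a [MilkDataset-class].
#' @param thresholds QC thresholds from [qcThresholds()].
#' @param tol consensus matching tolerance in Da.
#' @return a [MilkFeatureSet-class] with one column per consensus vector.
#' @export
buildFeatureMatrix <- function(dataset, thresholds = qcThresholds(),
                               tol = 2.0) {
  stopifnot(is(dataset, "MilkDataset"))
  rowsRead <- sum(vapply(dataset@runs, function(r) nrow(r@peaks), integer(1)))
  filtered <- qcFilter(dataset, thresholds)
  rowsKept <- sum(vapply(filtered@runs, function(r) nrow(r@peaks),
                         integer(1)))
  sids <- sampleIds(filtered)
  pieces <- lapply(sids, function(s)
    consensusVectors(datasetRuns(filtered, s), tol = tol))
  all <- do.call(rbind, pieces)
  known <- all$species %in% MILK_SPECIES
  if (!all(known)) {
    warning(sum(!known), " consensus vectors with unknown species dropped")
    all <- all[known, , drop = FALSE]
  }
  audit <- list(rowsRead = rowsRead, rowsRemoved = rowsRead - rowsKept,
                rowsKept = rowsKept,
                vectorsPerSample = setNames(
                  vapply(pieces, nrow, integer(1)), sids),
                qcThresholds = unclass(thresholds), tol = tol)
  MilkFeatureSet(as.matrix(all[, PEAK_COLUMNS]), species = all$species,
                 sample = all$sample,
                 metadata = list(audit = audit,
                                 provenance = dataset@provenance))
}

#' Fit a robust (median/IQR) scaler
#'
#' Computes per-feature median and interquartile range (Q75 - Q25 with
#' linear-interpolation quantiles, R type 7) over training rows only, for
#' the transform x' = (x - median) / IQR. Features with IQR exactly 0 are
#' flagged and given divisor 1. To avoid leakage, fit on the training fold
#' and apply to both folds ([applyRobustScaler()]).
#'
#' @param x numeric matrix (rows = vectors) or [MilkFeatureSet-class] of
#'   training data; at least 2 rows.
#' @return a [RobustScaler-class].
#' @export
fitRobustScaler <- function(x) {
  m <- if (is(x, "MilkFeatureSet")) featureMatrix(x) else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 training rows to fit a scaler")
  center <- apply(m, 2, median)
  iqr <- apply(m, 2, IQR, type = 7)
  zero <- iqr == 0
  scale <- ifelse(zero, 1, iqr)
  new("RobustScaler", center = center, scale = scale, zeroIqr = zero,
      fittedOn = configDigest(list(dim = dim(m), head = m[1, ],
                                   center = center)))
}

scalerTransform <- function(scaler, m, invert = FALSE) {
  m <- as.matrix(m)
  if (ncol(m) != length(scaler@center))
    stop("feature count does not match the fitted scaler")
  if (invert)
    sweep(sweep(m, 2, scaler@scale, "*"), 2, scaler@center, "+")
  else
    sweep(sweep(m, 2, scaler@center, "-"), 2, scaler@scale, "/")
}

#' @describeIn applyRobustScaler scale a plain matrix
#' @export
setMethod("applyRobustScaler", signature("RobustScaler", "matrix"),
  function(scaler, x) scalerTransform(scaler, x))

#' @describeIn applyRobustScaler scale a feature set (metadata records it)
#' @export
setMethod("applyRobustScaler", signature("RobustScaler", "MilkFeatureSet"),
  function(scaler, x) {
    scaled <- scalerTransform(scaler, featureMatrix(x))
    md <- S4Vectors::metadata(x)
    md$scaled <- TRUE
    MilkFeatureSet(scaled, species = speciesLabels(x),
                   sample = sampleIds(x), metadata = md)
  })

#' @describeIn invertRobustScaler invert on a plain matrix
#' @export
setMethod("invertRobustScaler", signature("RobustScaler", "matrix"),
  function(scaler, x) scalerTransform(scaler, x, invert = TRUE))

#' @describeIn invertRobustScaler invert on a feature set
#' @export
setMethod("invertRobustScaler", signature("RobustScaler", "MilkFeatureSet"),
  function(scaler, x) {
    raw <- scalerTransform(scaler, featureMatrix(x), invert = TRUE)
    md <- S4Vectors::metadata(x)
    md$scaled <- FALSE
    MilkFeatureSet(raw, species = speciesLabels(x),
                   sample = sampleIds(x), metadata = md)
  })
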