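# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

PEAK_COLS <- c("mz", "time", "intensity", "snr", "resolution",
               "area", "rel_intensity", "fwhm")

# A SpectrumRun with given m/z values and simple distinguishable features.
makeRun <- function(mz, sampleId = "s1", runIndex = 1L,
                    species = "Bovine_Milk", intensity = NULL) {
  n <- length(mz)
  if (n == 0)
    return(SpectrumRun(data.frame(), farmId = "f1", sampleId = sampleId,
                       runIndex = runIndex, species = species))
  if (is.null(intensity)) intensity <- 2000 + seq_len(n)
  pk <- data.frame(mz = mz, time = sqrt(mz), intensity = intensity,
                   snr = 10 + seq_len(n), resolution = 800 + seq_len(n),
                   area = intensity * 2, rel_intensity = intensity /
                     max(intensity), fwhm = mz / 800)
  SpectrumRun(pk, farmId = "f1", sampleId = sampleId,
              runIndex = runIndex, species = species)
}

# Brute-force consensus oracle: literal per-row nearest-neighbour averaging
# over all pairs, independent of the package's vectorised implementation.
bruteForceConsensus <- function(runs, tol) {
  mats <- lapply(runs, function(r) as.matrix(peakTable(r)[, PEAK_COLS]))
  out <- list()
  for (i in seq_along(mats)) {
    mi <- mats[[i]]
    for (p in seq_len(nrow(mi))) {
      members <- list(mi[p, ])
      for (j in seq_along(mats)) {
        if (j == i || nrow(mats[[j]]) == 0) next
        d <- abs(mats[[j]][, "mz"] - mi[p, "mz"])
        best <- which(d == min(d))
        if (length(best) > 1)          # distance tie -> lower mass
          best <- best[which.min(mats[[j]][best, "mz"])]
        if (d[best] <= tol)
          members[[length(members) + 1L]] <- mats[[j]][best, ]
      }
      out[[length(out) + 1L]] <- colMeans(do.call(rbind, members))
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- PEAK_COLS
  m
}

# Mann-Whitney U normalisation: AUC as the probability that a random
# positive outscores a random negative (ties count 1/2).
uStatisticAuc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  comp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(comp)
}

# Tiny dataset for fast end-to-end tests.
tinyFeatureSet <- function(seed = 42, nSamples = c(2, 3, 3), overlap = 0,
                           qcFailRate = 0.1) {
  sigs <- defaultSignatures(seed, nMasses = c(6, 6, 6), overlap = overlap,
                            minSep = 150)
  cfg <- simConfig(signatures = sigs, nSamplesPerSpecies = nSamples,
                   qcFailRate = qcFailRate, seed = seed)
  buildFeatureMatrix(generateDataset(cfg))
}
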