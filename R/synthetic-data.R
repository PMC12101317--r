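#' @include AllClasses.R methods-accessors.R peaklist-io.R
NULL

#' Construct a SpeciesSignature
#'
#' @param species species label.
#' @param baseMasses numeric peak centres (Da) in \[3000, 10000\], >= 3.
#' @param baseIntensities positive base intensity per mass; defaults to a
#'   deterministic log-spaced profile.
#' @param massJitterPpm per-run mass error sd in ppm (default 200, the
#'   calibration accuracy of a routinely calibrated linear-mode instrument).
#' @param intensityCv coefficient of variation of run-to-run peak intensity.
#' @return a [SpeciesSignature-class].
#' @export
speciesSignature <- function(species, baseMasses, baseIntensities = NULL,
                             massJitterPpm = 200, intensityCv = 0.35) {
  baseMasses <- sort(as.numeric(baseMasses))
  if (is.null(baseIntensities))
    baseIntensities <- 5000 * exp(seq(-0.5, 0.5,
                                      length.out = length(baseMasses)))
  new("SpeciesSignature", species = species, baseMasses = baseMasses,
      baseIntensities = as.numeric(baseIntensities),
      massJitterPpm = massJitterPpm, intensityCv = intensityCv)
}

# Draw masses uniformly in the acquisition window with a minimum spacing,
# so distinct peaks never sit closer than the consensus tolerance.
drawSpacedMasses <- function(n, existing = numeric(0), minSep = 15) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    cand <- runif(1, MZ_WINDOW[1] + 50, MZ_WINDOW[2] - 50)
    if (all(abs(cand - c(existing, out)) >= minSep))
      out <- c(out, cand)
    guard <- guard + 1L
    if (guard > 100000L) stop("cannot place masses with requested spacing")
  }
  sort(out)
}

#' Default species fingerprints
#'
#' Builds three species signatures with a documented overlap structure:
#' a fraction `overlap` of each species' masses is drawn from a pool shared
#' by all three species (emulating homologous casein masses), the remainder
#' are species-unique. Shared masses carry a shared base intensity, so
#' overlapping peaks look alike across species and the `overlap` fraction is
#' a genuine separability dial: `overlap = 0` gives disjoint fingerprints.
#' Deterministic given `seed`.
#'
#' The default fingerprint sizes (27, 27, 26 masses for bovine, goat, sheep)
#' emulate the roughly 23-25 QC-surviving peaks per exported spectrum implied
#' by the study design this generator mimics.
#'
#' @param seed integer seed.
#' @param nMasses integer vector of fingerprint sizes per species.
#' @param overlap fraction in \[0, 1\] of each fingerprint drawn from the
#'   shared pool.
#' @param minSep minimum spacing (Da) between any two distinct base masses;
#'   larger values give more widely separated, easier-to-learn
#'   fingerprints.
#' @param massJitterPpm,intensityCv passed to [speciesSignature()].
#' @return named list of three [SpeciesSignature-class] objects.
#' @examples
#' sigs <- defaultSignatures(1)
#' sigs$Bovine_Milk
#' @export
defaultSignatures <- function(seed = 1, nMasses = c(27L, 27L, 26L),
                              overlap = 0.4, minSep = 15,
                              massJitterPpm = 200, intensityCv = 0.35) {
  stopifnot(length(nMasses) == 3, overlap >= 0, overlap <= 1)
  withSeed(seed, {
    nShared <- round(overlap * min(nMasses))
    shared <- drawSpacedMasses(nShared, minSep = minSep)
    sharedInt <- rlnorm(nShared, meanlog = log(5000), sdlog = 0.4)
    placed <- shared
    sigs <- list()
    for (i in seq_along(MILK_SPECIES)) {
      nUnique <- nMasses[i] - nShared
      uniq <- drawSpacedMasses(nUnique, existing = placed, minSep = minSep)
      placed <- c(placed, uniq)
      masses <- c(shared, uniq)
      ints <- c(sharedInt, rlnorm(nUnique, meanlog = log(5000), sdlog = 0.4))
      ord <- order(masses)
      sigs[[MILK_SPECIES[i]]] <- speciesSignature(
        MILK_SPECIES[i], masses[ord], ints[ord],
        massJitterPpm = massJitterPpm, intensityCv = intensityCv)
    }
    sigs
  })
}

#' Construct a SimConfig
#'
#' Defaults emulate the study conditions this generator stands in for:
#' triplicate runs per sample, samples per species in proportion to the
#' per-species spectrum counts of the emulated study (6 : 14 : 22 for
#' bovine : goat : sheep, a 1/36 scale of 648 : 1,554 : 2,392, keeping the
#' class imbalance), a 10% QC-failure rate among generated peak rows, and
#' 200 ppm mass jitter via the default signatures.
#'
#' @param signatures list of three [SpeciesSignature-class] objects.
#' @param nSamplesPerSpecies integer vector (named or positional,
#'   bovine/goat/sheep order).
#' @param runsPerSample replicate runs per sample (>= 2; default triplicate).
#' @param qcFailRate probability a generated peak row is degraded below one
#'   QC threshold.
#' @param classMix optional named proportions for mixture generation.
#' @param seed master seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(signatures = defaultSignatures(seed),
                      nSamplesPerSpecies = c(Bovine_Milk = 6L,
                                             Goat_Milk = 14L,
                                             Sheep_Milk = 22L),
                      runsPerSample = 3L, qcFailRate = 0.1,
                      classMix = numeric(0), seed = 1L) {
  n <- as.integer(nSamplesPerSpecies)
  if (is.null(names(nSamplesPerSpecies))) names(n) <- MILK_SPECIES
  else names(n) <- names(nSamplesPerSpecies)
  new("SimConfig", signatures = signatures, nSamplesPerSpecies = n,
      runsPerSample = as.integer(runsPerSample),
      qcFailRate = qcFailRate, classMix = as.numeric(classMix),
      seed = as.integer(seed))
}

# Emission model for one peak row given its (possibly jittered) centre mass
# and base intensity. Rows destined to pass QC have their quality metrics
# truncated at the thresholds; failing rows are degraded below one threshold
# chosen uniformly.
emitPeakRows <- function(mz, baseInt, intensityCv, qcFailRate) {
  n <- length(mz)
  sdlog <- sqrt(log(1 + intensityCv^2))
  intensity <- rlnorm(n, meanlog = log(baseInt), sdlog = sdlog)
  snr <- rlnorm(n, meanlog = log(20), sdlog = 0.5)
  resolution <- rnorm(n, 800, 150)
  # QC-passing rows stay at or above every threshold
  intensity <- pmax(intensity, 1000)
  snr <- pmax(snr, 5)
  resolution <- pmax(resolution, 400)
  fail <- runif(n) < qcFailRate
  which3 <- sample.int(3L, n, replace = TRUE)
  degInt <- fail & which3 == 1L
  degSnr <- fail & which3 == 2L
  degRes <- fail & which3 == 3L
  intensity[degInt] <- runif(sum(degInt), 100, 999)
  snr[degSnr] <- runif(sum(degSnr), 0.5, 4.9)
  resolution[degRes] <- runif(sum(degRes), 100, 399)
  time <- 0.4 * sqrt(mz) + rnorm(n, 0, 0.05)   # TOF ~ sqrt(m/z)
  fwhm <- mz / resolution
  area <- 1.0645 * intensity * fwhm            # Gaussian peak shape
  rel_intensity <- intensity / max(intensity)
  data.frame(mz = mz, time = time, intensity = intensity, snr = snr,
             resolution = resolution, area = area,
             rel_intensity = rel_intensity, fwhm = fwhm)
}

#' Generate one synthetic acquisition run
#'
#' Emits one peak row per base mass of the signature: the observed m/z is the
#' centre perturbed by a Normal(0, jitter) relative error; intensity is
#' log-normal around the base intensity with the configured CV; S/N is
#' log-normal (median 20), resolution Normal(800, 150) truncated below at the
#' QC threshold for passing rows; FWHM = m/z / resolution; area follows a
#' Gaussian peak shape (1.0645 x intensity x FWHM); relative intensity is
#' intensity over the run maximum; acquisition time grows as sqrt(m/z).
#' With probability `qcFailRate` a row is instead degraded below one QC
#' threshold chosen uniformly among intensity, S/N and resolution.
#'
#' @param sig a [SpeciesSignature-class].
#' @param qcFailRate per-row QC failure probability.
#' @param sampleId,farmId,runIndex run metadata.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as [generateDataset()] does internally).
#' @return a [SpectrumRun-class] sorted by m/z.
#' @export
generateRun <- function(sig, qcFailRate = 0.1, sampleId = "synthetic",
                        farmId = "synthetic", runIndex = 1L, seed = NULL) {
  stopifnot(is(sig, "SpeciesSignature"))
  emit <- function() {
    mz <- sig@baseMasses *
      (1 + rnorm(length(sig@baseMasses), 0, sig@massJitterPpm * 1e-6))
    pk <- emitPeakRows(mz, sig@baseIntensities, sig@intensityCv, qcFailRate)
    pk <- pk[order(pk$mz), , drop = FALSE]
    rownames(pk) <- NULL
    pk
  }
  pk <- if (is.null(seed)) emit() else withSeed(seed, emit())
  SpectrumRun(pk, farmId = farmId, sampleId = sampleId,
              runIndex = runIndex, species = sig@species)
}

#' Generate a full labelled synthetic dataset
#'
#' Produces `nSamplesPerSpecies[s] * runsPerSample` runs per species, fully
#' reproducible from `cfg@seed`, as an in-memory [MilkDataset-class]; when
#' `outDir` is given the dataset is also written as a species-labelled folder
#' tree with a YAML manifest ([writeDatasetTree()]).
#'
#' @param cfg a [SimConfig-class].
#' @param outDir optional output directory.
#' @return a [MilkDataset-class] whose provenance records the generator
#'   configuration digest.
#' @examples
#' cfg <- simConfig(nSamplesPerSpecies = c(1, 1, 1), seed = 7)
#' generateDataset(cfg)
#' @export
generateDataset <- function(cfg, outDir = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  runs <- withSeed(cfg@seed, {
    out <- list()
    for (sp in MILK_SPECIES) {
      sig <- cfg@signatures[[sp]]
      if (is.null(sig))
        sig <- cfg@signatures[[match(sp, MILK_SPECIES)]]
      nS <- cfg@nSamplesPerSpecies[[sp]]
      if (is.na(nS)) nS <- cfg@nSamplesPerSpecies[[match(sp, MILK_SPECIES)]]
      abbrev <- c(Bovine_Milk = "bov", Goat_Milk = "cap",
                  Sheep_Milk = "ovi")[[sp]]
      for (i in seq_len(nS)) {
        farm <- sprintf("farm%s%02d", abbrev, i)
        sid <- sprintf("%s_s%02d", farm, i)
        for (r in seq_len(cfg@runsPerSample)) {
          out[[length(out) + 1L]] <- generateRun(
            sig, qcFailRate = cfg@qcFailRate, sampleId = sid,
            farmId = farm, runIndex = r)
        }
      }
    }
    out
  })
  ds <- MilkDataset(runs, provenance = list(
    source = "synthetic", seed = cfg@seed,
    configDigest = configDigest(list(
      n = as.list(cfg@nSamplesPerSpecies), runs = cfg@runsPerSample,
      qcFailRate = cfg@qcFailRate, seed = cfg@seed)),
    nRuns = length(runs)))
  if (!is.null(outDir)) writeDatasetTree(ds, outDir)
  ds
}

#' Generate a two-species mixture sample
#'
#' Emulates a milk mixture: each run draws, for every base mass of every
#' component species, a Bernoulli(`proportions[s]`) inclusion, and scales the
#' included peak's base intensity by the component proportion. A (1, 0)
#' mixture therefore reproduces the pure-species generator.
#'
#' @param sigs list of [SpeciesSignature-class] objects (the components).
#' @param proportions numeric of the same length, summing to 1.
#' @param nRuns number of replicate runs to emit.
#' @param qcFailRate per-row QC failure probability.
#' @param sampleId sample identifier for the emitted runs.
#' @param seed seed.
#' @return list of [SpectrumRun-class] with species `"Unknown"`.
#' @export
generateMixtureSample <- function(sigs, proportions, nRuns = 3,
                                  qcFailRate = 0.1, sampleId = "mixture",
                                  seed = 1) {
  stopifnot(length(sigs) == length(proportions))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("mixture proportions must sum to 1 (got ", sum(proportions), ")")
  withSeed(seed, {
    lapply(seq_len(nRuns), function(r) {
      mz <- numeric(0); bint <- numeric(0); cv <- numeric(0)
      for (k in seq_along(sigs)) {
        p <- proportions[k]
        if (p <= 0) next
        sig <- sigs[[k]]
        keep <- runif(length(sig@baseMasses)) < p
        jit <- sig@baseMasses[keep] *
          (1 + rnorm(sum(keep), 0, sig@massJitterPpm * 1e-6))
        mz <- c(mz, jit)
        bint <- c(bint, sig@baseIntensities[keep] * p)
        cv <- c(cv, rep(sig@intensityCv, sum(keep)))
      }
      if (length(mz) == 0) {
        pk <- emptyPeakFrame()
      } else {
        pk <- emitPeakRows(mz, bint, cv[1], qcFailRate)
        pk <- pk[order(pk$mz), , drop = FALSE]
        rownames(pk) <- NULL
      }
      SpectrumRun(pk, farmId = sampleId, sampleId = sampleId,
                  runIndex = r, species = "Unknown")
    })
  })
}
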