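test_that("QC thresholds are inclusive and missing values are removed", {
  pk <- data.frame(
    mz = c(5000, 5100, 5200, 5300, 5400, 5500),
    time = 30, intensity = c(1200, 999, 1500, 1500, 1000, 1500),
    snr = c(6, 8, 4.9, 8, 5, 8),
    resolution = c(500, 600, 700, 399, 400, 800),
    area = 100, rel_intensity = 0.5, fwhm = 6)
  pk$area[6] <- NA   # missing value in an otherwise-passing row
  run <- SpectrumRun(pk, sampleId = "s", species = "Goat_Milk")
  kept <- peakTable(qcFilter(run))
  # row 1 passes; rows 2-4 each fail one threshold strictly below it;
  # row 5 sits exactly at all three thresholds (>= is inclusive);
  # row 6 has a missing field
  expect_equal(kept$mz, c(5000, 5400))
  expect_equal(attr(kept, "nRemoved"), 4L)
})

test_that("qcFilter is idempotent and returns a subset in order", {
  run <- generateRun(defaultSignatures(3)[[1]], qcFailRate = 0.5, seed = 2)
  once <- qcFilter(run)
  twice <- qcFilter(once)
  expect_equal(peakTable(twice)$mz, peakTable(once)$mz)
  expect_true(all(peakTable(once)$mz %in% peakTable(run)$mz))
  expect_false(is.unsorted(match(peakTable(once)$mz, peakTable(run)$mz)))
})

test_that("a single run's consensus vectors are the rows themselves", {
  run <- makeRun(c(5000, 6000, 7000), sampleId = "s1")
  cv <- consensusVectors(list(run))
  expect_equal(nrow(cv), 3)
  expect_equal(as.matrix(cv[, PEAK_COLS]),
               as.matrix(peakTable(run)[, PEAK_COLS]),
               ignore_attr = TRUE)
})

test_that("cross-run matches within tolerance average element-wise", {
  r1 <- makeRun(5000.0, sampleId = "s1", runIndex = 1, intensity = 2000)
  r2 <- makeRun(5000.4, sampleId = "s1", runIndex = 2, intensity = 3000)
  cv <- consensusVectors(list(r1, r2), tol = 2.0)
  expect_equal(nrow(cv), 2)
  expect_equal(cv$mz, c(5000.2, 5000.2))
  expect_equal(cv$intensity, c(2500, 2500))
  expect_equal(cv$time, rep(mean(sqrt(c(5000, 5000.4))), 2))

  # beyond tolerance the rows stay isolated
  r3 <- makeRun(5010.0, sampleId = "s1", runIndex = 2)
  iso <- consensusVectors(list(r1, r3), tol = 2.0)
  expect_equal(iso$mz, c(5000, 5010))
  expect_equal(iso$intensity, c(2000, 2001))

  expect_error(consensusVectors(list()), "at least one")
})

test_that("consensus matching equals the brute-force oracle", {
  set.seed(7)
  for (case in 1:60) {
    nRuns <- sample(1:3, 1)
    runs <- lapply(seq_len(nRuns), function(r)
      makeRun(sort(runif(sample(1:6, 1), 5000, 5030)), sampleId = "s1",
              runIndex = r, species = "Sheep_Milk"))
    tol <- runif(1, 0.5, 10)
    got <- as.matrix(consensusVectors(runs, tol = tol)[, PEAK_COLS])
    want <- bruteForceConsensus(runs, tol = tol)
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
    # n-vector bookkeeping and mz locality
    expect_equal(nrow(got), sum(vapply(runs, function(r)
      nrow(peakTable(r)), integer(1))))
  }
})

test_that("every consensus mz lies within tol of its contributing rows", {
  sig <- defaultSignatures(9)[[3]]
  runs <- lapply(1:3, function(r)
    qcFilter(generateRun(sig, sampleId = "s1", runIndex = r, seed = r)))
  tol <- 2.0
  cv <- consensusVectors(runs, tol = tol)
  allMz <- sort(unlist(lapply(runs, function(r) peakTable(r)$mz)))
  # a mean over rows all within tol of the seed is within tol of each
  expect_true(all(vapply(cv$mz, function(m)
    min(abs(allMz - m)) <= tol, logical(1))))
})

test_that("robust scaler follows the linear-interpolation quantile rule", {
  m <- cbind(matrix(rep(c(1, 2, 3, 4, 5), 8), 5, 8))
  colnames(m) <- PEAK_COLS
  sc <- fitRobustScaler(m)
  expect_equal(unname(sc@center), rep(3, 8))
  expect_equal(unname(sc@scale), rep(2, 8))
  scaled <- applyRobustScaler(sc, m)
  expect_equal(unname(scaled[, 1]), c(-1, -0.5, 0, 0.5, 1))
  # shuffling rows leaves the fit unchanged
  sc2 <- fitRobustScaler(m[c(4, 1, 5, 3, 2), ])
  expect_equal(sc2@center, sc@center)
  expect_equal(sc2@scale, sc@scale)
})

test_that("zero-IQR features fall back to divisor 1", {
  m <- matrix(rnorm(40), 5, 8, dimnames = list(NULL, PEAK_COLS))
  m[, 3] <- 7
  sc <- fitRobustScaler(m)
  expect_equal(unname(sc@center[3]), 7)
  expect_equal(unname(sc@scale[3]), 1)
  expect_true(sc@zeroIqr[3])
  expect_equal(unname(applyRobustScaler(sc, m)[, 3]), rep(0, 5))
})

test_that("scaling centres the training data and inverts exactly", {
  fs <- tinyFeatureSet(seed = 31)
  sc <- fitRobustScaler(fs)
  scaled <- applyRobustScaler(sc, fs)
  sm <- featureMatrix(scaled)
  expect_equal(unname(apply(sm, 2, median)), rep(0, 8), tolerance = 1e-12)
  iqrs <- apply(sm, 2, IQR)
  expect_equal(unname(iqrs[!sc@zeroIqr]),
               rep(1, sum(!sc@zeroIqr)), tolerance = 1e-12)
  back <- invertRobustScaler(sc, scaled)
  expect_equal(featureMatrix(back), featureMatrix(fs), tolerance = 1e-12)
  # applying at the median gives exactly zero
  expect_equal(unname(applyRobustScaler(sc, matrix(sc@center, 1))[1, ]),
               rep(0, 8))
  expect_error(applyRobustScaler(sc, matrix(0, 2, 5)), "feature count")
})

test_that("the preprocessing audit is additive and complete", {
  cfg <- simConfig(nSamplesPerSpecies = c(2, 2, 2), qcFailRate = 0.3,
                   seed = 17)
  ds <- generateDataset(cfg)
  fs <- buildFeatureMatrix(ds)
  audit <- S4Vectors::metadata(fs)$audit
  expect_equal(audit$rowsRead, audit$rowsKept + audit$rowsRemoved)
  expect_gt(audit$rowsRemoved, 0)
  # one consensus vector per surviving row, per sample and in total
  filtered <- qcFilter(ds)
  perSample <- vapply(sampleIds(filtered), function(s)
    sum(vapply(datasetRuns(filtered, s), function(r)
      nrow(peakTable(r)), integer(1))), integer(1))
  expect_equal(audit$vectorsPerSample[names(perSample)], perSample)
  expect_equal(ncol(fs), sum(perSample))
})
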