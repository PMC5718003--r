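test_that("long-format peak tables read into FractionSets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fraction\tmz\tintensity\tsnr",
               "1\t169.0143\t1000\t10",
               "2\t169.0143\t500\t6"), path)
  fs <- readPeakTable(path)
  expect_s4_class(fs, "FractionSet")
  expect_equal(nFractions(fs), 2L)
  expect_equal(nrow(fractionSpectrum(fs, 1)), 1L)
  expect_equal(nrow(fractionSpectrum(fs, 2)), 1L)

  # empty file with header -> zero peaks
  writeLines("fraction\tmz\tintensity\tsnr", path)
  expect_equal(nrow(peaks(readPeakTable(path, nFractions = 3))), 0L)

  # non-numeric cell is rejected with the offending row named
  writeLines(c("fraction\tmz\tintensity", "1\toops\t10"), path)
  expect_error(readPeakTable(path), "row 1")
  # NaN / Inf cells are rejected explicitly
  writeLines(c("fraction\tmz\tintensity", "1\t200.1\tInf"), path)
  expect_error(readPeakTable(path), "non-finite")
})

test_that("peak tables round-trip through write/read to 1e-9", {
  fs <- toyFractionSet(seed = 3, n = 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePeakTable(fs, path)
  back <- readPeakTable(path, nFractions = nFractions(fs))
  expect_equal(peaks(back)$mz, peaks(fs)$mz, tolerance = 1e-9)
  expect_equal(peaks(back)$intensity, peaks(fs)$intensity, tolerance = 1e-9)
  expect_equal(peaks(back)$snr, peaks(fs)$snr, tolerance = 1e-9)
})

test_that("activity profiles read ordered, validated, round-tripped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fraction\tactivity", "2\t0.9", "1\t0.1"), path)
  ap <- readActivityProfile(path)
  expect_equal(activityValues(ap), c(0.1, 0.9))

  writeLines(c("fraction\tactivity", "1\t0.1", "1\t0.9"), path)
  expect_error(readActivityProfile(path), "duplicate")
  writeLines(c("fraction\tactivity", "1\t0.1", "3\t0.9"), path)
  expect_error(readActivityProfile(path), "gap")

  # explicit %DPPH-remaining -> activity conversion
  writeLines(c("fraction\tactivity", "1\t40", "2\t90"), path)
  expect_equal(activityValues(readActivityProfile(path, convert = "inhibitionToActivity")),
               c(60, 10))

  ap <- ActivityProfile(runif(33))
  writeActivityProfile(ap, path)
  expect_equal(activityValues(readActivityProfile(path)),
               activityValues(ap), tolerance = 1e-9)
})

test_that("binned matrices round-trip and record their normalization", {
  m <- matrix(c(0, 5, 10, 0, 0, 0), nrow = 2, byrow = TRUE)
  bm <- BinnedMatrix(c(169.01425, 301.03538), m, binWidthPpm = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeBinnedMatrix(bm, path)
  back <- readBinnedMatrix(path)
  expect_equal(binCenters(back), binCenters(bm), tolerance = 1e-9)
  expect_equal(unname(intensityMatrix(back)), unname(intensityMatrix(bm)),
               tolerance = 1e-9)
  # all-zero rows are retained, not silently dropped
  expect_equal(nrow(back), 2L)
  expect_equal(binNormalization(back), "raw")

  # unit-norm rows are detected
  u <- t(apply(matrix(runif(6), 2), 1, function(v) v / sqrt(sum(v^2))))
  writeBinnedMatrix(BinnedMatrix(c(200, 300), u), path)
  expect_equal(binNormalization(readBinnedMatrix(path)), "unit")
  # percent-of-max rows are detected
  p <- t(apply(matrix(runif(6), 2), 1, function(v) v / max(v) * 100))
  writeBinnedMatrix(BinnedMatrix(c(200, 300), p), path)
  expect_equal(binNormalization(readBinnedMatrix(path)), "percent")

  # grouping annotation columns survive the round trip
  bm2 <- BinnedMatrix(c(200, 300), m,
                      rowData = data.frame(group_center = c(2, 1),
                                           group_nf = c(1, 1)))
  writeBinnedMatrix(bm2, path)
  expect_equal(SummarizedExperiment::rowData(readBinnedMatrix(path))$group_center,
               c(2, 1))
  # declared N must match the file
  expect_error(readBinnedMatrix(path, nFractions = 7), "declared")
})

test_that("percent DPPH remaining follows the absorbance ratio formula", {
  expect_equal(dpphInhibition(0.5, 1.0, 0.1), 40)
  expect_equal(dpphInhibition(0.3, 2.5, 0.3), 0)   # abT == abB
  expect_equal(dpphInhibition(1.1, 1.0, 0.1), 100)
  expect_error(dpphInhibition(0.5, 0, 0.1), "> 0")
  # linear in abT for fixed ab0, abB
  abT <- seq(0, 2, length.out = 9)
  vals <- dpphInhibition(abT, 1.7, 0.2)
  expect_equal(diff(vals), rep(diff(vals)[1], 8), tolerance = 1e-12)
})

test_that("candidate tables write in rank order and read back exactly", {
  ds <- simulateDataset(simulationConfig(seed = 5, nCompounds = 20,
                                         nActive = 2, nFractions = 12,
                                         nNoisePeaksPerFraction = 5,
                                         nBlankPeaks = 5))
  res <- runScamp(ds$fractions, ds$activity, blanks = ds$blanks)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCandidates(res$candidates, path)
  back <- readCandidates(path)
  expect_equal(back$rank, res$candidates$rank)
  expect_equal(back$score, res$candidates$score, tolerance = 1e-9)
  expect_equal(back$cj, res$candidates$cj, tolerance = 1e-9)

  # empty candidate list -> header-only file
  empty <- res$candidates[0, ]
  writeCandidates(empty, path)
  expect_equal(nrow(readCandidates(path)), 0L)
})
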