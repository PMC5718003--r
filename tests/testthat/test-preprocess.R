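test_that("blank averaging merges within tolerance and divides by replicate count", {
  one <- FractionSet(data.frame(fraction = 1, mz = c(200, 300),
                                intensity = c(50, 70)))
  avg <- averageBlanks(one)
  expect_equal(peaks(avg)$intensity, c(50, 70))

  two <- FractionSet(data.frame(fraction = c(1, 2), mz = c(200, 200),
                                intensity = c(300, 100)), nFractions = 2)
  expect_equal(peaks(averageBlanks(two))$intensity, 200)

  # present in 1 of 3 replicates at 900 -> mean with zeros = 300
  three <- FractionSet(data.frame(fraction = 2, mz = 450.123,
                                  intensity = 900), nFractions = 3)
  expect_equal(peaks(averageBlanks(three))$intensity, 300)

  expect_error(averageBlanks(FractionSet(nFractions = 0)), "at least one")
})

test_that("blank subtraction needs both a mass match and the intensity ratio", {
  sample <- FractionSet(data.frame(fraction = 1, mz = c(200.00000, 350.5),
                                   intensity = c(500, 800)))
  blank <- FractionSet(data.frame(fraction = 1, mz = 200.00005,
                                  intensity = 400))
  out <- subtractBlank(sample, blank, tolPpm = 1, ratio = 3)
  expect_equal(peaks(out)$mz, 350.5)        # 0.25 ppm apart, 500 <= 1200

  # strong signal over a trace blank peak survives at finite ratio
  strong <- FractionSet(data.frame(fraction = 1, mz = 200.00000,
                                   intensity = 5000))
  expect_equal(nrow(peaks(subtractBlank(strong, blank, 1, 3))), 1L)
  # ... but ratio = Inf removes on mass match alone
  expect_equal(nrow(peaks(subtractBlank(strong, blank, 1, Inf))), 0L)

  # empty blank leaves the spectrum unchanged
  expect_equal(peaks(subtractBlank(sample, FractionSet(nFractions = 1))),
               peaks(sample))
})

test_that("S/N filtering is strictly greater-than and keeps unknown S/N", {
  fs <- FractionSet(data.frame(fraction = 1, mz = c(100.1, 100.2, 100.3, 100.4),
                               intensity = 1, snr = c(3, 4, 5, NA)))
  out <- filterSnr(fs, 4)
  expect_equal(peaks(out)$mz, c(100.3, 100.4))
  expect_equal(attr(out, "nMissingSnr"), 1L)
  # brute-force count over random peaks
  fs <- toyFractionSet(seed = 9, n = 1000)
  expect_equal(nrow(peaks(filterSnr(fs, 25))),
               sum(peaks(fs)$snr > 25))
})

test_that("de-isotoping removes 13C satellites of stronger peaks only", {
  fs <- FractionSet(data.frame(fraction = 1,
                               mz = c(301.03538, 302.03873, 303.04209),
                               intensity = c(100, 16.5, 1.9)))
  out <- deisotope(fs, tolPpm = 1, maxShift = 3)
  expect_equal(peaks(out)$mz, 301.03538)

  single <- FractionSet(data.frame(fraction = 1, mz = 400.2, intensity = 10))
  expect_equal(peaks(deisotope(single)), peaks(single))

  # half a Dalton apart is not an isotope spacing
  pair <- FractionSet(data.frame(fraction = 1, mz = c(400.2, 400.7),
                                 intensity = c(10, 5)))
  expect_equal(nrow(peaks(deisotope(pair))), 2L)

  # optional plausibility check: a +1 "satellite" at 80% of the parent is
  # far beyond the carbon-count expectation (~0.27 at m/z 300) and is kept
  # when the check is on, removed by the purely mass-based default
  implausible <- FractionSet(data.frame(
    fraction = 1, mz = c(301.03538, 302.03873), intensity = c(100, 80)))
  expect_equal(nrow(peaks(deisotope(implausible))), 1L)
  expect_equal(nrow(peaks(deisotope(implausible, intensityCheck = TRUE))), 2L)
})

test_that("de-isotoping is idempotent and recovers planted monoisotopic peaks", {
  iso <- isotopeSpectrum(seed = 11, nCompounds = 30)
  once <- deisotope(iso$fset, tolPpm = 1, maxShift = 3)
  expect_equal(sort(peaks(once)$mz), sort(iso$monoMz), tolerance = 1e-9)
  twice <- deisotope(once, tolPpm = 1, maxShift = 3)
  expect_equal(peaks(twice), peaks(once))
  # the globally most intense peak always survives
  big <- peaks(iso$fset)$mz[which.max(peaks(iso$fset)$intensity)]
  expect_true(big %in% peaks(once)$mz)
  expect_lte(nrow(peaks(once)), nrow(peaks(iso$fset)))
})

test_that("cross-fraction binning joins by ppm and sums within a fraction", {
  fs <- FractionSet(data.frame(fraction = c(1, 2), mz = c(301.03538, 301.03540),
                               intensity = c(1000, 800)), nFractions = 2)
  bm <- binAcrossFractions(fs, binPpm = 0.5)
  expect_equal(nrow(bm), 1L)                      # 0.07 ppm apart
  expect_equal(unname(intensityMatrix(bm)[1, ]), c(1000, 800))

  fs <- FractionSet(data.frame(fraction = c(1, 1), mz = c(301.0354, 301.0360),
                               intensity = c(10, 10)))
  expect_equal(nrow(binAcrossFractions(fs, 0.5)), 2L)  # ~2 ppm apart

  fs <- FractionSet(data.frame(fraction = c(1, 1), mz = c(500.00000, 500.00010),
                               intensity = c(100, 50)))
  bm <- binAcrossFractions(fs, 0.5)
  expect_equal(nrow(bm), 1L)
  expect_equal(unname(intensityMatrix(bm)[1, 1]), 150)  # summed m_kj
})

test_that("binning conserves total intensity and orders centers", {
  fs <- toyFractionSet(seed = 21, n = 500)
  bm <- binAcrossFractions(fs, 0.5)
  expect_equal(sum(intensityMatrix(bm)), sum(peaks(fs)$intensity),
               tolerance = 1e-9)
  expect_true(all(diff(binCenters(bm)) > 0))
  expect_equal(ncol(bm), nFractions(fs))
})

test_that("preprocessing is independent of input peak ordering", {
  p <- peaks(toyFractionSet(seed = 2, n = 200))
  shuffled <- p[withr::with_seed(4, sample.int(nrow(p))), ]
  a <- binAcrossFractions(deisotope(FractionSet(p)), 0.5)
  b <- binAcrossFractions(deisotope(FractionSet(shuffled)), 0.5)
  expect_equal(binCenters(a), binCenters(b))
  expect_equal(intensityMatrix(a), intensityMatrix(b))
})

test_that("unit-resolution bin counting is inclusive", {
  expect_identical(countUnitBins(120, 1200), 1081L)
  expect_identical(countUnitBins(120, 120), 1L)
  expect_identical(countUnitBins(122, 1200), 1079L)
  expect_error(countUnitBins(1200, 120), "inverted")
})
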