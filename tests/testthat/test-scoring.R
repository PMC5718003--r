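test_that("vector normalization preserves direction and is idempotent", {
  expect_equal(normalizeVector(c(3, 4, 0)), c(0.6, 0.8, 0))
  u <- normalizeVector(runif(5))
  expect_equal(normalizeVector(u), u)
  expect_equal(normalizeVector(rep(0, 4)), rep(0, 4))  # degenerate
  v <- withr::with_seed(1, runif(33))
  expect_equal(sqrt(sum(normalizeVector(v)^2)), 1, tolerance = 1e-12)
})

test_that("C_j is the unit-norm dot product on the 0-100 scale", {
  a <- c(1, 3, 2, 0.5)
  expect_equal(correlationCj(7 * a, a), 100)            # proportional
  expect_equal(correlationCj(c(1, 0, 0), c(0, 2, 3)), 0)  # disjoint support
  expect_equal(correlationCj(c(4, 3, 0), c(3, 4, 0)), 96)
  expect_equal(correlationCj(rep(0, 4), a), 0)          # degenerate
  expect_error(correlationCj(c(1, 2), c(1, 2, 3)), "lengths differ")
  # bounds and invariance to positive rescaling, over random cases
  withr::with_seed(42, for (i in 1:25) {
    m <- runif(33); a <- runif(33)
    cj <- correlationCj(m, a)
    expect_gte(cj, 0); expect_lte(cj, 100 + 1e-9)
    expect_equal(correlationCj(m * runif(1, 0.1, 50), a), cj, tolerance = 1e-9)
    expect_equal(correlationCj(m, a * runif(1, 0.1, 50)), cj, tolerance = 1e-9)
  })
})

test_that("group finding takes maximal strictly-above-mean runs", {
  m <- c(0, 0, 5, 9, 5, 0, 0, 0, 4, 8, 4, 0)
  g <- findGroups(m)
  expect_equal(g$start, c(3L, 9L))
  expect_equal(g$end, c(5L, 11L))
  expect_equal(g$nf, c(3L, 3L))
  expect_equal(nrow(findGroups(rep(2, 6))), 0L)   # constant profile
  spike <- c(0, 0, 0, 7, 0, 0)
  g <- findGroups(spike)
  expect_equal(unlist(g), c(start = 4L, end = 4L, nf = 1L))
  # disjointness and exact coverage of the above-mean set, random profiles
  withr::with_seed(13, for (i in 1:20) {
    m <- rlnorm(33, 5, 2)
    g <- findGroups(m)
    covered <- unlist(mapply(seq, g$start, g$end, SIMPLIFY = FALSE))
    expect_false(any(duplicated(covered)))
    expect_setequal(covered, which(m > mean(m)))
  })
})

test_that("group statistics use the population standard deviation of raw values", {
  m <- c(0, 0, 5, 9, 5, 0)
  st <- groupStatistics(m, 3, 5)
  expect_equal(st$sigma, sqrt(mean((c(5, 9, 5) - 19 / 3)^2)), tolerance = 1e-12)
  expect_equal(st$sigma, 1.8856, tolerance = 1e-4)
  expect_equal(st$intensity, 19)
  expect_equal(st$nf, 3L)
  expect_equal(groupStatistics(c(1, 8, 1), 2, 2)$sigma, 0)  # single fraction
  expect_equal(groupStatistics(c(4, 4), 1, 2)$sigma, 0)     # all equal
  expect_error(groupStatistics(m, 0, 3), "bounds")
})

test_that("Score 2 and Score 3 follow their defining products", {
  expect_equal(score2(0, 1e6), 0)
  expect_equal(score2(96, 2.5e6), 2.4e8)
  expect_equal(score2(100, 1), 100)
  expect_equal(score3(50, 2, 1000, 4), 12500)
  expect_equal(score3(77, 0, 1e9, 3), 0)
  expect_equal(score3(10, 3, 100, 1) / score3(10, 3, 100, 2), 4)
})

test_that("methods 1 and 2 rank whole-bin profiles as specified", {
  a <- ActivityProfile(c(0, 1, 5, 1, 0))
  m <- rbind(c(0, 2, 10, 2, 0),     # proportional-ish to activity
             c(5, 0, 0, 0, 5))      # orthogonal-ish
  bm <- BinnedMatrix(c(200, 300), m)
  r1 <- rankCandidates(bm, a, method = 1)
  expect_equal(r1$rank, 1:2)
  expect_equal(r1$mz[1], 200)
  expect_gt(r1$cj[1], 99)           # exactly proportional gives 100
  expect_equal(rankCandidates(BinnedMatrix(200, m[1, , drop = FALSE] * 0.2), a,
                              method = 1)$cj, 100, tolerance = 1e-9)

  # equal C_j, intensity differing 10x: method 2 puts the bigger bin first
  m2 <- rbind(c(0, 2, 10, 2, 0), c(0, 20, 100, 20, 0))
  r2 <- rankCandidates(BinnedMatrix(c(200, 300), m2), a, method = 2)
  expect_equal(r2$mz[1], 300)
  expect_equal(r2$cj[1], r2$cj[2], tolerance = 1e-9)
  expect_equal(r2$score, r2$cj * r2$intensity)
})

test_that("method 3 splits coeluting isomers into per-region candidates", {
  tp <- twoIsomerProfile()
  bm <- BinnedMatrix(169.014, matrix(tp$profile, nrow = 1))

  # activity over both elution regions: the whole-profile C_j overstates
  # each single component, so grouping lowers both
  ungrouped <- correlationCj(tp$profile, tp$activityBoth)
  r3 <- rankCandidates(bm, ActivityProfile(tp$activityBoth), method = 3)
  expect_equal(nrow(r3), 2L)                 # two elution regions
  expect_true(all(r3$cj < ungrouped))
  expect_equal(r3$score3, r3$cj * r3$sigma^2 * r3$intensity / r3$nf^2)

  # activity on one region only: grouping isolates the true contributor
  rOne <- rankCandidates(bm, ActivityProfile(tp$activityOne), method = 3)
  onTarget <- rOne[rOne$start <= 4 & rOne$end >= 4, ]
  offTarget <- rOne[rOne$start > 6, ]
  expect_gt(onTarget$cj, 99)
  expect_lt(offTarget$cj, 1)
})

test_that("ranking is a deterministic permutation with stable tie-breaks", {
  withr::with_seed(31, {
    m <- matrix(rlnorm(20 * 12, 6, 1), nrow = 20)
    a <- ActivityProfile(runif(12))
  })
  bm <- BinnedMatrix(sort(runif(20, 120, 1200)), m)
  for (method in 1:3) {
    r <- rankCandidates(bm, a, method = method)
    expect_equal(r$rank, seq_len(nrow(r)))
    expect_true(all(diff(r$score) <= 1e-12))
    # per-bin group intensities never exceed the bin total
    if (method == 3) {
      idx <- match(r$mz, binCenters(bm))
      byBin <- tapply(r$intensity, idx, sum)
      tot <- rowSums(m)[as.integer(names(byBin))]
      expect_true(all(byBin <= tot + 1e-9))
    }
  }
  # speed filter drops candidates at or below the threshold
  r <- rankCandidates(bm, a, method = 1)
  rf <- rankCandidates(bm, a, method = 1, minCj = 50)
  expect_true(all(rf$cj > 50))
  expect_equal(nrow(rf), sum(r$cj > 50))
  expect_error(rankCandidates(bm, ActivityProfile(runif(5)), 1), "does not match")
  expect_error(rankCandidates(bm, a, method = 9), "unknown")
})
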