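## Ground-truth fractionation simulator: compounds with Gaussian elution
## over N sequential fractions, 13C satellites, shared blank background,
## sub-S/N noise peaks, and an activity profile that is a noisy weighted
## sum of the planted actives' per-fraction amounts. Every random draw
## flows from the single mandatory seed; identical seed => identical data.

#' Simulation configuration
#'
#' Defaults state the emulated study design: 33 sequential preparative-LC
#' fractions, 200 detectable compounds over m/z 120-1200, 8 planted
#' actives. Elution widths of 1-2 fractions correspond to peaks a few
#' minutes wide under 2-min fraction collection. Compound abundances are
#' log-normal (a few dominant constituents over a long trace tail); the
#' actives are drawn from compounds at or above the 90th abundance
#' percentile, because a bulk radical-scavenging assay's profile is
#' necessarily driven by major constituents. Activity noise is 5% of the
#' maximum noiseless activity.
#'
#' @param seed integer seed (mandatory; the only source of randomness).
#' @param nFractions number of sequential fractions N.
#' @param nCompounds number of compounds in the extract.
#' @param nActive number of planted actives (<= nCompounds).
#' @param mzRange m/z acquisition range.
#' @param widthRange Gaussian elution SD range, in fractions.
#' @param abundanceMeanLog,abundanceSdLog log-normal abundance parameters
#'   (arbitrary intensity counts).
#' @param activeAbundanceQuantile actives are sampled among compounds with
#'   abundance at or above this quantile.
#' @param potencySdLog log-normal SD of the active potency weights w_i
#'   (meanlog 0).
#' @param activityNoiseSd Gaussian activity noise SD, as a fraction of the
#'   maximum noiseless activity; the noisy profile is clipped at 0.
#' @param nBlankPeaks background peaks present in blanks and every fraction.
#' @param blankIntensityRange intensity range of blank peaks.
#' @param nBlankSpectra replicate blank spectra generated.
#' @param nNoisePeaksPerFraction random low-S/N noise peaks per fraction.
#' @param noiseFloor intensity of one S/N unit: snr = intensity/noiseFloor.
#' @param isotopes add +1/+2 13C satellites at binomial-expected ratios.
#' @param mzJitterPpm per-peak Gaussian mass-measurement error (ppm).
#' @return A validated `SimulationConfig` (classed list).
#' @export
simulationConfig <- function(seed,
                             nFractions = 33,
                             nCompounds = 200,
                             nActive = 8,
                             mzRange = c(120, 1200),
                             widthRange = c(1.0, 2.0),
                             abundanceMeanLog = log(2e4),
                             abundanceSdLog = 1.5,
                             activeAbundanceQuantile = 0.9,
                             potencySdLog = 0.25,
                             activityNoiseSd = 0.05,
                             nBlankPeaks = 40,
                             blankIntensityRange = c(500, 5000),
                             nBlankSpectra = 3,
                             nNoisePeaksPerFraction = 25,
                             noiseFloor = 250,
                             isotopes = TRUE,
                             mzJitterPpm = 0.1) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), nFractions = as.integer(nFractions),
              nCompounds = as.integer(nCompounds),
              nActive = as.integer(nActive), mzRange = as.numeric(mzRange),
              widthRange = as.numeric(widthRange),
              abundanceMeanLog = abundanceMeanLog,
              abundanceSdLog = abundanceSdLog,
              activeAbundanceQuantile = activeAbundanceQuantile,
              potencySdLog = potencySdLog,
              activityNoiseSd = activityNoiseSd,
              nBlankPeaks = as.integer(nBlankPeaks),
              blankIntensityRange = as.numeric(blankIntensityRange),
              nBlankSpectra = as.integer(nBlankSpectra),
              nNoisePeaksPerFraction = as.integer(nNoisePeaksPerFraction),
              noiseFloor = noiseFloor, isotopes = isotopes,
              mzJitterPpm = mzJitterPpm)
  if (is.na(cfg$seed)) stop("seed must be an integer")
  if (cfg$nCompounds < 1L) stop("need at least one compound")
  if (cfg$nActive < 0L || cfg$nActive > cfg$nCompounds)
    stop("nActive must lie in 0..nCompounds")
  if (cfg$nFractions < 2L) stop("need at least two fractions")
  if (diff(cfg$mzRange) <= 0 || any(cfg$mzRange <= 0))
    stop("invalid mzRange")
  if (any(cfg$widthRange <= 0) || diff(cfg$widthRange) < 0)
    stop("invalid widthRange")
  if (cfg$activityNoiseSd < 0) stop("activityNoiseSd must be >= 0")
  if (cfg$activeAbundanceQuantile < 0 || cfg$activeAbundanceQuantile >= 1)
    stop("activeAbundanceQuantile must lie in [0, 1)")
  if (cfg$noiseFloor <= 0) stop("noiseFloor must be > 0")
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Discretized Gaussian elution profile
#'
#' Evaluates a Gaussian centered at `center` (in fraction units, need not
#' be integral) with SD `width` at the fraction indices 1..n and normalizes
#' to unit sum. As `width` shrinks toward 0 the profile tends to an
#' indicator at the nearest fraction.
#'
#' @param center peak position in fraction units.
#' @param width Gaussian SD in fractions (> 0).
#' @param n number of fractions.
#' @return Non-negative vector of length n summing to 1.
#' @export
elutionProfile <- function(center, width, n) {
  stopifnot(width > 0, n >= 1)
  z <- -((seq_len(n) - center)^2) / (2 * width^2)
  v <- exp(z - max(z))             # stable for tiny widths
  v / sum(v)
}

#' Simulate a fractionation dataset with known ground truth
#'
#' Each compound contributes `abundance * elutionProfile(...)` intensity at
#' its m/z in every fraction (peaks below half the noise floor are below
#' the instrument's reporting limit and are dropped), plus +1/+2 13C
#' satellites at the binomial-expected ratios for its carbon count when
#' `isotopes` is on. Blank peaks appear, jittered, in every fraction and in
#' the replicate blank spectra; random low-S/N noise peaks are added per
#' fraction. Activity is `a_k = sum_i w_i * amount_ik` over actives,
#' rescaled to a 0-100 assay-like scale, plus Gaussian noise, clipped at 0.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements `fractions` ([FractionSet-class]), `blanks`
#'   ([FractionSet-class] of replicate blank spectra), `activity`
#'   ([ActivityProfile-class]) and `truth` (list: `compounds` data.frame
#'   with id, mz, carbon, center, width, abundance, active, weight;
#'   `amounts` compound-by-fraction matrix).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .withSeed(cfg$seed, {
    N <- cfg$nFractions
    nc <- cfg$nCompounds
    mz <- sort(runif(nc, cfg$mzRange[1], cfg$mzRange[2]))
    carbon <- pmax(1L, as.integer(round(mz / 22)))  # CxHyOz-like C count
    center <- runif(nc, 1, N)
    width <- runif(nc, cfg$widthRange[1], cfg$widthRange[2])
    abundance <- rlnorm(nc, cfg$abundanceMeanLog, cfg$abundanceSdLog)

    active <- rep(FALSE, nc)
    weight <- rep(NA_real_, nc)
    if (cfg$nActive > 0L) {
      eligible <- which(abundance >=
                          quantile(abundance, cfg$activeAbundanceQuantile))
      if (length(eligible) < cfg$nActive)
        eligible <- order(abundance, decreasing = TRUE)[seq_len(cfg$nActive)]
      act <- sample(eligible, cfg$nActive)
      active[act] <- TRUE
      weight[act] <- rlnorm(cfg$nActive, 0, cfg$potencySdLog)
    }

    amounts <- t(vapply(seq_len(nc), function(i)
      abundance[i] * elutionProfile(center[i], width[i], N), numeric(N)))

    minIntensity <- cfg$noiseFloor / 2   # instrument reporting limit
    r1 <- carbon * 0.0107                # expected +1 satellite ratio
    r2 <- choose(carbon, 2) * 0.0107^2   # and its square-term +2 analog

    peakRows <- vector("list", nc)
    for (i in seq_len(nc)) {
      k <- which(amounts[i, ] >= minIntensity)
      if (!length(k)) next
      intens <- amounts[i, k]
      mzs <- list(mz[i])
      ints <- list(intens)
      if (cfg$isotopes) {
        for (s in 1:2) {
          sat <- intens * if (s == 1) r1[i] else r2[i]
          ok <- sat >= minIntensity
          if (any(ok)) {
            mzs <- c(mzs, mz[i] + carbon13Shift(s))
            ints <- c(ints, list(sat[ok]))
            k <- c(k, k[seq_along(intens)][ok])
          }
        }
      }
      ## assemble: first block monoisotopic, then satellites
      nIso <- lengths(ints)
      frac <- c(k[seq_len(nIso[1])],
                if (length(nIso) > 1) k[-seq_len(nIso[1])])
      mzAll <- rep(unlist(mzs), nIso)
      intAll <- unlist(ints)
      peakRows[[i]] <- data.frame(fraction = frac, mz = mzAll,
                                  intensity = intAll)
    }
    cmpPeaks <- do.call(rbind, peakRows)

    ## blank background present everywhere
    bMz <- runif(cfg$nBlankPeaks, cfg$mzRange[1], cfg$mzRange[2])
    bInt <- runif(cfg$nBlankPeaks, cfg$blankIntensityRange[1],
                  cfg$blankIntensityRange[2])
    blankInSample <- if (cfg$nBlankPeaks > 0)
      data.frame(fraction = rep(seq_len(N), each = cfg$nBlankPeaks),
                 mz = rep(bMz, N),
                 intensity = rep(bInt, N) * runif(N * cfg$nBlankPeaks, 0.8, 1.2))
    else NULL

    ## sub-threshold noise peaks
    nn <- cfg$nNoisePeaksPerFraction
    noisePeaks <- if (nn > 0)
      data.frame(fraction = rep(seq_len(N), each = nn),
                 mz = runif(N * nn, cfg$mzRange[1], cfg$mzRange[2]),
                 intensity = cfg$noiseFloor * runif(N * nn, 0.5, 6))
    else NULL

    allPeaks <- rbind(cmpPeaks, blankInSample, noisePeaks)
    if (is.null(allPeaks) || nrow(allPeaks) == 0L)
      stop("configuration produced no peaks")
    allPeaks$mz <- allPeaks$mz *
      (1 + rnorm(nrow(allPeaks), 0, cfg$mzJitterPpm * 1e-6))
    allPeaks$snr <- allPeaks$intensity / cfg$noiseFloor
    fractions <- FractionSet(allPeaks, nFractions = N)

    blankRows <- if (cfg$nBlankPeaks > 0)
      do.call(rbind, lapply(seq_len(cfg$nBlankSpectra), function(b) {
        intens <- bInt * runif(cfg$nBlankPeaks, 0.9, 1.1)
        data.frame(fraction = b,
                   mz = bMz * (1 + rnorm(cfg$nBlankPeaks, 0,
                                         cfg$mzJitterPpm * 1e-6)),
                   intensity = intens, snr = intens / cfg$noiseFloor)
      }))
    else data.frame()
    blanks <- FractionSet(blankRows, nFractions = cfg$nBlankSpectra)

    a0 <- if (cfg$nActive > 0L)
      colSums(amounts[active, , drop = FALSE] * weight[active])
    else rep(0, N)
    scale <- if (max(a0) > 0) 100 / max(a0) else 1
    a <- a0 * scale
    a <- pmax(0, a + rnorm(N, 0, cfg$activityNoiseSd * max(a)))

    truth <- list(compounds = data.frame(id = seq_len(nc), mz = mz,
                                         carbon = carbon, center = center,
                                         width = width,
                                         abundance = abundance,
                                         active = active, weight = weight),
                  amounts = amounts)
    list(fractions = fractions, blanks = blanks,
         activity = ActivityProfile(a), truth = truth)
  })
}
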