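## Peak-list preprocessing: blank averaging/subtraction, S/N filtering,
## intensity-descending 13C de-isotoping, and cross-fraction ppm binning.
## Fixed order in preprocessFractions(): S/N -> blank -> de-isotope -> bin.

## Greedy centroid clustering shared by binning and blank averaging: visit
## peaks in descending intensity; join the nearest existing cluster when
## within `ppm` of its running intensity-weighted centroid, else seed a new
## one. A fixed m/z grid would split peaks straddling grid edges.
.clusterPeaks <- function(mz, intensity, ppm) {
  n <- length(mz)
  assign <- integer(n)
  if (n == 0L) return(list(assign = assign, centers = numeric(0)))
  ord <- order(-intensity, mz)
  centers <- numeric(n)
  wsum <- numeric(n)
  isum <- numeric(n)
  nb <- 0L
  w <- intensity + 1e-12          # keep zero-intensity peaks well-defined
  for (i in ord) {
    if (nb > 0L) {
      d <- abs(mz[i] - centers[seq_len(nb)])
      k <- which.min(d)
      if (d[k] <= ppm * 1e-6 * centers[k]) {
        assign[i] <- k
        wsum[k] <- wsum[k] + mz[i] * w[i]
        isum[k] <- isum[k] + w[i]
        centers[k] <- wsum[k] / isum[k]
        next
      }
    }
    nb <- nb + 1L
    centers[nb] <- mz[i]
    wsum[nb] <- mz[i] * w[i]
    isum[nb] <- w[i]
    assign[i] <- nb
  }
  list(assign = assign, centers = centers[seq_len(nb)])
}

.asBlankPeaks <- function(blank) {
  if (is(blank, "FractionSet")) peaks(blank) else as.data.frame(blank)
}

#' Average replicate blank spectra
#'
#' Peaks from the replicate blank spectra are merged within `tolPpm`
#' (greedy centroid clustering); each merged peak's intensity is the mean
#' over all replicates, counting a replicate where the peak is absent as 0,
#' and its m/z is the intensity-weighted mean of the contributors.
#'
#' @param blanks a [FractionSet-class] whose "fractions" are the replicate
#'   blank spectra (>= 1).
#' @param tolPpm merge tolerance in ppm.
#' @return A single-fraction [FractionSet-class] holding the averaged blank.
#' @export
averageBlanks <- function(blanks, tolPpm = 1) {
  stopifnot(is(blanks, "FractionSet"))
  nrep <- nFractions(blanks)
  if (nrep < 1L) stop("at least one blank spectrum is required")
  p <- peaks(blanks)
  if (nrow(p) == 0L) return(FractionSet(nFractions = 1L))
  cl <- .clusterPeaks(p$mz, p$intensity, tolPpm)
  isum <- as.numeric(rowsum(p$intensity, cl$assign)[, 1])
  ord <- sort(unique(cl$assign))
  FractionSet(data.frame(fraction = 1L, mz = cl$centers[ord],
                         intensity = isum[ord] / nrep, snr = NA_real_),
              nFractions = 1L)
}

#' Remove blank (background) peaks from a spectrum
#'
#' A sample peak is removed iff some blank peak lies within `tolPpm` of it
#' AND the sample intensity is at most `ratio` times the blank intensity.
#' The ratio condition protects a strong genuine signal that happens to
#' coincide with a trace blank peak; `ratio = Inf` removes on mass match
#' alone.
#'
#' @param fset sample [FractionSet-class] (any number of fractions).
#' @param blank averaged blank: a single-fraction [FractionSet-class] or a
#'   data.frame with columns mz, intensity.
#' @param tolPpm mass-match tolerance in ppm (> 0).
#' @param ratio intensity ratio threshold (>= 1).
#' @return The [FractionSet-class] with matching peaks removed; survivors
#'   are unchanged.
#' @export
subtractBlank <- function(fset, blank, tolPpm = 1, ratio = 3) {
  stopifnot(is(fset, "FractionSet"), tolPpm > 0, ratio >= 1)
  b <- .asBlankPeaks(blank)
  p <- peaks(fset)
  if (nrow(b) == 0L || nrow(p) == 0L) return(fset)
  bo <- order(b$mz)
  bmz <- b$mz[bo]
  bint <- b$intensity[bo]
  tol <- tolPpm * 1e-6 * p$mz
  lo <- findInterval(p$mz - tol, bmz) + 1L
  hi <- findInterval(p$mz + tol, bmz)
  drop <- vapply(seq_len(nrow(p)), function(i) {
    if (lo[i] > hi[i]) return(FALSE)
    any(p$intensity[i] <= ratio * bint[lo[i]:hi[i]])
  }, logical(1))
  FractionSet(p[!drop, , drop = FALSE], nFractions = nFractions(fset))
}

#' Filter peaks by signal-to-noise ratio
#'
#' Keeps peaks with `snr` strictly greater than `minSnr`. Peaks without an
#' S/N value are kept; their count is attached as attribute
#' `"nMissingSnr"`.
#'
#' @param fset a [FractionSet-class].
#' @param minSnr threshold (>= 0); the instrument-vendor default for
#'   FT-ICR peak export is 4.
#' @return Filtered [FractionSet-class].
#' @export
filterSnr <- function(fset, minSnr = 4) {
  stopifnot(is(fset, "FractionSet"), minSnr >= 0)
  p <- peaks(fset)
  missing <- is.na(p$snr)
  keep <- missing | p$snr > minSnr
  out <- FractionSet(p[keep, , drop = FALSE], nFractions = nFractions(fset))
  attr(out, "nMissingSnr") <- sum(missing)
  out
}

.deisotopeOne <- function(p, tolPpm, maxShift, intensityCheck) {
  n <- nrow(p)
  if (n < 2L) return(p)
  mz <- p$mz
  int <- p$intensity
  keep <- rep(TRUE, n)
  ## p arrives sorted by mz (FractionSet canonical order)
  for (i in order(-int, mz)) {
    if (!keep[i]) next                      # removed peaks are never queried
    for (s in seq_len(maxShift)) {
      target <- mz[i] + s * .C13_DELTA
      tol <- tolPpm * 1e-6 * target
      lo <- findInterval(target - tol, mz) + 1L
      hi <- findInterval(target + tol, mz)
      if (lo > hi) next
      j <- lo:hi
      drop <- keep[j] & int[j] < int[i]
      if (intensityCheck) {
        ## plausible satellite/parent ratio from the carbon-count ceiling
        ## nC ~ mz/12: expected +s ratio (nC * 0.0107)^s / s!, with 10% slack
        maxRatio <- 1.1 * (mz[i] / 12 * 0.0107)^s / factorial(s)
        drop <- drop & int[j] / int[i] <= maxRatio
      }
      keep[j][drop] <- FALSE
    }
  }
  p[keep, , drop = FALSE]
}

#' Remove 13C isotope satellite peaks
#'
#' Peaks are processed in descending intensity (ties broken by ascending
#' m/z). For each still-retained peak P, any retained peak within `tolPpm`
#' of `P.mz + n * 1.0033548378` (n = 1..`maxShift`) whose intensity is
#' lower than P's is removed as an isotope satellite; removed peaks are
#' never themselves used as queries. Each fraction is de-isotoped
#' independently. The operation is idempotent and never removes a
#' fraction's most intense peak.
#'
#' @param fset a [FractionSet-class].
#' @param tolPpm mass tolerance in ppm (> 0).
#' @param maxShift largest number of heavy carbons tested, 1..3.
#' @param intensityCheck additionally require a plausible satellite/parent
#'   intensity ratio (at most 1.1 x the carbon-count expectation,
#'   nC ~ m/z / 12) before removing a peak. Off by default: the classical
#'   procedure tests mass differences only.
#' @return De-isotoped [FractionSet-class], sorted by m/z within fraction.
#' @export
deisotope <- function(fset, tolPpm = 1, maxShift = 3,
                      intensityCheck = FALSE) {
  stopifnot(is(fset, "FractionSet"), tolPpm > 0)
  if (!maxShift %in% 1:3) stop("maxShift must be 1, 2 or 3")
  p <- peaks(fset)
  if (nrow(p) == 0L) return(fset)
  out <- do.call(rbind, lapply(split(p, p$fraction), .deisotopeOne,
                               tolPpm = tolPpm, maxShift = maxShift,
                               intensityCheck = intensityCheck))
  FractionSet(out, nFractions = nFractions(fset))
}

#' Bin peaks across fractions into m/z bins
#'
#' Clusters the peaks of all fractions so that every member lies within
#' `binPpm` of its bin's intensity-weighted centroid (greedy centroid
#' clustering in descending intensity order). Within a bin, multiple peaks
#' from the same fraction are summed to give the bin's intensity m_kj in
#' fraction k. Total intensity is conserved.
#'
#' @param fset a [FractionSet-class].
#' @param binPpm bin half-width / matching tolerance in ppm (> 0); 0.5 ppm
#'   matches 15 T FT-ICR mass accuracy.
#' @return A [BinnedMatrix-class] with bins in ascending center order.
#' @export
binAcrossFractions <- function(fset, binPpm = 0.5) {
  stopifnot(is(fset, "FractionSet"), binPpm > 0)
  p <- peaks(fset)
  N <- max(nFractions(fset), 1L)
  if (nrow(p) == 0L)
    return(BinnedMatrix(numeric(0), matrix(0, 0, N), binWidthPpm = binPpm))
  cl <- .clusterPeaks(p$mz, p$intensity, binPpm)
  nb <- length(cl$centers)
  key <- (cl$assign - 1L) * N + p$fraction
  sums <- rowsum(p$intensity, key)
  m <- matrix(0, nb, N)
  k <- as.integer(rownames(sums))
  m[cbind((k - 1L) %/% N + 1L, (k - 1L) %% N + 1L)] <- sums[, 1]
  BinnedMatrix(cl$centers, m, binWidthPpm = binPpm)
}

#' Number of unit-resolution bins covering an integer m/z range
#'
#' @param mzLo,mzHi integer range bounds, `mzHi >= mzLo`.
#' @return `mzHi - mzLo + 1`.
#' @examples
#' countUnitBins(120, 1200)  # 1081
#' @export
countUnitBins <- function(mzLo, mzHi) {
  if (any(c(mzLo, mzHi) != round(c(mzLo, mzHi))))
    stop("bounds must be integers")
  if (mzHi < mzLo) stop("inverted range: mzHi < mzLo")
  as.integer(mzHi - mzLo + 1)
}

#' Full preprocessing chain
#'
#' Applies, in order: S/N filter, blank averaging + subtraction (when
#' blanks are given), de-isotoping, and cross-fraction binning.
#'
#' @param fset sample [FractionSet-class].
#' @param blanks optional replicate blank spectra ([FractionSet-class]).
#' @param minSnr S/N threshold (strictly-greater-than).
#' @param blankTolPpm,blankRatio blank-subtraction parameters.
#' @param deisotopeTolPpm,maxShift de-isotoping parameters.
#' @param binPpm bin half-width in ppm.
#' @return A [BinnedMatrix-class].
#' @export
preprocessFractions <- function(fset, blanks = NULL, minSnr = 4,
                                blankTolPpm = 1, blankRatio = 3,
                                deisotopeTolPpm = 1, maxShift = 3,
                                binPpm = 0.5) {
  fset <- filterSnr(fset, minSnr)
  if (!is.null(blanks)) {
    blank <- averageBlanks(if (is(blanks, "FractionSet")) filterSnr(blanks, minSnr) else blanks,
                           tolPpm = blankTolPpm)
    fset <- subtractBlank(fset, blank, tolPpm = blankTolPpm,
                          ratio = blankRatio)
  }
  fset <- deisotope(fset, tolPpm = deisotopeTolPpm, maxShift = maxShift)
  binAcrossFractions(fset, binPpm = binPpm)
}
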