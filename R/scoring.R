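## The SCAMP scores. Score 1 is the correlation coefficient
## C_j = 100 * sum_k a_k^0 m_kj^0 between the unit-normalized activity and
## mass profiles (reported on a 0-100 percent-of-perfect scale). Score 2
## multiplies by the bin's summed raw intensity I. Score 3 splits each bin
## into contiguous above-mean chromatographic groups and scores each group
## as C_j * sigma^2 * I / N_f^2 on its masked profile, penalizing broad or
## flat distributions and separating coeluting structural isomers.

#' Normalize a vector to unit Euclidean norm
#'
#' Direction is preserved; an all-zero vector is returned unchanged
#' (degenerate case, flagged downstream as C_j = 0).
#'
#' @param v numeric vector with finite entries.
#' @return Vector of Euclidean norm 1 (or the zero vector).
#' @examples
#' normalizeVector(c(3, 4, 0))  # 0.6 0.8 0.0
#' @export
normalizeVector <- function(v) {
  if (any(!is.finite(v))) stop("entries must be finite")
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) v else v / nrm
}

#' Correlation coefficient C_j between a mass profile and the activity
#'
#' `100 * sum_k a_k^0 m_kj^0` on unit-norm vectors. For non-negative
#' profiles C_j lies in \[0, 100\]; 100 means the bin's intensity profile is
#' exactly proportional to the activity profile. Either argument all-zero
#' gives 0. Invariant to positive rescaling of either argument.
#'
#' @param m mass-bin intensity profile (length N, non-negative).
#' @param a activity profile (length N) or an [ActivityProfile-class].
#' @return C_j on the 0-100 scale.
#' @examples
#' correlationCj(c(4, 3, 0), c(3, 4, 0))  # 96
#' @export
correlationCj <- function(m, a) {
  if (is(a, "ActivityProfile")) a <- activityValues(a)
  if (length(m) != length(a))
    stop("profile lengths differ: ", length(m), " vs ", length(a))
  100 * sum(normalizeVector(m) * normalizeVector(a))
}

#' Summed intensity I of a bin profile
#'
#' @param m intensity profile (raw, unnormalized).
#' @return `sum(m)`.
#' @export
totalIntensity <- function(m) sum(m)

#' Score 2 = C_j * I
#'
#' @param cj correlation coefficient (0-100 scale).
#' @param intensity summed raw intensity I.
#' @return The product.
#' @export
score2 <- function(cj, intensity) cj * intensity

#' Find chromatographic groups in a bin profile
#'
#' The mean of all N intensities is computed; maximal contiguous runs of
#' fractions with intensity strictly greater than the mean become groups
#' (left to right). A constant profile has no groups. Groups are disjoint
#' and their union is exactly the set of above-mean fractions.
#'
#' @param m intensity profile (length N >= 1).
#' @return data.frame with columns start, end, nf (1-based, inclusive).
#' @examples
#' findGroups(c(0, 0, 5, 9, 5, 0, 0, 0, 4, 8, 4, 0))  # fractions 3-5, 9-11
#' @export
findGroups <- function(m) {
  stopifnot(length(m) >= 1)
  r <- rle(m > mean(m))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = starts[r$values], end = ends[r$values])
  out$nf <- out$end - out$start + 1L
  out
}

#' Statistics of one group
#'
#' Over the raw in-group intensities: `sigma` is the population (divide by
#' N_f) standard deviation, `intensity` the sum, `nf` the fraction count.
#' A single-fraction group has sigma 0 by construction.
#'
#' @param m full bin profile.
#' @param start,end group bounds (1-based, inclusive).
#' @return list(sigma, intensity, nf).
#' @export
groupStatistics <- function(m, start, end) {
  if (start < 1 || end > length(m) || start > end)
    stop("group out of profile bounds")
  v <- m[start:end]
  list(sigma = sqrt(mean((v - mean(v))^2)),
       intensity = sum(v),
       nf = length(v))
}

#' Score 3 = C_j * sigma^2 * I / N_f^2
#'
#' @param cj correlation coefficient of the group's masked profile.
#' @param sigma population SD of raw in-group intensities.
#' @param intensity summed raw in-group intensity.
#' @param nf number of fractions in the group (>= 1).
#' @return The score; 0 whenever sigma is 0 (flat or single-fraction group).
#' @export
score3 <- function(cj, sigma, intensity, nf) {
  if (nf < 1) stop("nf must be >= 1")
  cj * sigma^2 * intensity / nf^2
}

#' Score and rank all mass bins against an activity profile
#'
#' Methods 1 and 2 score each bin's whole profile: Score 1 = C_j,
#' Score 2 = C_j * I. Method 3 first finds the chromatographic groups of
#' every bin; each group becomes its own candidate, its C_j computed on the
#' masked full-length profile (in-group intensities kept, all other
#' fractions zeroed) against the full normalized activity vector -- keeping
#' all C_j values on one comparable scale -- and its Score 3 from the raw
#' in-group statistics. Candidates are sorted by score descending, ties
#' broken by ascending m/z then ascending start fraction; ranks are 1..n.
#'
#' @param bm a [BinnedMatrix-class].
#' @param activity an [ActivityProfile-class] or numeric vector, length
#'   `nFractions(bm)`.
#' @param method 1, 2 or 3.
#' @param minCj optional speed filter: candidates with `C_j <= minCj` are
#'   dropped before ranking (the field uses values around 30 to discard
#'   background bins; default is no filter).
#' @return data.frame with columns rank, mz, start, end, nf, sigma,
#'   intensity, cj, score2, score3, score. For methods 1-2 the window is
#'   the whole profile and nf/sigma/score3 are NA.
#' @export
rankCandidates <- function(bm, activity, method = 3, minCj = NULL) {
  stopifnot(is(bm, "BinnedMatrix"))
  if (is(activity, "ActivityProfile")) activity <- activityValues(activity)
  if (length(activity) != ncol(bm))
    stop("activity length ", length(activity), " does not match ",
         ncol(bm), " fractions")
  if (!method %in% 1:3) stop("unknown scoring method: ", method)
  m <- intensityMatrix(bm)
  centers <- binCenters(bm)
  a0 <- normalizeVector(activity)
  N <- ncol(bm)

  if (method %in% c(1, 2)) {
    cj <- apply(m, 1, correlationCj, a = a0)
    I <- rowSums(m)
    out <- data.frame(mz = centers, start = 1L, end = N, nf = NA_integer_,
                      sigma = NA_real_, intensity = I, cj = cj,
                      score2 = cj * I, score3 = NA_real_)
    out$score <- if (method == 1) out$cj else out$score2
  } else {
    rows <- vector("list", nrow(m))
    for (j in seq_len(nrow(m))) {
      prof <- m[j, ]
      gs <- findGroups(prof)
      if (nrow(gs) == 0L) next
      rec <- lapply(seq_len(nrow(gs)), function(g) {
        masked <- numeric(N)
        idx <- gs$start[g]:gs$end[g]
        masked[idx] <- prof[idx]
        st <- groupStatistics(prof, gs$start[g], gs$end[g])
        cj <- correlationCj(masked, a0)
        data.frame(mz = centers[j], start = gs$start[g], end = gs$end[g],
                   nf = st$nf, sigma = st$sigma, intensity = st$intensity,
                   cj = cj, score2 = cj * st$intensity,
                   score3 = score3(cj, st$sigma, st$intensity, st$nf))
      })
      rows[[j]] <- do.call(rbind, rec)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(mz = numeric(), start = integer(), end = integer(),
                        nf = integer(), sigma = numeric(),
                        intensity = numeric(), cj = numeric(),
                        score2 = numeric(), score3 = numeric())
    out$score <- out$score3
  }
  if (!is.null(minCj)) out <- out[out$cj > minCj, , drop = FALSE]
  out <- out[order(-out$score, out$mz, out$start), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
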