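## Enrichment-curve evaluation of a ranked candidate list against known
## actives. Default convention is "roc": x advances by 1/n_inactive per
## inactive, y by 1/n_active per active, so an ideal ranking has AUC
## exactly 1 and random scoring 0.5 in expectation for any finite list.
## "screened" plots percent of actives found against percent of the whole
## list screened (ideal AUC is then 1 - n_active/(2n)).

#' Enrichment curve of a labeled ranking
#'
#' Walks the ranking from rank 1. Candidates sharing a score contribute a
#' single diagonal segment (the average over their permutations), so tied
#' scores cannot make the AUC order-dependent.
#'
#' @param active logical vector: is each candidate a known active? Given in
#'   rank order (rank 1 first) unless `scores` is supplied.
#' @param scores optional numeric scores (higher = better); when given, the
#'   ranking is by score descending and equal scores form tie groups.
#' @param convention `"roc"` (x = fraction of inactives screened, default)
#'   or `"screened"` (x = fraction of the database screened).
#' @return An [EnrichmentCurve-class], anchored at (0,0) and ending at (1,1).
#' @examples
#' curvePoints(enrichmentCurve(c(TRUE, FALSE, TRUE, FALSE)))
#' @export
enrichmentCurve <- function(active, scores = NULL,
                            convention = c("roc", "screened")) {
  convention <- match.arg(convention)
  active <- as.logical(active)
  if (any(is.na(active))) stop("active flags must be TRUE/FALSE")
  nA <- sum(active)
  nI <- sum(!active)
  if (nA == 0L) stop("ranking contains no actives")
  if (nI == 0L) stop("ranking contains no inactives")
  n <- length(active)
  if (is.null(scores)) {
    scores <- rev(seq_len(n))        # given order is the ranking; no ties
  } else {
    if (length(scores) != n) stop("scores length must match active flags")
    if (any(!is.finite(scores))) stop("scores must be finite")
  }
  o <- order(-scores)
  s <- scores[o]
  act <- active[o]
  grp <- cumsum(!duplicated(s))      # tie groups in descending-score order
  gA <- as.numeric(rowsum(as.numeric(act), grp)[, 1])
  gN <- as.numeric(rowsum(rep(1, n), grp)[, 1])
  gI <- gN - gA
  dy <- gA / nA
  dx <- if (convention == "roc") gI / nI else gN / n
  x <- c(0, cumsum(dx))
  y <- c(0, cumsum(dy))
  x[length(x)] <- 1                  # guard rounding at the anchor
  y[length(y)] <- 1
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  new("EnrichmentCurve", x = x, y = y, auc = min(max(auc, 0), 1),
      convention = convention)
}

#' @describeIn enrichmentCurve AUC straight from the labels: builds the
#'   curve and returns its area.
#' @param x logical active flags (rank order or with `scores`).
#' @param ... passed to [enrichmentCurve()].
#' @export
setMethod("enrichmentAUC", "logical", function(x, ...)
  enrichmentCurve(x, ...)@auc)

#' Label candidates against known active m/z values
#'
#' A candidate is labeled active iff its bin center lies within `tolPpm` of
#' the m/z of some compound flagged active in the ground truth (or in a
#' supplied known-actives list).
#'
#' @param truth data.frame with columns `mz` and `active` (and optionally
#'   `id`), e.g. `simulateDataset()$truth$compounds`, or a numeric vector
#'   of known-active m/z values.
#' @param candidateMz numeric vector of candidate bin centers, or a
#'   candidate data.frame with an `mz` column (e.g. from
#'   [rankCandidates()]).
#' @param tolPpm matching tolerance in ppm (> 0).
#' @return data.frame with columns `active` (logical) and `match` (index
#'   of the matched active compound within the active set, NA otherwise),
#'   one row per candidate in input order.
#' @export
truthLabels <- function(truth, candidateMz, tolPpm = 1) {
  stopifnot(tolPpm > 0)
  if (is.data.frame(candidateMz)) candidateMz <- candidateMz$mz
  if (is.data.frame(truth)) {
    if (!all(c("mz", "active") %in% names(truth)))
      stop("truth needs columns mz and active")
    activeMz <- truth$mz[as.logical(truth$active)]
  } else {
    activeMz <- as.numeric(truth)
  }
  if (length(activeMz) == 0L)
    return(data.frame(active = rep(FALSE, length(candidateMz)),
                      match = NA_integer_))
  res <- vapply(candidateMz, function(mz) {
    d <- abs(mz - activeMz) / activeMz * 1e6
    k <- which.min(d)
    if (d[k] <= tolPpm) k else NA_integer_
  }, integer(1))
  data.frame(active = !is.na(res), match = res)
}
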