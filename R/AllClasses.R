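#' @include AllGenerics.R
NULL

## Central data containers. FractionSet and ActivityProfile are light S4
## wrappers around validated base structures; BinnedMatrix extends
## SummarizedExperiment so the bin x fraction matrix travels with its
## per-bin metadata (centers, optional grouping annotations).

.PEAK_COLS <- c("fraction", "mz", "intensity", "snr")

#' FractionSet: centroid peak lists for N sequential fractions
#'
#' Holds every retained centroid peak of an experiment as one long table
#' with columns `fraction` (1-based index), `mz`, `intensity` and `snr`
#' (`NA` when the instrument reports none). Peaks are kept in canonical
#' order (fraction, then m/z ascending) and exact m/z duplicates within a
#' fraction are merged by summing their intensities, so all downstream
#' operations are independent of input peak ordering.
#'
#' @slot peaks data.frame with columns fraction, mz, intensity, snr.
#' @slot nFractions integer, the total number of fractions N (empty
#'   fractions are legal and simply have no rows).
#' @export
setClass("FractionSet",
  representation(peaks = "data.frame", nFractions = "integer"))

setValidity("FractionSet", function(object) {
  p <- object@peaks
  n <- object@nFractions
  if (length(n) != 1L || is.na(n) || n < 0L)
    return("nFractions must be a single non-negative integer")
  if (!identical(names(p), .PEAK_COLS))
    return(sprintf("peaks must have columns %s", paste(.PEAK_COLS, collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  if (any(p$fraction < 1L) || any(p$fraction > n))
    return("fraction indices must lie in 1..nFractions")
  if (any(!is.finite(p$mz)) || any(p$mz <= 0))
    return("mz must be finite and > 0")
  if (any(!is.finite(p$intensity)) || any(p$intensity < 0))
    return("intensity must be finite and >= 0")
  if (any(!is.na(p$snr) & p$snr < 0))
    return("snr must be >= 0 where present")
  o <- order(p$fraction, p$mz)
  if (!identical(o, seq_len(nrow(p))))
    return("peaks must be sorted by fraction then mz")
  TRUE
})

#' Construct a FractionSet
#'
#' @param peaks data.frame with columns `fraction`, `mz`, `intensity` and
#'   optionally `snr`; extra columns are dropped.
#' @param nFractions total fraction count N; defaults to `max(fraction)`
#'   (0 for an empty table).
#' @return A [FractionSet-class] object.
#' @examples
#' fs <- FractionSet(data.frame(fraction = c(1, 2), mz = c(169.0143, 169.0143),
#'                              intensity = c(1000, 500), snr = c(10, 6)))
#' nFractions(fs)
#' @export
FractionSet <- function(peaks = data.frame(), nFractions = NULL) {
  if (nrow(peaks) == 0L) {
    p <- data.frame(fraction = integer(), mz = numeric(),
                    intensity = numeric(), snr = numeric())
  } else {
    missing <- setdiff(c("fraction", "mz", "intensity"), names(peaks))
    if (length(missing))
      stop("peaks table lacks mandatory column(s): ",
           paste(missing, collapse = ", "))
    if (is.null(peaks$snr)) peaks$snr <- NA_real_
    p <- data.frame(fraction = as.integer(peaks$fraction),
                    mz = as.numeric(peaks$mz),
                    intensity = as.numeric(peaks$intensity),
                    snr = as.numeric(peaks$snr))
    p <- p[order(p$fraction, p$mz, -p$intensity), , drop = FALSE]
    ## merge exact duplicates (same fraction, same mz): sum intensity,
    ## keep the largest snr among contributors
    key <- paste(p$fraction, format(p$mz, digits = 17))
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      idx <- match(key, key[first])
      intensity <- as.numeric(rowsum(p$intensity, idx)[, 1])
      snr <- vapply(split(p$snr, idx), function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), numeric(1))
      p <- data.frame(fraction = p$fraction[first], mz = p$mz[first],
                      intensity = intensity, snr = as.numeric(snr))
      p <- p[order(p$fraction, p$mz), , drop = FALSE]
    }
    rownames(p) <- NULL
  }
  if (is.null(nFractions))
    nFractions <- if (nrow(p)) max(p$fraction) else 0L
  new("FractionSet", peaks = p, nFractions = as.integer(nFractions))
}

#' @describeIn FractionSet Number of fractions N.
#' @param x a FractionSet
#' @export
setMethod("nFractions", "FractionSet", function(x) x@nFractions)

#' @describeIn FractionSet The full peak table (all fractions).
#' @param ... unused
#' @export
setMethod("peaks", "FractionSet", function(x, ...) x@peaks)

#' @describeIn FractionSet Peak table of a single fraction `k`.
#' @param k fraction index (1-based)
#' @export
setMethod("fractionSpectrum", "FractionSet", function(x, k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > x@nFractions)
    stop("fraction index out of range 1..", x@nFractions)
  p <- x@peaks[x@peaks$fraction == k, , drop = FALSE]
  rownames(p) <- NULL
  p
})

setMethod("show", "FractionSet", function(object) {
  cat(sprintf("FractionSet: %d fraction(s), %d peak(s)\n",
              object@nFractions, nrow(object@peaks)))
  if (nrow(object@peaks))
    cat(sprintf("  m/z range %.5f - %.5f\n",
                min(object@peaks$mz), max(object@peaks$mz)))
})

#' ActivityProfile: one bioactivity value per fraction
#'
#' The activity vector A = (a_1, ..., a_N), e.g. DPPH radical-scavenging
#' strength per fraction. Values are stored on whatever scale the assay
#' produced (higher = more active); `normalizeActivity()` returns the
#' unit-Euclidean-norm form used by the correlation scores.
#'
#' @slot values numeric vector of length N, all finite.
#' @slot normalized logical; TRUE if `values` has Euclidean norm 1.
#' @export
setClass("ActivityProfile",
  representation(values = "numeric", normalized = "logical"))

setValidity("ActivityProfile", function(object) {
  v <- object@values
  if (length(v) == 0L) return("activity profile must be non-empty")
  if (any(!is.finite(v))) return("activity values must be finite")
  if (length(object@normalized) != 1L) return("normalized must be a flag")
  if (object@normalized) {
    nrm <- sqrt(sum(v^2))
    if (nrm > 0 && abs(nrm - 1) > 1e-12)
      return("normalized profile must have Euclidean norm 1")
  }
  TRUE
})

#' Construct an ActivityProfile
#'
#' @param values numeric activity per fraction, ordered by fraction index.
#' @param normalized logical, whether `values` is already unit-norm.
#' @return An [ActivityProfile-class] object.
#' @examples
#' ActivityProfile(c(0.1, 0.9))
#' @export
ActivityProfile <- function(values, normalized = FALSE) {
  new("ActivityProfile", values = as.numeric(values),
      normalized = isTRUE(normalized))
}

#' @describeIn ActivityProfile The activity vector.
#' @param x an ActivityProfile
#' @export
setMethod("activityValues", "ActivityProfile", function(x) x@values)

#' @describeIn ActivityProfile Whether the stored vector is unit-norm.
#' @export
setMethod("isNormalized", "ActivityProfile", function(x) x@normalized)

#' @describeIn ActivityProfile Number of fractions N.
#' @export
setMethod("nFractions", "ActivityProfile", function(x) length(x@values))

#' @describeIn ActivityProfile Unit-Euclidean-norm copy (all-zero input is
#'   returned unchanged and flagged unnormalized).
#' @export
setMethod("normalizeActivity", "ActivityProfile", function(x) {
  v <- normalizeVector(x@values)
  ActivityProfile(v, normalized = any(v != 0))
})

setMethod("show", "ActivityProfile", function(object) {
  cat(sprintf("ActivityProfile: %d fraction(s)%s\n", length(object@values),
              if (object@normalized) " (unit-norm)" else ""))
  cat("  ", paste(signif(head(object@values, 8), 4), collapse = " "),
      if (length(object@values) > 8) "...\n" else "\n")
})

#' BinnedMatrix: per-bin intensity profiles over fractions
#'
#' A \linkS4class{SummarizedExperiment} whose single assay `"intensity"`
#' holds the bin-by-fraction matrix: row j is the mass profile
#' M_j = (m_1j, ..., m_Nj) of one m/z bin, column k is fraction k.
#' `rowData` carries the bin centers (column `mz`, strictly increasing) and
#' any grouping annotations; metadata records the ppm bin half-width and
#' the intensity normalization that was detected or applied
#' (`"raw"`, `"unit"` or `"percent"`).
#'
#' @export
setClass("BinnedMatrix", contains = "SummarizedExperiment")

setValidity("BinnedMatrix", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("BinnedMatrix needs an 'intensity' assay")
  m <- SummarizedExperiment::assay(object, "intensity")
  if (any(!is.finite(m)) || any(m < 0))
    return("intensities must be finite and >= 0")
  mz <- rowData(object)$mz
  if (is.null(mz)) return("rowData must contain bin centers in column 'mz'")
  if (nrow(object) > 1L && any(diff(mz) <= 0))
    return("bin centers must be strictly increasing")
  w <- metadata(object)$binWidthPpm
  if (!is.null(w) &&
      (length(w) != 1L || (is.finite(w) && w <= 0) || is.infinite(w)))
    return("binWidthPpm must be a positive scalar (or NA when unknown)")
  TRUE
})

#' Construct a BinnedMatrix
#'
#' @param centers numeric vector of bin-center m/z values (ascending).
#' @param intensities numeric matrix, bins in rows, fractions in columns.
#' @param binWidthPpm ppm half-width used to build the bins (or `NA` when
#'   unknown, e.g. unit-resolution external tables).
#' @param normalization `"raw"`, `"unit"` (each row unit-Euclidean-norm) or
#'   `"percent"` (each row scaled to max 100).
#' @param rowData optional extra per-bin annotation (data.frame).
#' @return A [BinnedMatrix-class] object.
#' @export
BinnedMatrix <- function(centers, intensities, binWidthPpm = NA_real_,
                         normalization = "raw", rowData = NULL) {
  intensities <- as.matrix(intensities)
  if (length(centers) != nrow(intensities))
    stop("one bin center per intensity row required")
  o <- order(centers)
  centers <- centers[o]
  intensities <- intensities[o, , drop = FALSE]
  rd <- DataFrame(mz = as.numeric(centers))
  if (!is.null(rowData)) {
    rowData <- as.data.frame(rowData)[o, , drop = FALSE]
    for (nm in names(rowData)) rd[[nm]] <- rowData[[nm]]
  }
  dimnames(intensities) <- list(NULL, paste0("F", seq_len(ncol(intensities))))
  se <- SummarizedExperiment(assays = list(intensity = intensities),
                             rowData = rd)
  metadata(se)$binWidthPpm <- as.numeric(binWidthPpm)
  metadata(se)$normalization <- match.arg(normalization,
                                          c("raw", "unit", "percent"))
  new("BinnedMatrix", se)
}

#' @describeIn BinnedMatrix Bin-center m/z values.
#' @param x a BinnedMatrix
#' @export
setMethod("binCenters", "BinnedMatrix", function(x) rowData(x)$mz)

#' @describeIn BinnedMatrix ppm half-width the bins were built with.
#' @export
setMethod("binWidthPpm", "BinnedMatrix", function(x) metadata(x)$binWidthPpm)

#' @describeIn BinnedMatrix The bin-by-fraction intensity matrix.
#' @export
setMethod("intensityMatrix", "BinnedMatrix",
          function(x) SummarizedExperiment::assay(x, "intensity"))

#' @describeIn BinnedMatrix Intensity normalization recorded for the matrix.
#' @export
setMethod("binNormalization", "BinnedMatrix",
          function(x) metadata(x)$normalization)

#' @describeIn BinnedMatrix Number of fractions N (columns).
#' @export
setMethod("nFractions", "BinnedMatrix", function(x) ncol(x))

setMethod("show", "BinnedMatrix", function(object) {
  cat(sprintf("BinnedMatrix: %d bin(s) x %d fraction(s) [%s intensities%s]\n",
              nrow(object), ncol(object), metadata(object)$normalization,
              if (is.finite(metadata(object)$binWidthPpm))
                sprintf(", %.3g ppm bins", metadata(object)$binWidthPpm)
              else ""))
  if (nrow(object))
    cat(sprintf("  m/z %.5f - %.5f\n", min(binCenters(object)),
                max(binCenters(object))))
})

#' EnrichmentCurve: recovery of actives through a ranked list
#'
#' Piecewise-linear curve anchored at (0,0) and (1,1): y is the fraction of
#' known actives recovered after screening prefix x of the ranked candidate
#' list, where x counts inactives (`"roc"` convention, ideal AUC exactly 1)
#' or all candidates (`"screened"`).
#'
#' @slot x,y curve coordinates, non-decreasing in \[0,1\].
#' @slot auc trapezoidal area under the curve.
#' @slot convention `"roc"` or `"screened"`.
#' @export
setClass("EnrichmentCurve",
  representation(x = "numeric", y = "numeric", auc = "numeric",
                 convention = "character"))

setValidity("EnrichmentCurve", function(object) {
  x <- object@x; y <- object@y
  if (length(x) != length(y)) return("x and y must have equal length")
  if (any(x < -1e-12) || any(x > 1 + 1e-12) ||
      any(y < -1e-12) || any(y > 1 + 1e-12))
    return("curve points must lie in [0,1]")
  if (any(diff(x) < -1e-12) || any(diff(y) < -1e-12))
    return("curve must be non-decreasing")
  if (length(object@auc) != 1L || object@auc < -1e-12 ||
      object@auc > 1 + 1e-12)
    return("auc must be a scalar in [0,1]")
  if (!object@convention %in% c("roc", "screened"))
    return("convention must be 'roc' or 'screened'")
  TRUE
})

#' @describeIn EnrichmentCurve Curve points as a data.frame.
#' @param x an EnrichmentCurve
#' @export
setMethod("curvePoints", "EnrichmentCurve",
          function(x) data.frame(x = x@x, y = x@y))

#' @describeIn EnrichmentCurve Trapezoidal area under the curve.
#' @param ... unused
#' @export
setMethod("enrichmentAUC", "EnrichmentCurve", function(x, ...) x@auc)

setMethod("show", "EnrichmentCurve", function(object) {
  cat(sprintf("EnrichmentCurve (%s convention): %d point(s), AUC = %.4f\n",
              object@convention, length(object@x), object@auc))
})
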