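## TSV readers/writers for the package's data surface, plus the DPPH
## activity computation. All tables are UTF-8, tab-separated, '.' decimal,
## header row mandatory; floats survive a write/read round trip to 1e-9.

.checkNumericColumn <- function(x, col, allowNA = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(allowNA & (is.na(x) | x == "" | x == "NA")))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                 as.character(x[bad[1]]), col, bad[1]))
  nonfinite <- which(!is.finite(v) & !is.na(v))
  if (length(nonfinite))
    stop(sprintf("non-finite value in column '%s', row %d",
                 col, nonfinite[1]))
  v
}

.writeTsv <- function(tab, path) {
  ## format() at 15 significant digits keeps 1e-9 round trips
  out <- as.data.frame(lapply(tab, function(col)
    if (is.numeric(col)) vapply(col, function(x)
      if (is.na(x)) NA_character_ else format(x, digits = 15, scientific = FALSE,
                                              trim = TRUE), character(1))
    else as.character(col)), check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- names(tab)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
}

#' Read a peak table into a FractionSet
#'
#' Two dialects: `"long"` is one TSV with columns `fraction`, `mz`,
#' `intensity` and optional `snr`; `"per-fraction"` takes a character
#' vector of one-file-per-fraction TSVs (columns `mz`, `intensity`,
#' optional `snr`), file i becoming fraction i.
#'
#' @param path file path (long) or vector of paths (per-fraction).
#' @param dialect `"long"` or `"per-fraction"`.
#' @param nFractions total N; defaults to the largest index seen.
#' @return A [FractionSet-class]; fractions without rows are present and empty.
#' @export
readPeakTable <- function(path, dialect = c("long", "per-fraction"),
                          nFractions = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "per-fraction") {
    tabs <- lapply(seq_along(path), function(i) {
      t <- read.delim(path[i], stringsAsFactors = FALSE, check.names = FALSE)
      if (nrow(t)) t$fraction <- i
      t
    })
    tab <- do.call(rbind, tabs[vapply(tabs, nrow, 0L) > 0])
    if (is.null(tab)) tab <- data.frame()
    if (is.null(nFractions)) nFractions <- length(path)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(tab) == 0L)
    return(FractionSet(nFractions = if (is.null(nFractions)) 0L else nFractions))
  need <- c("fraction", "mz", "intensity")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("peak table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in need) tab[[col]] <- .checkNumericColumn(tab[[col]], col)
  if (!is.null(tab$snr))
    tab$snr <- .checkNumericColumn(tab$snr, "snr", allowNA = TRUE)
  FractionSet(tab, nFractions = nFractions)
}

#' Write a FractionSet as a long-format TSV
#'
#' @param fset a [FractionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(fset, path) {
  stopifnot(is(fset, "FractionSet"))
  .writeTsv(peaks(fset), path)
  invisible(path)
}

#' Read an activity profile
#'
#' Two-column TSV (`fraction`, `activity`). Rows may be out of order;
#' indices must be exactly 1..N with no duplicates or gaps. Activity is
#' stored as scavenging strength (higher = more active); set
#' `convert = "inhibitionToActivity"` when the file holds %DPPH remaining,
#' which applies `100 - value` explicitly.
#'
#' @param path file path.
#' @param convert `"none"` or `"inhibitionToActivity"`.
#' @return An [ActivityProfile-class].
#' @export
readActivityProfile <- function(path,
                                convert = c("none", "inhibitionToActivity")) {
  convert <- match.arg(convert)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("fraction", "activity")
  if (!all(need %in% names(tab)))
    stop("activity table needs columns: ", paste(need, collapse = ", "))
  fr <- .checkNumericColumn(tab$fraction, "fraction")
  ac <- .checkNumericColumn(tab$activity, "activity")
  if (anyDuplicated(fr))
    stop("duplicate fraction index: ", fr[duplicated(fr)][1])
  o <- order(fr)
  fr <- fr[o]; ac <- ac[o]
  if (!identical(as.integer(fr), seq_along(fr)))
    stop("fraction indices must be exactly 1..N (gap or offset found)")
  if (convert == "inhibitionToActivity") ac <- 100 - ac
  ActivityProfile(ac)
}

#' Write an activity profile
#'
#' @param activity an [ActivityProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeActivityProfile <- function(activity, path) {
  stopifnot(is(activity, "ActivityProfile"))
  v <- activityValues(activity)
  .writeTsv(data.frame(fraction = seq_along(v), activity = v), path)
  invisible(path)
}

#' Read a pre-binned bin-by-fraction intensity matrix
#'
#' Wide TSV: one row per mass bin with the bin center in column `mz`,
#' fraction intensities in columns `F1..FN` (any all-numeric-suffix naming
#' is accepted in file order), and optional grouping annotation columns
#' `group_center` / `group_nf` (fraction number of the group's center
#' position and the group's fraction count), which land in `rowData`.
#' All-zero rows are retained. Whether intensities are raw, per-row
#' unit-norm or per-row percent-of-maximum is detected and recorded in the
#' object's metadata (`binNormalization()`).
#'
#' @param path file path.
#' @param nFractions declared N; error if the file disagrees.
#' @return A [BinnedMatrix-class].
#' @export
readBinnedMatrix <- function(path, nFractions = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"mz" %in% names(tab))
    stop("binned matrix needs a 'mz' column")
  groupCols <- intersect(c("group_center", "group_nf"), names(tab))
  fracCols <- setdiff(names(tab), c("mz", groupCols))
  if (!is.null(nFractions) && length(fracCols) != nFractions)
    stop(sprintf("file has %d fraction columns but N = %d was declared",
                 length(fracCols), nFractions))
  if (length(fracCols) == 0L) stop("no fraction columns found")
  mz <- .checkNumericColumn(tab$mz, "mz")
  m <- do.call(cbind, lapply(fracCols, function(col)
    .checkNumericColumn(tab[[col]], col)))
  rd <- if (length(groupCols))
    as.data.frame(lapply(tab[groupCols], as.numeric)) else NULL
  norms <- sqrt(rowSums(m^2))
  normalization <-
    if (nrow(m) && all(abs(norms[norms > 0] - 1) < 1e-6)) "unit"
    else if (nrow(m) && all(m <= 100 + 1e-9) &&
             all(abs(apply(m, 1, max)[norms > 0] - 100) < 1e-6)) "percent"
    else "raw"
  BinnedMatrix(mz, m, binWidthPpm = NA_real_, normalization = normalization,
               rowData = rd)
}

#' Write a BinnedMatrix as a wide TSV
#'
#' @param bm a [BinnedMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBinnedMatrix <- function(bm, path) {
  stopifnot(is(bm, "BinnedMatrix"))
  m <- intensityMatrix(bm)
  tab <- data.frame(mz = binCenters(bm), m, check.names = FALSE)
  rd <- rowData(bm)
  for (nm in intersect(c("group_center", "group_nf"), names(rd)))
    tab[[nm]] <- rd[[nm]]
  .writeTsv(tab, path)
  invisible(path)
}

#' Percent DPPH remaining
#'
#' `((abT - abB) / ab0) * 100`, where `abT` is the absorbance of the DPPH
#' solution with the tested extract, `ab0` the absorbance of DPPH with
#' solvent only, and `abB` the extract-only blank absorbance. Lower values
#' mean stronger radical scavenging; `100 - dpphInhibition(...)` is the
#' conventional activity scale.
#'
#' @param abT,ab0,abB absorbances (vectorized; `ab0` must be > 0).
#' @return %DPPH remaining.
#' @examples
#' dpphInhibition(0.5, 1.0, 0.1)  # 40
#' @export
dpphInhibition <- function(abT, ab0, abB) {
  if (any(!is.finite(ab0)) || any(ab0 <= 0))
    stop("ab0 must be finite and > 0")
  ((abT - abB) / ab0) * 100
}

#' Write a ranked candidate table
#'
#' TSV with columns rank, mz, start, end, nf, sigma, intensity, cj,
#' score2, score3, score plus any annotation columns present (e.g. name,
#' formula).
#'
#' @param candidates data.frame as returned by [rankCandidates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(candidates, path) {
  cols <- c("rank", "mz", "start", "end", "nf", "sigma", "intensity",
            "cj", "score2", "score3", "score")
  missing <- setdiff(cols, names(candidates))
  if (length(missing))
    stop("candidate table lacks column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(candidates), cols)
  .writeTsv(candidates[c(cols, extra)], path)
  invisible(path)
}

#' Read a ranked candidate table written by [writeCandidates()]
#'
#' @param path file path.
#' @return data.frame in rank order.
#' @export
readCandidates <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in intersect(c("rank", "mz", "start", "end", "nf", "sigma",
                          "intensity", "cj", "score2", "score3", "score"),
                        names(tab)))
    tab[[col]] <- .checkNumericColumn(tab[[col]], col, allowNA = TRUE)
  tab
}

#' Write an enrichment curve as a TSV of (x, y) points
#'
#' @param curve an [EnrichmentCurve-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnrichmentCurve <- function(curve, path) {
  stopifnot(is(curve, "EnrichmentCurve"))
  .writeTsv(curvePoints(curve), path)
  invisible(path)
}
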