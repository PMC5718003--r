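## One-call pipeline and its configuration. The CLI in
## inst/scripts/scamp.R is a thin wrapper over these functions.

#' Pipeline configuration
#'
#' All preprocessing / scoring / evaluation parameters with their
#' defaults: 0.5-ppm bins, S/N > 4, 1-ppm de-isotoping over up to three
#' heavy carbons, blank ratio 3, scoring method 3, C_j on the 0-100 scale,
#' "roc" AUC convention. Unknown keys are rejected.
#'
#' @param binPpm bin half-width (ppm).
#' @param minSnr S/N threshold (strictly greater than).
#' @param deisotopeTolPpm de-isotoping mass tolerance (ppm).
#' @param maxShift heavy carbons tested (1..3).
#' @param blankTolPpm blank-subtraction mass tolerance (ppm).
#' @param blankRatio blank-subtraction intensity ratio (>= 1; Inf removes
#'   on mass match alone).
#' @param method scoring method (1, 2 or 3).
#' @param minCj optional C_j speed filter (NULL = off).
#' @param aucConvention `"roc"` or `"screened"`.
#' @param labelTolPpm ppm tolerance for matching candidates to known
#'   actives.
#' @return A classed list (`ScampConfig`).
#' @export
scampConfig <- function(binPpm = 0.5, minSnr = 4, deisotopeTolPpm = 1,
                        maxShift = 3, blankTolPpm = 1, blankRatio = 3,
                        method = 3, minCj = NULL,
                        aucConvention = c("roc", "screened"),
                        labelTolPpm = 1) {
  aucConvention <- match.arg(aucConvention)
  stopifnot(binPpm > 0, minSnr >= 0, deisotopeTolPpm > 0,
            maxShift %in% 1:3, blankTolPpm > 0, blankRatio >= 1,
            method %in% 1:3, labelTolPpm > 0)
  structure(list(binPpm = binPpm, minSnr = minSnr,
                 deisotopeTolPpm = deisotopeTolPpm, maxShift = maxShift,
                 blankTolPpm = blankTolPpm, blankRatio = blankRatio,
                 method = method, minCj = minCj,
                 aucConvention = aucConvention, labelTolPpm = labelTolPpm),
            class = "ScampConfig")
}

#' @export
print.ScampConfig <- function(x, ...) {
  cat("ScampConfig:\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(x[[nm]])) "off" else paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the [scampConfig()] arguments; unknown keys are rejected
#' with an error naming the offending key.
#'
#' @param path JSON file path.
#' @return A `ScampConfig`.
#' @export
readScampConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(scampConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(scampConfig, raw)
}

#' Run the full scoring pipeline
#'
#' Preprocesses the fraction peak lists (S/N filter, optional blank
#' averaging and subtraction, de-isotoping, ppm binning) and ranks every
#' mass bin against the activity profile with the configured scoring
#' method.
#'
#' @param fractions a [FractionSet-class].
#' @param activity an [ActivityProfile-class] (length must equal
#'   `nFractions(fractions)`).
#' @param blanks optional replicate blank spectra ([FractionSet-class]).
#' @param config a [scampConfig()].
#' @return list with `candidates` (ranked data.frame), `matrix` (the
#'   [BinnedMatrix-class]) and `config`.
#' @export
runScamp <- function(fractions, activity, blanks = NULL,
                     config = scampConfig()) {
  stopifnot(is(fractions, "FractionSet"), is(activity, "ActivityProfile"),
            inherits(config, "ScampConfig"))
  if (nFractions(fractions) != nFractions(activity))
    stop("fraction count mismatch: peaks have ", nFractions(fractions),
         ", activity has ", nFractions(activity))
  bm <- preprocessFractions(fractions, blanks = blanks,
                            minSnr = config$minSnr,
                            blankTolPpm = config$blankTolPpm,
                            blankRatio = config$blankRatio,
                            deisotopeTolPpm = config$deisotopeTolPpm,
                            maxShift = config$maxShift,
                            binPpm = config$binPpm)
  cand <- rankCandidates(bm, activity, method = config$method,
                         minCj = config$minCj)
  list(candidates = cand, matrix = bm, config = config)
}

#' Evaluate a ranked candidate list against ground truth
#'
#' Labels candidates by m/z proximity to the known actives and computes
#' the enrichment curve of the ranking.
#'
#' @param candidates data.frame from [rankCandidates()] (rank order).
#' @param truth ground truth (see [truthLabels()]).
#' @param tolPpm label matching tolerance (ppm).
#' @param convention AUC convention, `"roc"` or `"screened"`.
#' @return list with `labels` (per-candidate data.frame), `curve`
#'   ([EnrichmentCurve-class]), `auc`, and `topActives` -- the number of
#'   distinct true actives among the top 20 candidates.
#' @export
evaluateRanking <- function(candidates, truth, tolPpm = 1,
                            convention = c("roc", "screened")) {
  convention <- match.arg(convention)
  labels <- truthLabels(truth, candidates, tolPpm = tolPpm)
  curve <- enrichmentCurve(labels$active, convention = convention)
  top <- head(labels, 20)
  list(labels = labels, curve = curve, auc = curve@auc,
       topActives = length(unique(top$match[top$active])))
}
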