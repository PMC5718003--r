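## Molecular-formula arithmetic for negative-mode ESI work: monoisotopic
## masses, [M-H]- m/z, 13C spacing, and candidate matching in mDa.

## NIST-recommended monoisotopic atomic masses (Da). 12C defines the scale.
.ISOTOPE_MASS <- c(C = 12,
                   H = 1.00782503207,
                   N = 14.0030740048,
                   O = 15.9949146196,
                   S = 31.97207100,
                   P = 30.97376163)

## m(1H) - m(e-): subtracting this from the neutral mass gives [M-H]-.
## Dropping the electron mass shifts every value by ~0.55 mDa, which is
## far outside FT-ICR accuracy, so the electron must be kept.
.PROTON_MASS <- 1.00727646688

## mass(13C) - mass(12C), Da
.C13_DELTA <- 1.0033548378

#' Monoisotopic atomic masses used by the package
#'
#' @return Named numeric vector of monoisotopic masses (Da) for the
#'   supported elements C, H, N, O, S, P (NIST-recommended values).
#' @export
isotopeMasses <- function() .ISOTOPE_MASS

#' Mass of the proton (Da)
#'
#' The value subtracted from a neutral monoisotopic mass to obtain the
#' m/z of the deprotonated ion; equals m(1H) - m(e-), i.e. the electron
#' stays with the ion.
#' @return 1.00727646688
#' @export
protonMass <- function() .PROTON_MASS

#' Parse a Hill-notation molecular formula
#'
#' @param text formula string such as `"C7H6O5"`; an omitted count means 1.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C7H6O5")   # gallic acid
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("formula must be a single non-empty string")
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(parts)) != nchar(text))
    stop("malformed formula near '",
         substr(text, sum(nchar(parts)) + 1, nchar(text)), "'")
  counts <- integer(0)
  for (tok in parts) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% names(.ISOTOPE_MASS))
      stop("unsupported element symbol '", el, "' in formula '", text, "'")
    ns <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(ns)) as.integer(ns) else 1L
    if (n < 1L) stop("element count must be positive in token '", tok, "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Render element counts back to a Hill-notation string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' `parseFormula(formulaString(f))` is the identity.
#'
#' @param counts named integer vector as returned by [parseFormula()].
#' @return Formula string.
#' @export
formulaString <- function(counts) {
  counts <- .asFormula(counts)
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (counts[[e]] > 1L) counts[[e]] else ""), character(1)),
    collapse = "")
}

.asFormula <- function(f) {
  if (is.character(f)) f <- parseFormula(f)
  if (is.null(names(f)) || any(!names(f) %in% names(.ISOTOPE_MASS)))
    stop("formula must be a Hill string or a named count vector over ",
         paste(names(.ISOTOPE_MASS), collapse = ","))
  f <- f[f != 0]
  if (length(f) == 0L) stop("formula is empty")
  if (any(f < 0) || any(f != round(f))) stop("element counts must be positive integers")
  storage.mode(f) <- "integer"
  f
}

#' Neutral monoisotopic mass of a formula
#'
#' @param f formula string or named count vector.
#' @return Mass in Da at full double precision.
#' @examples
#' monoisotopicMass("C7H6O5")  # 170.02152...
#' @export
monoisotopicMass <- function(f) {
  f <- .asFormula(f)
  sum(.ISOTOPE_MASS[names(f)] * f)
}

#' m/z of the deprotonated ion \[M-H\]-
#'
#' `monoisotopicMass(f) - protonMass()`, i.e. M - m(H) + m(e-).
#'
#' @param f formula string or named count vector; must contain hydrogen.
#' @return m/z in Th.
#' @examples
#' deprotonatedMz("C7H6O5")    # 169.01425 (gallic acid)
#' deprotonatedMz("C27H30O16") # 609.14611 (rutin)
#' @export
deprotonatedMz <- function(f) {
  f <- .asFormula(f)
  if (!"H" %in% names(f))
    stop("cannot deprotonate a formula without hydrogen")
  monoisotopicMass(f) - .PROTON_MASS
}

#' Mass shift of n heavy carbons
#'
#' @param n number of 13C substitutions, 1..3.
#' @return `n * (mass(13C) - mass(12C))` in Da.
#' @export
carbon13Shift <- function(n) {
  if (any(is.na(n)) || any(n != round(n)) || any(n < 1) || any(n > 3))
    stop("n must be an integer in 1..3")
  n * .C13_DELTA
}

#' Match an observed m/z against candidate formulas
#'
#' Signed error is `(observed - calculated) * 1000` mDa; the result is
#' sorted by absolute error, ascending.
#'
#' @param observedMz observed \[M-H\]- m/z.
#' @param candidates character vector of formulas, optionally named, or a
#'   data.frame with columns `name` and `formula`.
#' @param tolMda tolerance in mDa (> 0) for the `withinTol` flag.
#' @return data.frame with columns name, formula, calcMz, errorMda,
#'   withinTol; zero rows for an empty candidate list.
#' @examples
#' matchFormula(169.01426, c(`gallic acid` = "C7H6O5"), tolMda = 1)
#' @export
matchFormula <- function(observedMz, candidates, tolMda = 1) {
  stopifnot(is.numeric(observedMz), length(observedMz) == 1L,
            is.finite(observedMz))
  if (!is.numeric(tolMda) || length(tolMda) != 1L || tolMda <= 0)
    stop("tolMda must be a positive scalar")
  if (is.data.frame(candidates)) {
    nm <- as.character(candidates$name)
    fo <- as.character(candidates$formula)
  } else {
    fo <- as.character(candidates)
    nm <- if (is.null(names(candidates))) fo else names(candidates)
  }
  if (length(fo) == 0L)
    return(data.frame(name = character(), formula = character(),
                      calcMz = numeric(), errorMda = numeric(),
                      withinTol = logical()))
  calc <- vapply(fo, deprotonatedMz, numeric(1), USE.NAMES = FALSE)
  err <- (observedMz - calc) * 1000
  out <- data.frame(name = nm, formula = fo, calcMz = calc, errorMda = err,
                    withinTol = abs(err) <= tolMda)
  out <- out[order(abs(out$errorMda), out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a candidate-formula table
#'
#' Two-column TSV (`name`, `formula`), UTF-8, header mandatory.
#'
#' @param path file path.
#' @return data.frame with columns name, formula.
#' @export
readFormulaTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "formula")
  if (!all(need %in% names(tab)))
    stop("formula table needs columns: ", paste(need, collapse = ", "))
  invisible(lapply(tab$formula, parseFormula))  # validate early
  tab[need]
}
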