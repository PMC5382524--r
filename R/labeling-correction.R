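#' @include core.R
NULL

## Natural isotope abundance handling for measured MDVs. The correction
## deconvolves the mass envelope contributed by every atom outside the
## measured carbon backbone (derivatization carbons, H, N, O, Si, S, ...)
## using the standard isotope abundance table.

.isotopeTable <- list(
  ## mass-shift distributions (m+0, m+1, m+2, ...), IUPAC representative values
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Si = c(0.92223, 0.04685, 0.03092),
  S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  P  = 1,
  F  = 1,
  I  = 1,
  Na = 1,
  K  = c(0.932581, 0.000117, 0.067302)
)

#' Natural isotope abundance table
#'
#' @return Named list: element symbol -> numeric vector of natural mass-shift
#'   probabilities (m+0, m+1, ...). Pass a modified copy to
#'   [correctionMatrix()]/[correctMDV()] to override values.
#' @export
isotopeAbundances <- function() .isotopeTable

#' Create an MS fragment record
#'
#' @param name Full fragment name (e.g. `"glu_12345"`).
#' @param abbreviation Short name used interchangeably in lookups.
#' @param formula Elemental composition of the detected ion, including any
#'   derivatization groups.
#' @param nCarbons Number of backbone carbons actually measured.
#' @param formulaNoBackbone Composition excluding the `nCarbons` backbone
#'   carbons; computed from `formula` when omitted.
#' @return A `Fragment` object.
#' @export
Fragment <- function(name, abbreviation = name, formula, nCarbons,
                     formulaNoBackbone = NULL) {
  nCarbons <- as.integer(nCarbons)
  if (is.null(formulaNoBackbone)) {
    cf <- parseFormula(formula)
    if (!"C" %in% names(cf) && nCarbons > 0)
      emufluxError("formula has no carbons to assign to the backbone",
                   "validationError")
    if (nCarbons > 0) {
      cf[["C"]] <- cf[["C"]] - nCarbons
      if (cf[["C"]] < 0)
        emufluxError("nCarbons exceeds the carbons in the formula",
                     "validationError")
      if (cf[["C"]] == 0) cf <- cf[names(cf) != "C"]
    }
    formulaNoBackbone <- formulaString(cf)
  }
  new("Fragment", name = name, abbreviation = abbreviation, formula = formula,
      nCarbons = nCarbons, formulaNoBackbone = formulaNoBackbone)
}

setMethod("show", "Fragment", function(object) {
  cat(sprintf("Fragment %s (%s): %s, %d backbone carbons, envelope %s\n",
              object@name, object@abbreviation, object@formula,
              object@nCarbons,
              if (nzchar(object@formulaNoBackbone))
                object@formulaNoBackbone else "(none)"))
})

## mass-shift distribution of the whole non-backbone envelope
envelopeDistribution <- function(fragment, abundances = isotopeAbundances()) {
  counts <- parseFormula(fragment@formulaNoBackbone)
  unknown <- setdiff(names(counts), names(abundances))
  if (length(unknown))
    emufluxError(sprintf(
      "no natural-abundance data for element(s) %s (supported: %s)",
      paste(unknown, collapse = ", "),
      paste(names(abundances), collapse = ", ")), "lookupError")
  env <- 1
  for (el in names(counts))
    for (i in seq_len(counts[[el]]))
      env <- convolveRaw(env, abundances[[el]])
  env
}

#' Natural-abundance correction matrix of a fragment
#'
#' Column `m` (0-based) is the mass-isotope distribution of the non-backbone
#' atom envelope shifted down by `m` backbone labels, truncated to the
#' `nCarbons + 1` measured masses and column-normalized. Multiplying a true
#' backbone MDV by this matrix predicts the measured envelope; [correctMDV()]
#' inverts the map.
#'
#' @param fragment A [Fragment].
#' @param abundances Isotope table (see [isotopeAbundances()]).
#' @return A column-stochastic `(nCarbons+1) x (nCarbons+1)` matrix.
#' @export
correctionMatrix <- function(fragment, abundances = isotopeAbundances()) {
  n <- fragment@nCarbons + 1L
  env <- envelopeDistribution(fragment, abundances)
  M <- matrix(0, n, n)
  for (m in seq_len(n) - 1L) {
    col <- numeric(n)
    reach <- min(n - m, length(env))
    col[m + seq_len(reach)] <- env[seq_len(reach)]
    M[, m + 1L] <- col / sum(col)
  }
  M
}

#' Correct a measured MDV for natural isotope abundance
#'
#' Solves `correctionMatrix(fragment) %*% corrected = raw` by nonnegative
#' least squares (negative fractions from measurement noise are not allowed)
#' and renormalizes. A residual above 0.1 indicates a raw envelope severely
#' inconsistent with the fragment formula and triggers a warning.
#'
#' @param raw Measured [MDV] (or fraction vector) of length `nCarbons + 1`.
#' @param fragment The measured [Fragment].
#' @param abundances Isotope table override.
#' @return The corrected, normalized [MDV].
#' @export
correctMDV <- function(raw, fragment, abundances = isotopeAbundances()) {
  f <- if (is(raw, "MDV")) fractions(raw) else as.numeric(raw)
  if (length(f) != fragment@nCarbons + 1L)
    emufluxError(sprintf("raw MDV length %d does not match %d carbons + 1",
                         length(f), fragment@nCarbons), "validationError")
  M <- correctionMatrix(fragment, abundances)
  sol <- pracma::lsqnonneg(M, f)
  if (sqrt(sum((M %*% sol$x - f)^2)) > 0.1)
    warning(sprintf(
      "fragment '%s': raw envelope poorly explained by the correction model (residual %.3f)",
      fragment@name, sqrt(sum((M %*% sol$x - f)^2))))
  MDV(sol$x)
}

#' Measured labeling data for one fragment
#'
#' Container pairing a fragment with its raw and natural-abundance-corrected
#' MDVs. The mass-spectrometry platform (`LCMS`, `GCMS`, `CEMS`) is carried as
#' metadata; `LCMSLabelData()`, `GCMSLabelData()` and `CEMSLabelData()` are
#' the platform-tagged constructors.
#'
#' @param fragment A [Fragment].
#' @param raw Measured [MDV].
#' @param platform Platform tag.
#' @param abundances Isotope table override.
#' @return A `LabelData` object with the correction applied.
#' @export
LabelData <- function(fragment, raw, platform = c("LCMS", "GCMS", "CEMS"),
                      abundances = isotopeAbundances()) {
  platform <- match.arg(platform)
  raw <- if (is(raw, "MDV")) raw else MDV(raw)
  new("LabelData", fragment = fragment, rawMDV = raw,
      correctedMDV = correctMDV(raw, fragment, abundances),
      platform = platform)
}

#' @rdname LabelData
#' @export
LCMSLabelData <- function(fragment, raw, ...) LabelData(fragment, raw, "LCMS", ...)
#' @rdname LabelData
#' @export
GCMSLabelData <- function(fragment, raw, ...) LabelData(fragment, raw, "GCMS", ...)
#' @rdname LabelData
#' @export
CEMSLabelData <- function(fragment, raw, ...) LabelData(fragment, raw, "CEMS", ...)

setMethod("show", "LabelData", function(object) {
  cat(sprintf("%s data for %s\n  raw:       ", object@platform,
              object@fragment@name))
  cat(sprintf("%.4f", fractions(object@rawMDV)), "\n  corrected: ")
  cat(sprintf("%.4f", fractions(object@correctedMDV)), "\n")
})

#' Load the fragment database
#'
#' Reads a fragment database CSV with columns exactly
#' `name, abbreviation, formula, n_carbons, formula_no_backbone`. The package
#' ships an editable seed database under `extdata/fragments.csv`.
#'
#' @param path CSV path; default is the shipped database.
#' @return Named list of [Fragment] objects (keyed by name).
#' @export
fragmentDatabase <- function(path = system.file("extdata", "fragments.csv",
                                                package = "emuflux")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  frs <- lapply(seq_len(nrow(df)), function(i)
    Fragment(df$name[i], df$abbreviation[i], df$formula[i], df$n_carbons[i],
             df$formula_no_backbone[i]))
  names(frs) <- df$name
  frs
}

#' Look up a fragment by name or abbreviation
#'
#' Case-insensitive exact match on either field; a miss reports the nearest
#' known name as a suggestion.
#'
#' @param db Database from [fragmentDatabase()].
#' @param nameOrAbbrev Query string.
#' @return The matching [Fragment].
#' @export
lookupFragment <- function(db, nameOrAbbrev) {
  q <- tolower(nameOrAbbrev)
  names_ <- tolower(vapply(db, function(f) f@name, character(1)))
  abbrevs <- tolower(vapply(db, function(f) f@abbreviation, character(1)))
  i <- match(q, names_)
  if (is.na(i)) i <- match(q, abbrevs)
  if (is.na(i)) {
    pool <- unique(c(names_, abbrevs))
    nearest <- pool[which.min(utils::adist(q, pool))]
    emufluxError(sprintf("fragment '%s' not found; did you mean '%s'?",
                         nameOrAbbrev, nearest), "notFoundError")
  }
  db[[i]]
}
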