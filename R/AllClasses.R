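#' @import methods
NULL

## Central S4 classes. Validity methods enforce the domain invariants; all
## user-facing construction goes through the camelCase constructor functions
## defined alongside each class.

setClass("Metabolite",
  representation(id = "character", name = "character", carbons = "integer",
                 compartment = "character", source = "logical",
                 excreted = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@carbons) != 1L || is.na(object@carbons) ||
        object@carbons < 0L)
      msg <- c(msg, "'carbons' must be a single nonnegative integer")
    if (length(msg)) msg else TRUE
  })

setClass("Reaction",
  representation(id = "character", reactants = "numeric", products = "numeric",
                 reversible = "logical", lowerBound = "numeric",
                 upperBound = "numeric", objectiveCoefficient = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@reactants) && (is.null(names(object@reactants)) ||
        any(!nzchar(names(object@reactants)))))
      msg <- c(msg, "reactants must be a named numeric vector")
    if (length(object@products) && (is.null(names(object@products)) ||
        any(!nzchar(names(object@products)))))
      msg <- c(msg, "products must be a named numeric vector")
    if (any(object@reactants <= 0) || any(object@products <= 0))
      msg <- c(msg, "stoichiometric coefficients must be > 0")
    if (object@lowerBound > object@upperBound)
      msg <- c(msg, sprintf("reaction '%s': lowerBound > upperBound",
                            object@id))
    if (!object@reversible && object@lowerBound < 0)
      msg <- c(msg, sprintf(
        "reaction '%s': irreversible reaction with negative lower bound",
        object@id))
    if (length(msg)) msg else TRUE
  })

setClass("Flux",
  representation(net = "numeric", exchange = "numeric"),
  validity = function(object) {
    if (length(object@net) != 1L || length(object@exchange) != 1L)
      return("'net' and 'exchange' must be single numbers")
    if (is.na(object@exchange) || object@exchange < 0)
      return("'exchange' must be nonnegative")
    TRUE
  })

setClass("RangedNumber",
  representation(lo = "numeric", best = "numeric", hi = "numeric"),
  validity = function(object) {
    if (any(lengths(list(object@lo, object@best, object@hi)) != 1L))
      return("'lo', 'best' and 'hi' must be single numbers")
    if (object@lo > object@best || object@best > object@hi)
      return("range must satisfy lo <= best <= hi")
    TRUE
  })

setClass("MDV",
  representation(fractions = "numeric", errors = "numeric"),
  validity = function(object) {
    f <- object@fractions
    if (!length(f)) return("'fractions' must be non-empty")
    if (any(!is.finite(f))) return("'fractions' must be finite")
    if (any(f < -1e-12) || any(f > 1 + 1e-9))
      return("mass fractions must lie in [0, 1]")
    if (abs(sum(f) - 1) > 1e-9)
      return("mass fractions must sum to 1 (use MDV() to normalize)")
    if (length(object@errors) &&
        length(object@errors) != length(f))
      return("'errors' must match the length of 'fractions'")
    TRUE
  })

setClass("AtomTransition",
  representation(reactionId = "character", reactants = "data.frame",
                 products = "data.frame", weight = "numeric"),
  validity = function(object) {
    msg <- character(0)
    for (side in list(object@reactants, object@products))
      if (!all(c("met", "pattern") %in% names(side)))
        msg <- c(msg, "pattern sides need 'met' and 'pattern' columns")
    if (length(object@weight) != 1L || object@weight <= 0 ||
        object@weight > 1)
      msg <- c(msg, "'weight' must be in (0, 1]")
    if (!length(msg)) {
      rl <- paste(object@reactants$pattern, collapse = "")
      pl <- paste(object@products$pattern, collapse = "")
      if (anyDuplicated(strsplit(rl, "")[[1]]))
        msg <- c(msg, sprintf(
          "reaction '%s': reactant carbon letters must be distinct",
          object@reactionId))
      if (!identical(sortLetters(rl), sortLetters(pl)))
        msg <- c(msg, sprintf(
          "reaction '%s': product carbon letters are not a permutation of reactant letters",
          object@reactionId))
    }
    if (length(msg)) msg else TRUE
  })

setClass("EMU",
  representation(metaboliteId = "character", indices = "integer"),
  validity = function(object) {
    if (!length(object@indices)) return("an EMU needs at least one carbon")
    if (any(object@indices < 1L)) return("carbon indices are 1-based")
    if (anyDuplicated(object@indices)) return("carbon indices must be distinct")
    if (is.unsorted(object@indices)) return("carbon indices must be ascending")
    TRUE
  })

setClass("EMUTransition",
  representation(reactionId = "character", direction = "character",
                 sources = "list", target = "EMU", weight = "numeric"),
  validity = function(object) {
    if (!object@direction %in% c("forward", "backward"))
      return("'direction' must be \"forward\" or \"backward\"")
    if (!length(object@sources)) return("at least one source EMU required")
    szs <- vapply(object@sources, function(e) length(e@indices), integer(1))
    if (sum(szs) != length(object@target@indices))
      return("sum of source EMU sizes must equal the target EMU size")
    TRUE
  })

setClass("ReactionNetwork",
  representation(metabolites = "list", reactions = "list"),
  validity = function(object) {
    msg <- character(0)
    mids <- vapply(object@metabolites, function(m) m@id, character(1))
    rids <- vapply(object@reactions, function(r) r@id, character(1))
    if (anyDuplicated(mids))
      msg <- c(msg, paste("duplicate metabolite ids:",
                          paste(unique(mids[duplicated(mids)]), collapse = ", ")))
    if (anyDuplicated(rids))
      msg <- c(msg, paste("duplicate reaction ids:",
                          paste(unique(rids[duplicated(rids)]), collapse = ", ")))
    for (r in object@reactions) {
      unknown <- setdiff(c(names(r@reactants), names(r@products)), mids)
      if (length(unknown))
        msg <- c(msg, sprintf("reaction '%s' references unknown metabolites: %s",
                              r@id, paste(unknown, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

setClass("C13ReactionNetwork", contains = "ReactionNetwork",
  representation(transitions = "list", feed = "list", measurements = "list"))

setClass("TwoScaleNetwork",
  representation(genomeScale = "ReactionNetwork", core = "C13ReactionNetwork",
                 coreMap = "list"),
  validity = function(object) {
    gsIds <- reactionIds(object@genomeScale)
    msg <- character(0)
    for (cid in reactionIds(object@core)) {
      mapped <- if (cid %in% names(object@coreMap)) object@coreMap[[cid]] else cid
      if (!all(mapped %in% gsIds))
        msg <- c(msg, sprintf(
          "core reaction '%s' has no genome-scale counterpart", cid))
    }
    if (length(msg)) msg else TRUE
  })

setClass("FluxDistribution",
  representation(fluxes = "list", objectiveValue = "numeric"),
  validity = function(object) {
    if (length(object@fluxes) && is.null(names(object@fluxes)))
      return("fluxes must be named by reaction id")
    if (!all(vapply(object@fluxes, is, logical(1), "Flux")))
      return("all elements must be Flux objects")
    TRUE
  })

setClass("RangedFluxDistribution",
  representation(ranges = "list"),
  validity = function(object) {
    if (length(object@ranges) && is.null(names(object@ranges)))
      return("ranges must be named by reaction id")
    if (!all(vapply(object@ranges, is, logical(1), "RangedNumber")))
      return("all elements must be RangedNumber objects")
    TRUE
  })

setClass("FitResult",
  representation(fluxes = "FluxDistribution", ssr = "numeric",
                 residuals = "numeric", nMeasurements = "integer",
                 nFreeFluxes = "integer", converged = "logical",
                 restartsUsed = "integer", degenerate = "logical",
                 freeParameters = "numeric", context = "list"),
  validity = function(object) {
    if (object@ssr < 0) return("'ssr' must be nonnegative")
    if (length(object@residuals) &&
        abs(object@ssr - sum(object@residuals^2)) >
          1e-6 * max(1, object@ssr))
      return("'ssr' must equal the sum of squared residuals")
    TRUE
  })

setClass("Fragment",
  representation(name = "character", abbreviation = "character",
                 formula = "character", nCarbons = "integer",
                 formulaNoBackbone = "character"),
  validity = function(object) {
    cf <- parseFormula(object@formula)
    nc <- if ("C" %in% names(cf)) cf[["C"]] else 0L
    if (nc < object@nCarbons)
      return("formula carries fewer carbons than the measured backbone")
    TRUE
  })

setClass("LabelData",
  representation(fragment = "Fragment", rawMDV = "MDV", correctedMDV = "MDV",
                 platform = "character"),
  validity = function(object) {
    if (!object@platform %in% c("LCMS", "GCMS", "CEMS"))
      return("platform must be one of LCMS, GCMS, CEMS")
    n <- object@fragment@nCarbons + 1L
    if (length(object@rawMDV@fractions) != n ||
        length(object@correctedMDV@fractions) != n)
      return("MDV lengths must equal nCarbons + 1")
    TRUE
  })

setClass("PCAPResult",
  representation(scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", production = "numeric",
                 centers = "numeric", scales = "numeric"),
  validity = function(object) {
    if (nrow(object@scores) != length(object@production))
      return("production length must equal the number of rows (strains)")
    if (is.unsorted(rev(object@explainedVariance)))
      return("explained variance must be nonincreasing")
    TRUE
  })
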