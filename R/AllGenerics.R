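#' @include AllClasses.R
NULL

#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @export
setGeneric("stoichiometricMatrix",
           function(x, internalOnly = TRUE) standardGeneric("stoichiometricMatrix"))
#' @export
setGeneric("netFlux", function(x, ...) standardGeneric("netFlux"))
#' @export
setGeneric("exchangeFlux", function(x, ...) standardGeneric("exchangeFlux"))
#' @export
setGeneric("forwardFlux", function(x) standardGeneric("forwardFlux"))
#' @export
setGeneric("backwardFlux", function(x) standardGeneric("backwardFlux"))
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @export
setGeneric("mdvErrors", function(x) standardGeneric("mdvErrors"))
#' @export
setGeneric("emuName", function(x) standardGeneric("emuName"))
#' @export
setGeneric("emuSize", function(x) standardGeneric("emuSize"))
#' @export
setGeneric("rangeContains", function(x, value) standardGeneric("rangeContains"))
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @export
setGeneric("fittedFluxes", function(x) standardGeneric("fittedFluxes"))
#' @export
setGeneric("ssr", function(x) standardGeneric("ssr"))
#' @export
setGeneric("fluxRanges", function(x) standardGeneric("fluxRanges"))
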