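#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Create a metabolite
#'
#' Metabolites carry an id (unique within a network), a carbon count and flags
#' marking them as a feed (source) or excreted species. Source and excreted
#' metabolites are excluded from steady-state mass-balance rows.
#'
#' @param id Unique metabolite identifier, e.g. `"accoa_c"`.
#' @param carbons Nonnegative integer number of carbon atoms.
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Compartment label (kept verbatim, may be `""`).
#' @param source Logical; is this a feed metabolite?
#' @param excreted Logical; is this metabolite excreted (a product sink)?
#' @return A `Metabolite` object.
#' @examples
#' Metabolite("accoa_c", 2, source = TRUE)
#' @export
Metabolite <- function(id, carbons, name = id, compartment = "",
                       source = FALSE, excreted = FALSE) {
  new("Metabolite", id = id, name = name, carbons = as.integer(carbons),
      compartment = compartment, source = source, excreted = excreted)
}

#' Create a reaction
#'
#' @param id Unique reaction identifier.
#' @param reactants,products Named numeric vectors of positive stoichiometric
#'   coefficients, named by metabolite id.
#' @param reversible Logical. Irreversible reactions must have a nonnegative
#'   lower bound.
#' @param lowerBound,upperBound Flux bounds (mmol gDW^-1 h^-1). Defaults follow
#'   the COBRA convention: `[0, 1000]` irreversible, `[-1000, 1000]` reversible.
#' @param objectiveCoefficient Coefficient of this reaction in the network
#'   objective (0 for most reactions).
#' @return A `Reaction` object.
#' @examples
#' Reaction("CS", reactants = c(accoa = 1, oac = 1), products = c(cit = 1))
#' @export
Reaction <- function(id, reactants = numeric(0), products = numeric(0),
                     reversible = FALSE,
                     lowerBound = if (reversible) -1000 else 0,
                     upperBound = 1000, objectiveCoefficient = 0) {
  new("Reaction", id = id, reactants = reactants, products = products,
      reversible = reversible, lowerBound = lowerBound,
      upperBound = upperBound, objectiveCoefficient = objectiveCoefficient)
}

#' Net/exchange flux decomposition
#'
#' A flux is stored as a net rate plus a nonnegative exchange rate. The derived
#' directional rates follow the standard 13C-MFA convention
#' `forward = exchange + max(net, 0)` and `backward = exchange + max(-net, 0)`,
#' so that `forward - backward = net` and `min(forward, backward) = exchange`.
#'
#' @param net Net flux (may be negative for reversible reactions).
#' @param exchange Nonnegative exchange flux.
#' @return A `Flux` object.
#' @examples
#' f <- Flux(net = -1, exchange = 0.5)
#' forwardFlux(f)   # 0.5
#' backwardFlux(f)  # 1.5
#' @export
Flux <- function(net, exchange = 0) {
  if (is.na(exchange) || exchange < 0)
    emufluxError("'exchange' must be nonnegative", "validationError")
  new("Flux", net = as.numeric(net), exchange = as.numeric(exchange))
}

#' Reconstruct a Flux from directional rates
#'
#' Inverse of the net/exchange decomposition: `net = forward - backward`,
#' `exchange = min(forward, backward)`.
#'
#' @param forward,backward Nonnegative directional fluxes.
#' @return A `Flux` object.
#' @export
fluxFromForwardBackward <- function(forward, backward) {
  if (forward < 0 || backward < 0)
    emufluxError("directional fluxes must be nonnegative", "validationError")
  Flux(net = forward - backward, exchange = min(forward, backward))
}

#' @describeIn Flux net component
#' @param x A `Flux` object.
#' @param ... Unused.
#' @export
setMethod("netFlux", "Flux", function(x, ...) x@net)
#' @describeIn Flux exchange component
#' @export
setMethod("exchangeFlux", "Flux", function(x, ...) x@exchange)
#' @describeIn Flux derived forward rate
#' @export
setMethod("forwardFlux", "Flux", function(x) x@exchange + max(x@net, 0))
#' @describeIn Flux derived backward rate
#' @export
setMethod("backwardFlux", "Flux", function(x) x@exchange + max(-x@net, 0))

setMethod("show", "Flux", function(object) {
  cat(sprintf("Flux(net = %g, exchange = %g; forward = %g, backward = %g)\n",
              object@net, object@exchange, forwardFlux(object),
              backwardFlux(object)))
})

#' Number with confidence limits
#'
#' Holds a best-fit value with lower and upper limits, as used for fluxes whose
#' confidence intervals are derived from the experimental data.
#'
#' @param lo,best,hi Numbers with `lo <= best <= hi`.
#' @return A `RangedNumber` object.
#' @examples
#' r <- RangedNumber(0.3, 0.5, 0.6)
#' rangeContains(r, 0.55)
#' @export
RangedNumber <- function(lo, best, hi) {
  if (lo > best || best > hi)
    emufluxError("range must satisfy lo <= best <= hi", "validationError")
  new("RangedNumber", lo = as.numeric(lo), best = as.numeric(best),
      hi = as.numeric(hi))
}

#' @describeIn RangedNumber is `value` inside `[lo, hi]`?
#' @param x A `RangedNumber`.
#' @param value Number to test.
#' @export
setMethod("rangeContains", "RangedNumber",
          function(x, value) value >= x@lo & value <= x@hi)

setMethod("show", "RangedNumber", function(object) {
  cat(sprintf("[%g, %g, %g]\n", object@lo, object@best, object@hi))
})

#' Mass distribution vector
#'
#' The fraction of molecules of an n-carbon fragment or EMU carrying
#' 0, 1, ..., n labeled carbons. The m0 (unlabeled) component is included, so
#' the vector has length n + 1 and sums to 1.
#'
#' @param fractions Numeric vector of length n + 1; normalized to sum to 1.
#' @param errors Optional standard deviations, same length.
#' @param normalize Divide by the sum (default). With `normalize = FALSE` the
#'   input must already sum to 1 within 1e-9.
#' @return An `MDV` object.
#' @examples
#' MDV(c(0.5, 0.25, 0.25))
#' @export
MDV <- function(fractions, errors = numeric(0), normalize = TRUE) {
  fractions <- as.numeric(fractions)
  if (any(!is.finite(fractions)))
    emufluxError("mass fractions must be finite numbers", "validationError")
  if (any(fractions < -1e-9))
    emufluxError("mass fractions must be nonnegative", "validationError")
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (s <= 0)
    emufluxError("mass fractions must not all be zero", "validationError")
  if (normalize) fractions <- fractions / s
  new("MDV", fractions = fractions, errors = as.numeric(errors))
}

#' @describeIn MDV the fraction vector
#' @param x An `MDV`.
#' @export
setMethod("fractions", "MDV", function(x) x@fractions)
#' @describeIn MDV the standard deviations (may be empty)
#' @export
setMethod("mdvErrors", "MDV", function(x) x@errors)

setMethod("show", "MDV", function(object) {
  cat("MDV:", paste(sprintf("m%d=%.4f", seq_along(object@fractions) - 1L,
                            object@fractions), collapse = " "), "\n")
})

#' Convolve two mass distribution vectors
#'
#' The MDV of a condensation product of two independent moieties is the Cauchy
#' product of the source MDVs: `result[m] = sum_k a[k] * b[m - k]`.
#'
#' @param a,b `MDV` objects (or bare fraction vectors).
#' @return An `MDV` of length `length(a) + length(b) - 1`.
#' @examples
#' fractions(convolveMDV(MDV(c(0.5, 0.5)), MDV(c(0.5, 0.5))))
#' @export
convolveMDV <- function(a, b) {
  fa <- if (is(a, "MDV")) a@fractions else as.numeric(a)
  fb <- if (is(b, "MDV")) b@fractions else as.numeric(b)
  MDV(convolveRaw(fa, fb), normalize = FALSE)
}

## bare-vector convolution used in inner loops
convolveRaw <- function(fa, fb) {
  out <- numeric(length(fa) + length(fb) - 1L)
  for (k in seq_along(fa))
    out[k:(k + length(fb) - 1L)] <- out[k:(k + length(fb) - 1L)] + fa[k] * fb
  out
}

#' Parse an elemental composition string
#'
#' Splits a composition string such as `"H6NO2Si"` into element/count pairs,
#' preserving first-appearance order; an omitted count means 1.
#'
#' @param s Composition string; `""` yields an empty result.
#' @return Named integer vector of counts, names are element symbols.
#' @examples
#' parseFormula("H6NO2Si")  # H=6, N=1, O=2, Si=1
#' @export
parseFormula <- function(s) {
  if (!is.character(s) || length(s) != 1L)
    emufluxError("formula must be a single string", "parseError")
  if (!nzchar(s)) return(structure(integer(0), names = character(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s) || m[1] != 1L)
    emufluxError(sprintf("cannot parse formula '%s'", s), "parseError")
  els <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  out <- integer(0)
  for (i in seq_along(els)) {
    if (els[i] %in% names(out)) out[[els[i]]] <- out[[els[i]]] + cnt[i]
    else out[[els[i]]] <- cnt[i]
  }
  out
}

#' Serialize element counts back to a composition string
#'
#' @param counts Named integer vector as returned by [parseFormula()].
#' @return A canonical composition string (count 1 omitted).
#' @export
formulaString <- function(counts) {
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}
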