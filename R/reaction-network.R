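#' @include atom-transitions.R
NULL

#' Stoichiometric reaction network
#'
#' The container for flux balance analysis: metabolites, reactions with bounds
#' and objective coefficients, and the derived stoichiometric matrix.
#'
#' @param metabolites List of [Metabolite] objects.
#' @param reactions List of [Reaction] objects.
#' @return A `ReactionNetwork` object.
#' @export
ReactionNetwork <- function(metabolites, reactions) {
  new("ReactionNetwork", metabolites = metabolites, reactions = reactions)
}

#' @describeIn ReactionNetwork list of metabolites
#' @param x A network.
#' @export
setMethod("metabolites", "ReactionNetwork", function(x) x@metabolites)
#' @describeIn ReactionNetwork list of reactions
#' @export
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)
#' @describeIn ReactionNetwork metabolite ids
#' @export
setMethod("metaboliteIds", "ReactionNetwork", function(x)
  vapply(x@metabolites, function(m) m@id, character(1)))
#' @describeIn ReactionNetwork reaction ids
#' @export
setMethod("reactionIds", "ReactionNetwork", function(x)
  vapply(x@reactions, function(r) r@id, character(1)))

getMetabolite <- function(network, id) {
  i <- match(id, metaboliteIds(network))
  if (is.na(i))
    emufluxError(sprintf("unknown metabolite '%s'", id), "lookupError")
  network@metabolites[[i]]
}

getReaction <- function(network, id) {
  i <- match(id, reactionIds(network))
  if (is.na(i))
    emufluxError(sprintf("unknown reaction '%s'", id), "lookupError")
  network@reactions[[i]]
}

carbonCounts <- function(network) {
  structure(vapply(network@metabolites, function(m) m@carbons, integer(1)),
            names = metaboliteIds(network))
}

## metabolites that enter steady-state balance rows
internalMetaboliteIds <- function(network) {
  keep <- !vapply(network@metabolites,
                  function(m) m@source || m@excreted, logical(1))
  metaboliteIds(network)[keep]
}

#' Stoichiometric matrix of a network
#'
#' Rows are metabolites (by default only internal, balanced ones), columns are
#' reactions; consumption is negative. `S %*% v = 0` expresses the steady-state
#' mass balance of the internal metabolites.
#'
#' @param x A [ReactionNetwork].
#' @param internalOnly Drop source/excreted metabolite rows (default `TRUE`).
#' @return A dense numeric matrix with dimnames.
#' @export
setMethod("stoichiometricMatrix", "ReactionNetwork",
  function(x, internalOnly = TRUE) {
    mids <- if (internalOnly) internalMetaboliteIds(x) else metaboliteIds(x)
    rids <- reactionIds(x)
    S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
    for (r in x@reactions) {
      for (m in names(r@reactants))
        if (m %in% mids) S[m, r@id] <- S[m, r@id] - r@reactants[[m]]
      for (m in names(r@products))
        if (m %in% mids) S[m, r@id] <- S[m, r@id] + r@products[[m]]
    }
    S
  })

fluxBounds <- function(network) {
  rids <- reactionIds(network)
  list(lb = structure(vapply(network@reactions, function(r) r@lowerBound,
                             numeric(1)), names = rids),
       ub = structure(vapply(network@reactions, function(r) r@upperBound,
                             numeric(1)), names = rids))
}

objectiveCoefficients <- function(network) {
  structure(vapply(network@reactions,
                   function(r) r@objectiveCoefficient, numeric(1)),
            names = reactionIds(network))
}

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("%s with %d metabolites (%d balanced) and %d reactions\n",
              class(object), length(object@metabolites),
              length(internalMetaboliteIds(object)),
              length(object@reactions)))
})

#' Reaction network with carbon transitions
#'
#' A [ReactionNetwork] whose reactions also carry [AtomTransition]s, plus the
#' feed labeling specification and optional measured fragment MDVs — the
#' substrate for 13C metabolic flux analysis.
#'
#' @param network A [ReactionNetwork] (or metabolite/reaction lists via `...`).
#' @param transitions List of [AtomTransition] objects, validated against the
#'   network (see [carbonTransitionsOK()]).
#' @param feed Named list: metabolite id -> data frame with columns `mask`
#'   (positional isotopomer string, `"01"` = carbon 2 labeled) and `fraction`
#'   (mixture fractions summing to 1).
#' @param measurements List of `list(fragment = <name>, mdv = <MDV>)` entries;
#'   fragment names follow the `"<met>_<positions>"` convention, e.g.
#'   `"glu_12345"`.
#' @param validate Stop on any consistency report (default `TRUE`).
#' @return A `C13ReactionNetwork` object.
#' @export
C13ReactionNetwork <- function(network, transitions, feed = list(),
                               measurements = list(), validate = TRUE) {
  obj <- new("C13ReactionNetwork", metabolites = network@metabolites,
             reactions = network@reactions, transitions = transitions,
             feed = feed, measurements = measurements)
  for (m in names(feed)) {
    f <- feed[[m]]
    if (abs(sum(f$fraction) - 1) > 1e-6)
      emufluxError(sprintf("feed fractions for '%s' must sum to 1", m),
                   "validationError")
    nc <- getMetabolite(obj, m)@carbons
    if (any(nchar(f$mask) != nc))
      emufluxError(sprintf(
        "feed mask length for '%s' must equal its %d carbons", m, nc),
        "validationError")
  }
  if (validate) {
    reports <- carbonTransitionsOK(obj)
    if (length(reports))
      emufluxError(paste(c("carbon transition inconsistencies:", reports),
                         collapse = "\n  "), "carbonBalanceError")
  }
  obj
}

#' Check carbon transitions against the reaction network
#'
#' Verifies, reaction by reaction, that the atom transitions name exactly the
#' reaction's carbon-bearing reactants and products, that pattern lengths match
#' metabolite carbon counts, that carbon is conserved, and that every
#' carbon-bearing non-source metabolite is produced by at least one transition.
#'
#' @param network A [C13ReactionNetwork].
#' @return Character vector of human-readable inconsistency reports; empty if
#'   the network is consistent.
#' @export
carbonTransitionsOK <- function(network) {
  reports <- character(0)
  carbons <- carbonCounts(network)
  byRxn <- split(network@transitions,
                 vapply(network@transitions, function(t) t@reactionId,
                        character(1)))
  for (rid in names(byRxn)) {
    if (!rid %in% reactionIds(network)) {
      reports <- c(reports, sprintf(
        "transition for unknown reaction '%s'", rid))
      next
    }
    rxn <- getReaction(network, rid)
    w <- sum(vapply(byRxn[[rid]], function(t) t@weight, numeric(1)))
    if (abs(w - 1) > 1e-9)
      reports <- c(reports, sprintf(
        "reaction '%s': transition weights sum to %g, not 1", rid, w))
    carbonMets <- function(side) {
      ids <- names(side)
      sort(rep(ids[carbons[ids] > 0], side[carbons[ids] > 0]))
    }
    for (tr in byRxn[[rid]]) {
      reports <- c(reports, checkTransitionPatterns(tr, carbons))
      extraR <- setdiff(tr@reactants$met, names(rxn@reactants))
      extraP <- setdiff(tr@products$met, names(rxn@products))
      if (length(extraR))
        reports <- c(reports, sprintf(
          "reaction '%s': transition reactant '%s' is not a reactant of the reaction",
          rid, extraR))
      if (length(extraP))
        reports <- c(reports, sprintf(
          "reaction '%s': transition product '%s' is not a product of the reaction",
          rid, extraP))
      if (!length(extraR) && !length(extraP) &&
          !setequal(character(0), symdiffMultiset(
            sort(tr@reactants$met[carbons[tr@reactants$met] > 0]),
            carbonMets(rxn@reactants))))
        reports <- c(reports, sprintf(
          "reaction '%s': transition reactant multiplicities differ from the reaction",
          rid))
    }
  }
  produced <- unique(unlist(lapply(network@transitions,
                                   function(t) t@products$met)))
  for (m in network@metabolites) {
    if (m@carbons > 0L && !m@source && !(m@id %in% produced) &&
        producedByAnyReaction(network, m@id))
      reports <- c(reports, sprintf(
        "metabolite '%s' is produced by the stoichiometry but by no carbon transition",
        m@id))
  }
  reports
}

symdiffMultiset <- function(a, b) {
  ta <- table(a); tb <- table(b)
  keys <- union(names(ta), names(tb))
  keys[vapply(keys, function(k)
    (if (k %in% names(ta)) ta[[k]] else 0L) !=
    (if (k %in% names(tb)) tb[[k]] else 0L), logical(1))]
}

producedByAnyReaction <- function(network, mid) {
  any(vapply(network@reactions, function(r) mid %in% names(r@products),
             logical(1)))
}

#' Two-scale network: genome-scale stoichiometry with a carbon-mapped core
#'
#' Pairs a genome-scale [ReactionNetwork] with a core [C13ReactionNetwork]
#' whose reactions carry atom transitions. Labeling is simulated on the core
#' while the full genome-scale stoichiometry constrains all fluxes.
#'
#' @param genomeScale The full stoichiometric network.
#' @param core The carbon-mapped core network.
#' @param coreMap Optional named list mapping a core reaction id to the
#'   genome-scale reaction id(s) it lumps; identity by default.
#' @return A `TwoScaleNetwork` object.
#' @export
TwoScaleNetwork <- function(genomeScale, core, coreMap = list()) {
  new("TwoScaleNetwork", genomeScale = genomeScale, core = core,
      coreMap = coreMap)
}

setMethod("show", "TwoScaleNetwork", function(object) {
  cat(sprintf("TwoScaleNetwork: %d genome-scale reactions, %d core reactions\n",
              length(object@genomeScale@reactions),
              length(object@core@reactions)))
})

#' Flux distribution over a network
#'
#' @param net Named numeric vector of net fluxes (names are reaction ids), or a
#'   named list of [Flux] objects.
#' @param exchange Optional named numeric vector of exchange fluxes (subset of
#'   reactions; zero elsewhere).
#' @param objectiveValue Objective value where applicable.
#' @return A `FluxDistribution` object.
#' @export
FluxDistribution <- function(net, exchange = numeric(0),
                             objectiveValue = NA_real_) {
  if (is.list(net) && all(vapply(net, is, logical(1), "Flux"))) {
    fluxes <- net
  } else {
    fluxes <- lapply(names(net), function(id)
      Flux(net[[id]],
           if (id %in% names(exchange)) exchange[[id]] else 0))
    names(fluxes) <- names(net)
  }
  new("FluxDistribution", fluxes = fluxes,
      objectiveValue = as.numeric(objectiveValue))
}

#' @describeIn FluxDistribution named vector of net fluxes
#' @param x A `FluxDistribution`.
#' @param ... Optional reaction ids to extract.
#' @export
setMethod("netFlux", "FluxDistribution", function(x, ...) {
  v <- vapply(x@fluxes, netFlux, numeric(1))
  ids <- c(...)
  if (length(ids)) v[ids] else v
})

#' @describeIn FluxDistribution named vector of exchange fluxes
#' @export
setMethod("exchangeFlux", "FluxDistribution", function(x, ...) {
  v <- vapply(x@fluxes, exchangeFlux, numeric(1))
  ids <- c(...)
  if (length(ids)) v[ids] else v
})

#' @describeIn FluxDistribution objective value of the underlying optimization
#' @export
setMethod("objectiveValue", "FluxDistribution", function(x) x@objectiveValue)

setMethod("show", "FluxDistribution", function(object) {
  v <- netFlux(object)
  cat(sprintf("FluxDistribution over %d reactions", length(v)))
  if (!is.na(object@objectiveValue))
    cat(sprintf(" (objective %g)", object@objectiveValue))
  cat("\n")
  print(round(v, 6))
})

#' Flux distribution with confidence ranges
#'
#' @param ranges Named list of [RangedNumber] objects keyed by reaction id.
#' @return A `RangedFluxDistribution` object.
#' @export
RangedFluxDistribution <- function(ranges) {
  new("RangedFluxDistribution", ranges = ranges)
}

#' @describeIn RangedFluxDistribution data frame of (reaction, lo, best, hi)
#' @param x A `RangedFluxDistribution`.
#' @export
setMethod("fluxRanges", "RangedFluxDistribution", function(x) {
  data.frame(reaction = names(x@ranges),
             lo = vapply(x@ranges, function(r) r@lo, numeric(1)),
             best = vapply(x@ranges, function(r) r@best, numeric(1)),
             hi = vapply(x@ranges, function(r) r@hi, numeric(1)),
             row.names = NULL)
})

setMethod("show", "RangedFluxDistribution", function(object) {
  cat("RangedFluxDistribution:\n")
  print(fluxRanges(object), digits = 6)
})

#' @describeIn FitResult the fitted flux distribution
#' @param x A `FitResult`.
#' @export
setMethod("fittedFluxes", "FitResult", function(x) x@fluxes)
#' @describeIn FitResult variance-weighted sum of squared residuals
#' @export
setMethod("ssr", "FitResult", function(x) x@ssr)

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: SSR %.6g over %d measurements, %d free fluxes%s%s\n",
    object@ssr, object@nMeasurements, object@nFreeFluxes,
    if (object@converged) ", converged" else ", NOT converged",
    if (object@degenerate) " (degenerate optimum)" else ""))
})
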