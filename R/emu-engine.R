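#' @include reaction-network.R labeling-io.R
NULL

## The EMU engine: backward decomposition of a carbon-transition network into
## the elementary metabolite units needed for a set of target EMUs, and the
## forward simulation of labeling (fluxes -> MDVs). The production path is the
## classic size-partitioned cascade: for each EMU size s the unknown MDVs X_s
## solve the linear system A_s X_s = -B_s, where condensation inputs are
## convolutions of already-solved smaller EMUs and feed EMUs. A fixed-point
## solve of the fully coupled system is kept as an independent path for
## cross-checks.

setClass("EMUNetwork",
  representation(unknowns = "list", feedEMUs = "character",
                 targets = "character"))

setMethod("show", "EMUNetwork", function(object) {
  szs <- vapply(object@unknowns, function(u) emuSize(u$emu), integer(1))
  cat(sprintf("EMUNetwork: %d unknown EMUs (sizes %s), %d feed EMUs\n",
              length(object@unknowns),
              paste(sort(unique(szs)), collapse = ","),
              length(object@feedEMUs)))
})

## per-direction production occurrences: for each metabolite, the list of
## (reaction, direction, weight, product pattern, reactant side) entries that
## produce one molecule of it
productionOccurrences <- function(network) {
  revOf <- structure(vapply(network@reactions, function(r) r@reversible,
                            logical(1)), names = reactionIds(network))
  occ <- list()
  for (tr in network@transitions) {
    dirs <- if (revOf[[tr@reactionId]]) c("forward", "backward") else "forward"
    for (d in dirs) {
      prodSide <- if (d == "forward") tr@products else tr@reactants
      reacSide <- if (d == "forward") tr@reactants else tr@products
      for (i in seq_len(nrow(prodSide))) {
        met <- prodSide$met[i]
        occ[[met]] <- c(occ[[met]], list(list(
          rid = tr@reactionId, dir = d, weight = tr@weight,
          pattern = prodSide$pattern[i], reac = reacSide)))
      }
    }
  }
  occ
}

normalizeTargets <- function(targets) {
  if (is.character(targets)) lapply(targets, emuFromName)
  else if (is(targets, "EMU")) list(targets)
  else targets
}

#' Minimal EMU closure for a set of targets
#'
#' Walks backward from the target EMUs through the atom transitions and
#' returns every EMU whose mass distribution is needed, feed EMUs included as
#' leaves.
#'
#' @param network A [C13ReactionNetwork].
#' @param targets List of [EMU] objects or canonical EMU names.
#' @return Named list of [EMU] objects (names are canonical EMU names).
#' @export
requiredEMUs <- function(network, targets) {
  d <- emuDecompose(network, targets)
  out <- lapply(d@unknowns, `[[`, "emu")
  feeds <- lapply(d@feedEMUs, emuFromName)
  names(feeds) <- d@feedEMUs
  c(out, feeds)[order(names(c(out, feeds)))]
}

#' EMU transitions feeding a set of EMUs
#'
#' @param network A [C13ReactionNetwork].
#' @param emuSet Targets (the returned transitions cover their backward
#'   closure, which must be contained in the network).
#' @return List of [EMUTransition] objects.
#' @export
emuTransitionsFor <- function(network, emuSet) {
  d <- emuDecompose(network, emuSet)
  out <- list()
  for (u in d@unknowns)
    for (ro in u$routes)
      out[[length(out) + 1L]] <- EMUTransition(ro$rid, ro$dir, ro$sources,
                                               u$emu, weight = ro$weight)
  out
}

#' Decompose a network into the EMU system for given targets
#'
#' @param network A [C13ReactionNetwork].
#' @param targets Target EMUs (objects or names).
#' @return An `EMUNetwork` object holding, for every unknown EMU, its
#'   producing routes (source EMUs, reaction, direction, weight).
#' @export
emuDecompose <- function(network, targets) {
  targets <- normalizeTargets(targets)
  carbons <- carbonCounts(network)
  sourceOf <- structure(vapply(network@metabolites, function(m) m@source,
                               logical(1)), names = metaboliteIds(network))
  for (e in targets) {
    if (!e@metaboliteId %in% names(carbons))
      emufluxError(sprintf("target EMU names unknown metabolite '%s'",
                           e@metaboliteId), "lookupError")
    if (max(e@indices) > carbons[[e@metaboliteId]])
      emufluxError(sprintf("EMU '%s' exceeds the %d carbons of '%s'",
                           emuName(e), carbons[[e@metaboliteId]],
                           e@metaboliteId), "validationError")
  }
  occ <- productionOccurrences(network)
  unknowns <- list()
  feedEMUs <- character(0)
  queue <- targets
  while (length(queue)) {
    e <- queue[[1]]; queue <- queue[-1]
    nm <- emuName(e)
    if (sourceOf[[e@metaboliteId]]) {
      feedEMUs <- union(feedEMUs, nm)
      next
    }
    if (nm %in% names(unknowns)) next
    prodOcc <- occ[[e@metaboliteId]]
    if (is.null(prodOcc))
      emufluxError(sprintf(
        "EMU '%s': metabolite '%s' is produced by no carbon transition",
        nm, e@metaboliteId), "carbonBalanceError")
    routes <- lapply(prodOcc, function(o) {
      letters <- strsplit(o$pattern, "")[[1]][e@indices]
      sources <- list()
      for (j in seq_len(nrow(o$reac))) {
        sp <- strsplit(o$reac$pattern[j], "")[[1]]
        J <- which(sp %in% letters)
        if (length(J))
          sources[[length(sources) + 1L]] <- EMU(o$reac$met[j], J)
      }
      list(rid = o$rid, dir = o$dir, weight = o$weight, sources = sources,
           sourceNames = vapply(sources, emuName, character(1)))
    })
    unknowns[[nm]] <- list(emu = e, routes = routes)
    for (ro in routes) queue <- c(queue, ro$sources)
  }
  szs <- vapply(unknowns, function(u) emuSize(u$emu), integer(1))
  if (length(unknowns))
    unknowns <- unknowns[order(szs, names(unknowns))]
  new("EMUNetwork", unknowns = unknowns,
      feedEMUs = feedEMUs,
      targets = vapply(targets, emuName, character(1)))
}

## MDV of an EMU of a feed metabolite: positional, so correlations between
## carbons of one source molecule are preserved
feedEMUMDV <- function(feed, emu) {
  spec <- feed[[emu@metaboliteId]]
  if (is.null(spec))
    emufluxError(sprintf("no feed labeling specified for source '%s'",
                         emu@metaboliteId), "validationError")
  out <- numeric(length(emu@indices) + 1L)
  for (i in seq_len(nrow(spec))) {
    bits <- as.integer(strsplit(spec$mask[i], "")[[1]])
    m <- sum(bits[emu@indices])
    out[m + 1L] <- out[m + 1L] + spec$fraction[i]
  }
  out / sum(out)
}

directionalFluxes <- function(network, fluxes) {
  rids <- reactionIds(network)
  missing <- setdiff(rids, names(fluxes@fluxes))
  if (length(missing))
    emufluxError(paste("no flux given for reaction(s):",
                       paste(missing, collapse = ", ")), "validationError")
  list(forward = vapply(fluxes@fluxes[rids], forwardFlux, numeric(1)),
       backward = vapply(fluxes@fluxes[rids], backwardFlux, numeric(1)))
}

checkBalanced <- function(network, fluxes, tol = 1e-6) {
  S <- stoichiometricMatrix(network)
  if (nrow(S) == 0L) return(invisible(0))
  v <- netFlux(fluxes)[colnames(S)]
  imbalance <- max(abs(S %*% v))
  if (imbalance > tol)
    emufluxError(sprintf(
      "fluxes violate steady state: max |S v| = %.3g (tolerance %.1g)",
      imbalance, tol), "validationError")
  invisible(imbalance)
}

#' Flux-linear EMU balance matrices for one size
#'
#' Exposes the `A_s`, `B_s` pair of the size-`s` EMU balance system
#' `A_s X_s = -B_s` at a given flux distribution: diagonal entries of `A_s`
#' are negative total production rates, off-diagonals carry same-size transfer
#' fluxes, and `B_s` accumulates the flux-weighted known inputs (feed EMUs and
#' convolutions of smaller solved EMUs).
#'
#' @param decomp An `EMUNetwork` from [emuDecompose()].
#' @param network The [C13ReactionNetwork].
#' @param fluxes A [FluxDistribution].
#' @param size EMU size `s`.
#' @return List with `A` (n x n), `B` (n x (s+1)), and `emus` (row names).
#' @export
emuMatrices <- function(decomp, network, fluxes, size) {
  solved <- solveCascade(decomp, network, fluxes, upToSize = size)
  lvl <- solved$systems[[as.character(size)]]
  if (is.null(lvl))
    emufluxError(sprintf("no unknown EMUs of size %d", size),
                 "validationError")
  lvl
}

#' Simulate steady-state labeling from fluxes
#'
#' Solves the EMU balance systems size by size and returns the mass
#' distribution vectors of the target EMUs. The result depends only on flux
#' ratios, is independent of EMU ordering, and each MDV is normalized.
#' Feed carbon is used exactly as specified (no natural-abundance envelope is
#' added here; measured-data correction lives in [correctMDV()]).
#'
#' @param network A [C13ReactionNetwork] with feed labeling for every source.
#' @param fluxes A [FluxDistribution] satisfying `S v = 0` within `tol`.
#' @param targets Target EMUs (objects or canonical names). Defaults to the
#'   EMUs of the network's measured fragments.
#' @param decomp Optional precomputed [emuDecompose()] result (reused across
#'   many flux evaluations during fitting).
#' @param method `"cascade"` (size-partitioned, the production path) or
#'   `"coupled"` (fixed-point solve of the full coupled system, kept as an
#'   independent cross-check).
#' @param tol Steady-state tolerance on `max |S v|`.
#' @return Named list of [MDV] objects keyed by canonical EMU name.
#' @export
simulateLabeling <- function(network, fluxes, targets = NULL, decomp = NULL,
                             method = c("cascade", "coupled"), tol = 1e-6) {
  method <- match.arg(method)
  if (is.null(targets)) {
    if (!length(network@measurements))
      emufluxError("no targets given and no measured fragments present",
                   "validationError")
    targets <- lapply(network@measurements,
                      function(m) fragmentEMU(m$fragment))
  }
  targets <- normalizeTargets(targets)
  checkBalanced(network, fluxes, tol)
  if (is.null(decomp)) decomp <- emuDecompose(network, targets)
  known <- if (method == "cascade")
    solveCascade(decomp, network, fluxes)$known
  else
    solveCoupled(decomp, network, fluxes)
  out <- lapply(targets, function(e) {
    nm <- emuName(e)
    v <- known[[nm]]
    if (is.null(v)) v <- feedEMUMDV(network@feed, e)
    MDV(v)
  })
  names(out) <- vapply(targets, emuName, character(1))
  out
}

solveCascade <- function(decomp, network, fluxes, upToSize = Inf) {
  dir <- directionalFluxes(network, fluxes)
  known <- list()
  for (nm in decomp@feedEMUs)
    known[[nm]] <- feedEMUMDV(network@feed, emuFromName(nm))
  szs <- vapply(decomp@unknowns, function(u) emuSize(u$emu), integer(1))
  systems <- list()
  for (s in sort(unique(szs))) {
    if (s > upToSize) break
    us <- decomp@unknowns[szs == s]
    n <- length(us)
    nms <- names(us)
    A <- matrix(0, n, n, dimnames = list(nms, nms))
    B <- matrix(0, n, s + 1L)
    for (i in seq_len(n)) {
      for (ro in us[[i]]$routes) {
        phi <- dir[[if (ro$dir == "forward") "forward" else "backward"]][[ro$rid]] *
          ro$weight
        if (phi <= 0) next
        A[i, i] <- A[i, i] - phi
        if (length(ro$sources) == 1L && ro$sourceNames %in% nms) {
          A[i, ro$sourceNames] <- A[i, ro$sourceNames] + phi
        } else {
          y <- Reduce(convolveRaw, lapply(ro$sourceNames, function(sn) {
            v <- known[[sn]]
            if (is.null(v)) v <- feedEMUMDV(network@feed, emuFromName(sn))
            v
          }))
          B[i, ] <- B[i, ] + phi * y
        }
      }
      if (A[i, i] >= -1e-12)
        emufluxError(sprintf(
          "EMU '%s' has zero throughput at these fluxes (singular EMU system)",
          nms[i]), "singularEMUSystem")
    }
    X <- tryCatch(solve(A, -B), error = function(e)
      emufluxError(sprintf("singular EMU system at size %d: %s", s,
                           conditionMessage(e)), "singularEMUSystem"))
    for (i in seq_len(n)) {
      xi <- X[i, ]
      known[[nms[i]]] <- xi / sum(xi)
    }
    systems[[as.character(s)]] <- list(A = A, B = B, emus = nms)
  }
  list(known = known, systems = systems)
}

solveCoupled <- function(decomp, network, fluxes, maxIter = 50000,
                         tol = 1e-14) {
  dir <- directionalFluxes(network, fluxes)
  known <- list()
  for (nm in decomp@feedEMUs)
    known[[nm]] <- feedEMUMDV(network@feed, emuFromName(nm))
  for (u in decomp@unknowns)
    known[[emuName(u$emu)]] <- c(1, numeric(emuSize(u$emu)))
  for (iter in seq_len(maxIter)) {
    delta <- 0
    for (u in decomp@unknowns) {
      nm <- emuName(u$emu)
      acc <- numeric(emuSize(u$emu) + 1L)
      tot <- 0
      for (ro in u$routes) {
        phi <- dir[[ro$dir]][[ro$rid]] * ro$weight
        if (phi <= 0) next
        y <- Reduce(convolveRaw, lapply(ro$sourceNames,
                                        function(sn) known[[sn]]))
        acc <- acc + phi * y
        tot <- tot + phi
      }
      if (tot <= 0)
        emufluxError(sprintf(
          "EMU '%s' has zero throughput at these fluxes (singular EMU system)",
          nm), "singularEMUSystem")
      newv <- acc / tot
      delta <- max(delta, max(abs(newv - known[[nm]])))
      known[[nm]] <- newv
    }
    if (delta < tol) break
  }
  known
}
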