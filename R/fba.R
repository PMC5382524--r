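#' @include lp.R reaction-network.R
NULL

#' Flux balance analysis
#'
#' Maximizes the network objective over the steady-state flux polytope
#' `{v : S v = 0, lb <= v <= ub}` by linear programming.
#'
#' @param network A [ReactionNetwork].
#' @param objective Optional named numeric vector of objective coefficients;
#'   defaults to the coefficients stored on the reactions.
#' @return A [FluxDistribution] with `objectiveValue` set to the optimum.
#' @examples
#' net <- chainToyNetwork()
#' objectiveValue(fba(net))  # 10: uptake-limited
#' @export
fba <- function(network, objective = NULL) {
  rids <- reactionIds(network)
  obj <- numeric(length(rids)); names(obj) <- rids
  oc <- objectiveCoefficients(network)
  obj[names(oc)] <- oc
  if (!is.null(objective)) {
    obj[] <- 0
    obj[names(objective)] <- objective
  }
  if (all(obj == 0))
    emufluxError("no objective coefficient set", "validationError")
  S <- stoichiometricMatrix(network)
  bounds <- fluxBounds(network)
  res <- solveLP(unname(obj), Aeq = S, beq = numeric(nrow(S)),
                 lb = unname(bounds$lb), ub = unname(bounds$ub),
                 maximize = TRUE)
  if (res$status != "optimal")
    emufluxError(sprintf("FBA problem is %s", res$status),
                 paste0(res$status, "LP"))
  v <- structure(res$x, names = rids)
  FluxDistribution(v, objectiveValue = res$objective)
}

#' Flux variability analysis
#'
#' For every reaction, the minimum and maximum flux subject to the objective
#' staying within `fraction` of its FBA optimum.
#'
#' @param network A [ReactionNetwork].
#' @param objective Optional objective override (see [fba()]).
#' @param fraction Required fraction of the optimal objective, in `[0, 1]`.
#' @return A [RangedFluxDistribution]; `best` is the FBA solution, which every
#'   range contains.
#' @export
fva <- function(network, objective = NULL, fraction = 1.0) {
  sol <- fba(network, objective)
  rids <- reactionIds(network)
  obj <- numeric(length(rids)); names(obj) <- rids
  oc <- objectiveCoefficients(network)
  obj[names(oc)] <- oc
  if (!is.null(objective)) {
    obj[] <- 0
    obj[names(objective)] <- objective
  }
  S <- stoichiometricMatrix(network)
  bounds <- fluxBounds(network)
  ## objective >= fraction * optimum as -obj . v <= -fraction * opt
  Aineq <- matrix(-obj, nrow = 1)
  bineq <- -fraction * sol@objectiveValue
  best <- netFlux(sol)
  ranges <- lapply(rids, function(r) {
    e <- numeric(length(rids)); e[match(r, rids)] <- 1
    lohi <- vapply(c(FALSE, TRUE), function(maxit) {
      res <- solveLP(e, Aeq = S, beq = numeric(nrow(S)),
                     lb = unname(bounds$lb), ub = unname(bounds$ub),
                     Aineq = Aineq, bineq = bineq, maximize = maxit)
      if (res$status != "optimal")
        emufluxError(sprintf("FVA subproblem for '%s' is %s", r, res$status),
                     paste0(res$status, "LP"))
      res$objective
    }, numeric(1))
    RangedNumber(min(lohi[1], best[[r]]), best[[r]], max(lohi[2], best[[r]]))
  })
  names(ranges) <- rids
  RangedFluxDistribution(ranges)
}
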