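#' @include fba.R
NULL

## Knockout phenotype prediction against a reference flux distribution.
## MoMA: minimal Euclidean flux adjustment, a strictly convex QP solved with
## quadprog. ROOM: minimal number of significantly changed fluxes, a small
## mixed-integer program solved by branch-and-bound over the binary change
## indicators with LP relaxations.

koMatrices <- function(network, ko) {
  rids <- reactionIds(network)
  bad <- setdiff(ko, rids)
  if (length(bad))
    emufluxError(paste("unknown knockout reaction(s):",
                       paste(bad, collapse = ", ")), "lookupError")
  S <- stoichiometricMatrix(network)
  E <- matrix(0, length(ko), length(rids), dimnames = list(ko, rids))
  E[cbind(ko, ko)] <- 1
  list(S = S, E = E, rids = rids, bounds = fluxBounds(network))
}

#' Minimization of metabolic adjustment (MoMA)
#'
#' Predicts the flux state after a reaction knockout as the feasible flux
#' vector closest (in Euclidean distance) to the reference state: minimize
#' `sum((v - v_ref)^2)` subject to `S v = 0`, the bounds, and `v = 0` on the
#' knocked-out reactions.
#'
#' @param network A [ReactionNetwork].
#' @param reference The reference [FluxDistribution] (e.g. an FBA or 13C MFA
#'   solution of the unmodified network).
#' @param ko Character vector of reaction ids forced to zero (may be empty, in
#'   which case the reference is returned unchanged).
#' @return A [FluxDistribution]; its `objectiveValue` is the squared distance
#'   to the reference. An infeasible knockout raises a condition of class
#'   `"lethalKnockout"`.
#' @export
moma <- function(network, reference, ko = character(0)) {
  m <- koMatrices(network, ko)
  ref <- netFlux(reference)[m$rids]
  n <- length(m$rids)
  Aeq <- rbind(m$S, m$E)
  Amat <- t(rbind(Aeq, diag(n), -diag(n)))
  bvec <- c(numeric(nrow(Aeq)), m$bounds$lb, -m$bounds$ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = ref, Amat = Amat, bvec = bvec,
                       meq = nrow(Aeq)),
    error = function(e)
      emufluxError(sprintf("knockout {%s} is lethal: %s",
                           paste(ko, collapse = ", "), conditionMessage(e)),
                   "lethalKnockout"))
  v <- structure(sol$solution, names = m$rids)
  v[abs(v) < 1e-10] <- 0
  FluxDistribution(v, objectiveValue = sum((v - ref)^2))
}

#' Regulatory on/off minimization (ROOM)
#'
#' Predicts the post-knockout flux state minimizing the number of reactions
#' whose flux changes significantly relative to the reference: reaction `r`
#' counts as changed when `v_r` leaves
#' `[v_ref - delta |v_ref| - epsilon, v_ref + delta |v_ref| + epsilon]`.
#' Solved exactly as a mixed-integer program by branch-and-bound with big-M
#' constraints from the flux bounds.
#'
#' @param network A [ReactionNetwork].
#' @param reference Reference [FluxDistribution].
#' @param ko Reaction ids forced to zero.
#' @param delta Relative significance threshold (default 0.03).
#' @param epsilon Absolute significance threshold (default 0.001).
#' @param maxNodes Node budget for the branch-and-bound search; if exhausted
#'   the best incumbent is returned with `optimal = FALSE`.
#' @return List with `fluxes` (a [FluxDistribution]), `nChanged` (number of
#'   significantly changed reactions) and `optimal` (logical). An infeasible
#'   knockout raises `"lethalKnockout"`.
#' @export
room <- function(network, reference, ko = character(0), delta = 0.03,
                 epsilon = 0.001, maxNodes = 10000) {
  m <- koMatrices(network, ko)
  ref <- netFlux(reference)[m$rids]
  n <- length(m$rids)
  wu <- ref + delta * abs(ref) + epsilon
  wl <- ref - delta * abs(ref) - epsilon
  lb <- m$bounds$lb; ub <- m$bounds$ub
  ## variables x = (v, y); constraints:
  ##   v - y (ub - wu) <= wu   (y=1 relaxes the upper window to ub)
  ##   -v - y (wl - lb) <= -wl (y=1 relaxes the lower window to lb)
  A1 <- cbind(diag(n), diag(-(ub - wu)))
  A2 <- cbind(-diag(n), diag(lb - wl))
  Aineq <- rbind(A1, A2)
  bineq <- c(wu, -wl)
  Aeq <- cbind(rbind(m$S, m$E), matrix(0, nrow(m$S) + nrow(m$E), n))
  beq <- numeric(nrow(Aeq))
  obj <- c(numeric(n), rep(1, n))
  lbx <- c(lb, numeric(n))
  ubx <- c(ub, rep(1, n))
  relax <- function(fix0, fix1) {
    l <- lbx; u <- ubx
    l[n + fix1] <- 1; u[n + fix0] <- 0
    solveLP(obj, Aeq = Aeq, beq = beq, lb = l, ub = u,
            Aineq = Aineq, bineq = bineq)
  }
  root <- relax(integer(0), integer(0))
  if (root$status != "optimal")
    emufluxError(sprintf("knockout {%s} is lethal", paste(ko, collapse = ", ")),
                 "lethalKnockout")
  bestObj <- Inf; bestX <- NULL; nodes <- 0; optimal <- TRUE
  stack <- list(list(fix0 = integer(0), fix1 = integer(0)))
  while (length(stack)) {
    nodes <- nodes + 1
    if (nodes > maxNodes) { optimal <- FALSE; break }
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    res <- relax(nd$fix0, nd$fix1)
    if (res$status != "optimal") next
    if (res$objective >= bestObj - 1e-6) next
    y <- res$x[n + seq_len(n)]
    frac <- which(y > 1e-6 & y < 1 - 1e-6)
    if (!length(frac)) {
      bestObj <- res$objective
      bestX <- res$x
      next
    }
    j <- frac[which.min(abs(y[frac] - 0.5))]
    stack[[length(stack) + 1L]] <- list(fix0 = c(nd$fix0, j), fix1 = nd$fix1)
    stack[[length(stack) + 1L]] <- list(fix0 = nd$fix0, fix1 = c(nd$fix1, j))
  }
  if (is.null(bestX))
    emufluxError(sprintf("knockout {%s} is lethal", paste(ko, collapse = ", ")),
                 "lethalKnockout")
  v <- structure(bestX[seq_len(n)], names = m$rids)
  v[abs(v) < 1e-10] <- 0
  changed <- sum(v > wu + 1e-6 | v < wl - 1e-6)
  list(fluxes = FluxDistribution(v), nChanged = changed, optimal = optimal)
}
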