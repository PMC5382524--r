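#' @include emu-engine.R fba.R
NULL

## 13C MFA fitting. Free parameters are the null-space coordinates of the
## stoichiometric equality system (S v = 0 plus any bounds with lb == ub)
## together with one exchange flux per reversible reaction. The
## variance-weighted least-squares problem is solved by Levenberg-Marquardt
## (minpack.lm) with hinge-penalty residuals keeping net fluxes inside their
## bounds, restarted from uniform samples of the flux polytope.

BOUND_PENALTY <- 1e3

pinvSolve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, 1)
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
}

## assemble the fitting context shared by c13Fit / c13FVA / elva
c13Context <- function(network, exchangeBound = 100, fixedExchange = numeric(0),
                       fluxNetwork = NULL, coreMap = list(),
                       extraEq = NULL, extraBeq = NULL) {
  fnet <- fluxNetwork %||% network
  S <- stoichiometricMatrix(fnet)
  rids <- reactionIds(fnet)
  bounds <- fluxBounds(fnet)
  lb <- unname(bounds$lb); ub <- unname(bounds$ub)
  fixed <- which(ub - lb < 1e-9)
  Aeq <- S
  beq <- numeric(nrow(S))
  if (length(fixed)) {
    E <- matrix(0, length(fixed), length(rids))
    E[cbind(seq_along(fixed), fixed)] <- 1
    Aeq <- rbind(Aeq, E)
    beq <- c(beq, lb[fixed])
  }
  if (!is.null(extraEq)) {
    Aeq <- rbind(Aeq, extraEq)
    beq <- c(beq, extraBeq)
  }
  v0 <- as.numeric(pinvSolve(Aeq, beq))
  if (max(abs(Aeq %*% v0 - beq)) > 1e-6)
    emufluxError("no flux vector satisfies the balance and fixed-bound equalities",
                 "infeasibleStatus")
  N <- nullSpace(Aeq)
  coreRev <- vapply(reactions(network), function(r) r@reversible, logical(1))
  revIds <- setdiff(reactionIds(network)[coreRev], names(fixedExchange))
  meas <- network@measurements
  if (!length(meas))
    emufluxError("network carries no labeling measurements", "validationError")
  targets <- lapply(meas, function(m) fragmentEMU(m$fragment))
  decomp <- emuDecompose(network, targets)
  obs <- unname(unlist(lapply(meas, function(m) fractions(m$mdv))))
  sds <- unname(unlist(lapply(meas, function(m) {
    e <- mdvErrors(m$mdv)
    if (!length(e)) rep(0.003, length(fractions(m$mdv))) else e
  })))
  list(network = network, fluxRids = rids, lb = lb, ub = ub, v0 = v0, N = N,
       nNet = ncol(N), revIds = revIds, exchangeBound = exchangeBound,
       fixedExchange = fixedExchange, coreMap = coreMap,
       targets = decomp@targets, decomp = decomp, obs = obs, sds = sds)
}

ctxNetFluxes <- function(ctx, thetaNet) {
  v <- ctx$v0
  if (ctx$nNet) v <- v + as.numeric(ctx$N %*% thetaNet)
  structure(v, names = ctx$fluxRids)
}

## map genome-scale fluxes onto the carbon-mapped (core) network
ctxCoreFluxes <- function(ctx, vfull, exch) {
  coreIds <- reactionIds(ctx$network)
  vcore <- vapply(coreIds, function(id) {
    gsIds <- if (id %in% names(ctx$coreMap)) ctx$coreMap[[id]] else id
    sum(vfull[gsIds])
  }, numeric(1))
  exchange <- numeric(length(coreIds)); names(exchange) <- coreIds
  exchange[ctx$revIds] <- exch
  fe <- ctx$fixedExchange
  exchange[names(fe)] <- fe
  FluxDistribution(vcore, exchange = exchange)
}

ctxResiduals <- function(ctx, theta, penalty = TRUE) {
  thetaNet <- theta[seq_len(ctx$nNet)]
  exch <- theta[ctx$nNet + seq_along(ctx$revIds)]
  vfull <- ctxNetFluxes(ctx, thetaNet)
  fd <- ctxCoreFluxes(ctx, vfull, exch)
  pred <- tryCatch({
    sim <- simulateLabeling(ctx$network, fd, targets = ctx$targets,
                            decomp = ctx$decomp, tol = Inf)
    unname(unlist(lapply(sim, fractions)))
  }, error = function(e) NULL)
  if (is.null(pred))
    return(rep(1e3, length(ctx$obs) + if (penalty) length(vfull) else 0))
  r <- (ctx$obs - pred) / ctx$sds
  if (penalty) {
    viol <- pmax(0, ctx$lb - vfull, vfull - ctx$ub)
    r <- c(r, BOUND_PENALTY * viol)
  }
  r
}

ctxSSR <- function(ctx, theta) {
  r <- ctxResiduals(ctx, theta, penalty = FALSE)
  viol <- any(pmax(0, ctx$lb - ctxNetFluxes(ctx, theta[seq_len(ctx$nNet)]),
                   ctxNetFluxes(ctx, theta[seq_len(ctx$nNet)]) - ctx$ub) > 1e-6)
  sum(r^2) + if (viol) 1e6 else 0
}

## interior point of {theta : lb <= v0 + N theta <= ub} by slack maximization;
## falls back to theta = 0 when the particular solution already sits inside
ctxInteriorPoint <- function(ctx) {
  k <- ctx$nNet
  if (!k) return(numeric(0))
  v0ok <- all(ctx$v0 >= ctx$lb - 1e-9 & ctx$v0 <= ctx$ub + 1e-9)
  ## variables (theta, t): maximize t s.t. -N theta + t <= v0 - lb,
  ##                                      N theta + t <= ub - v0, t <= tmax
  tmax <- max(1, (max(ctx$ub[is.finite(ctx$ub)]) - min(ctx$lb)) / 2)
  box <- 2 * sum(pmin(ctx$ub, 1e4) - pmax(ctx$lb, -1e4))
  A <- rbind(cbind(-ctx$N, 1), cbind(ctx$N, 1), c(numeric(k), 1))
  b <- c(ctx$v0 - ctx$lb, ctx$ub - ctx$v0, tmax)
  res <- solveLP(c(numeric(k), 1), lb = c(rep(-box, k), 0),
                 ub = c(rep(box, k), tmax), Aineq = A, bineq = b,
                 maximize = TRUE)
  if (res$status != "optimal" || res$x[k + 1] <= 0) {
    if (v0ok) return(numeric(k))
    emufluxError("flux polytope has an empty interior", "infeasibleStatus")
  }
  res$x[seq_len(k)]
}

## hit-and-run samples over the net-flux polytope plus uniform exchange draws
ctxSampleStarts <- function(ctx, nStarts, seed) {
  set.seed(seed)
  k <- ctx$nNet
  m <- length(ctx$revIds)
  theta <- if (k) ctxInteriorPoint(ctx) else numeric(0)
  starts <- vector("list", nStarts)
  for (s in seq_len(nStarts)) {
    if (k) {
      for (step in seq_len(10 * k)) {
        d <- stats::rnorm(k); d <- d / sqrt(sum(d^2))
        Nd <- as.numeric(ctx$N %*% d)
        slackUp <- ctx$ub - ctxNetFluxes(ctx, theta)
        slackDn <- ctxNetFluxes(ctx, theta) - ctx$lb
        aHi <- suppressWarnings(min(ifelse(Nd > 1e-12, slackUp / Nd, Inf),
                                    ifelse(Nd < -1e-12, -slackDn / Nd, Inf)))
        aLo <- suppressWarnings(max(ifelse(Nd > 1e-12, -slackDn / Nd, -Inf),
                                    ifelse(Nd < -1e-12, slackUp / Nd, -Inf)))
        if (is.finite(aHi) && is.finite(aLo) && aHi > aLo)
          theta <- theta + stats::runif(1, aLo, aHi) * d
      }
    }
    starts[[s]] <- c(theta, stats::runif(m, 0, ctx$exchangeBound))
  }
  starts
}

ctxSingleFit <- function(ctx, start, maxiter = 300) {
  k <- ctx$nNet; m <- length(ctx$revIds)
  lower <- c(rep(-Inf, k), rep(0, m))
  upper <- c(rep(Inf, k), rep(ctx$exchangeBound, m))
  if (k + m == 0L) {
    r <- ctxResiduals(ctx, numeric(0), penalty = FALSE)
    return(list(theta = numeric(0), ssr = sum(r^2), converged = TRUE))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) ctxResiduals(ctx, p),
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-15, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(theta = start, ssr = ctxSSR(ctx, start), converged = FALSE))
  list(theta = as.numeric(fit$par), ssr = ctxSSR(ctx, as.numeric(fit$par)),
       converged = fit$info %in% 1:4)
}

buildFitResult <- function(ctx, best, restarts, degenerate) {
  thetaNet <- best$theta[seq_len(ctx$nNet)]
  exch <- best$theta[ctx$nNet + seq_along(ctx$revIds)]
  vfull <- ctxNetFluxes(ctx, thetaNet)
  fd <- ctxCoreFluxes(ctx, vfull, exch)
  resid <- ctxResiduals(ctx, best$theta, penalty = FALSE)
  new("FitResult", fluxes = fd, ssr = sum(resid^2), residuals = resid,
      nMeasurements = length(resid),
      nFreeFluxes = as.integer(ctx$nNet + length(ctx$revIds)),
      converged = best$converged, restartsUsed = as.integer(restarts),
      degenerate = degenerate, freeParameters = as.numeric(best$theta),
      context = list(ctx = ctx, vfull = vfull))
}

#' Fit fluxes to 13C labeling measurements
#'
#' Minimizes the variance-weighted sum of squared residuals between measured
#' and simulated mass distribution vectors over the balanced, bounded flux
#' space. Free parameters are the null-space coordinates of `S v = 0` (with
#' `lb == ub` bounds treated as equalities) plus one exchange flux per
#' reversible reaction, bounded by `exchangeBound`. The optimizer restarts
#' from `nStarts` uniform samples of the flux polytope; the best SSR wins, and
#' the fit is flagged degenerate when two restarts reach the same SSR with
#' fluxes differing by more than 1e-3.
#'
#' @param network A [C13ReactionNetwork] with feed and measurements.
#' @param nStarts Number of multistart restarts (default 10).
#' @param seed Seed for the restart sampler (default 0).
#' @param exchangeBound Upper bound on fitted exchange fluxes (default 100).
#' @param fixedExchange Named numeric vector of exchange fluxes to hold fixed
#'   instead of fitting (e.g. for fully determined demonstration scenarios).
#' @return A [FitResult].
#' @export
c13Fit <- function(network, nStarts = 10, seed = 0, exchangeBound = 100,
                   fixedExchange = numeric(0)) {
  ctx <- c13Context(network, exchangeBound, fixedExchange)
  starts <- ctxSampleStarts(ctx, nStarts, seed)
  fits <- lapply(starts, function(s) ctxSingleFit(ctx, s))
  ssrs <- vapply(fits, `[[`, numeric(1), "ssr")
  best <- fits[[which.min(ssrs)]]
  if (!any(vapply(fits, `[[`, logical(1), "converged")))
    best$converged <- FALSE
  nearBest <- fits[ssrs <= best$ssr + 1e-9]
  degenerate <- FALSE
  if (length(nearBest) > 1L) {
    vs <- vapply(nearBest, function(f)
      ctxNetFluxes(ctx, f$theta[seq_len(ctx$nNet)]), numeric(length(ctx$v0)))
    degenerate <- any(apply(vs, 1, function(r) diff(range(r))) > 1e-3)
  }
  buildFitResult(ctx, best, nStarts, degenerate)
}

#' Profile-likelihood confidence intervals for fitted fluxes (13C FVA)
#'
#' For every reaction, the smallest and largest net flux whose profile SSR
#' (the SSR re-minimized with that flux pinned) stays within
#' `qchisq(confidence, df = 1)` of the best fit — the flux values compatible
#' with the experimental data.
#'
#' @param network The fitted [C13ReactionNetwork].
#' @param fit A converged [FitResult] from [c13Fit()].
#' @param confidence Confidence level (default 0.95).
#' @param reactions Reaction ids to profile (default: all).
#' @param tol Absolute bisection tolerance on the interval endpoints.
#' @return A [RangedFluxDistribution] whose `best` values are the fitted
#'   fluxes; every interval contains its best fit.
#' @export
c13FVA <- function(network, fit, confidence = 0.95, reactions = NULL,
                   tol = 1e-4) {
  ctx <- fit@context$ctx
  if (is.null(ctx))
    emufluxError("fit carries no context; refit with c13Fit()",
                 "validationError")
  threshold <- fit@ssr + stats::qchisq(confidence, df = 1)
  rids <- reactions %||% ctx$fluxRids
  vhat <- fit@context$vfull
  S <- NULL
  profileSSR <- function(r, t) {
    e <- numeric(length(ctx$fluxRids))
    e[match(r, ctx$fluxRids)] <- 1
    pc <- tryCatch(
      c13Context(ctx$network, ctx$exchangeBound, ctx$fixedExchange,
                 fluxNetwork = fit@context$fluxNetwork %||% ctx$network,
                 coreMap = ctx$coreMap,
                 extraEq = matrix(e, nrow = 1), extraBeq = t),
      error = function(e2) NULL)
    if (is.null(pc)) return(Inf)
    ## warm start: project the best-fit fluxes onto the pinned space
    thetaNet <- if (pc$nNet)
      as.numeric(pinvSolve(pc$N, vhat - pc$v0)) else numeric(0)
    start <- c(thetaNet,
               fit@freeParameters[ctx$nNet + seq_along(ctx$revIds)])
    ctxSingleFit(pc, start, maxiter = 150)$ssr
  }
  bounds <- list(lb = ctx$lb, ub = ctx$ub)
  Seq <- stoichiometricMatrix(fit@context$fluxNetwork %||% ctx$network)
  ranges <- lapply(rids, function(r) {
    i <- match(r, ctx$fluxRids)
    ## stoichiometrically attainable range of v_r
    e <- numeric(length(ctx$fluxRids)); e[i] <- 1
    lims <- vapply(c(FALSE, TRUE), function(maxit) {
      res <- solveLP(e, Aeq = Seq, beq = numeric(nrow(Seq)),
                     lb = bounds$lb, ub = bounds$ub, maximize = maxit)
      if (res$status != "optimal") vhat[i] else res$objective
    }, numeric(1))
    searchEdge <- function(far) {
      if (abs(far - vhat[i]) < tol) return(vhat[i])
      if (profileSSR(r, far) <= threshold) return(far)
      lo <- vhat[i]; hi <- far
      while (abs(hi - lo) > tol) {
        mid <- (lo + hi) / 2
        if (profileSSR(r, mid) <= threshold) lo <- mid else hi <- mid
      }
      lo
    }
    lo <- min(searchEdge(lims[1]), vhat[i])
    hi <- max(searchEdge(lims[2]), vhat[i])
    RangedNumber(lo, vhat[i], hi)
  })
  names(ranges) <- rids
  RangedFluxDistribution(ranges)
}

#' Two-scale 13C metabolic flux analysis
#'
#' Fits the carbon-mapped core reactions to labeling data exactly as
#' [c13Fit()] does, while the complete genome-scale stoichiometry
#' `S_gs v = 0` (rather than the core's own balances) constrains the flux
#' space — so drains to biomass and other genome-scale routes shift the core
#' boundary exchange consistently. With core = entire network this reduces to
#' plain 13C MFA.
#'
#' @param ts A [TwoScaleNetwork].
#' @param nStarts,seed,exchangeBound,fixedExchange As in [c13Fit()].
#' @return List with `fit` (a [FitResult] over the core reactions) and
#'   `genomeScale` (the consistent genome-scale [FluxDistribution]).
#' @export
twoScaleFit <- function(ts, nStarts = 10, seed = 0, exchangeBound = 100,
                        fixedExchange = numeric(0)) {
  validObject(ts)
  ctx <- c13Context(ts@core, exchangeBound, fixedExchange,
                    fluxNetwork = ts@genomeScale, coreMap = ts@coreMap)
  starts <- ctxSampleStarts(ctx, nStarts, seed)
  fits <- lapply(starts, function(s) ctxSingleFit(ctx, s))
  ssrs <- vapply(fits, `[[`, numeric(1), "ssr")
  best <- fits[[which.min(ssrs)]]
  res <- buildFitResult(ctx, best, nStarts, FALSE)
  res@context$fluxNetwork <- ts@genomeScale
  gs <- FluxDistribution(structure(res@context$vfull,
                                   names = reactionIds(ts@genomeScale)))
  list(fit = res, genomeScale = gs)
}

#' External labeling variability analysis (ELVA)
#'
#' Attainable range of each mass fraction of the queried EMUs over the flux
#' vectors whose SSR stays within the chi-squared band of a converged fit —
#' how tightly the measurements pin the labeling of metabolites that were not
#' themselves measured. The region is explored by directional boundary
#' search from the best fit (random directions, bisection to the SSR
#' threshold), so the reported ranges are inner approximations.
#'
#' @param network The fitted [C13ReactionNetwork].
#' @param fit A converged [FitResult].
#' @param emus EMUs (objects or canonical names) to query.
#' @param confidence Confidence level defining the SSR band (default 0.95).
#' @param nDirections Number of random search directions (default 64).
#' @param seed Seed for the direction sampler.
#' @return Named list: EMU name -> list of [RangedNumber], one per mass
#'   fraction m0..mn, each within `[0, 1]`.
#' @export
elva <- function(network, fit, emus, confidence = 0.95, nDirections = 64,
                 seed = 0) {
  ctx <- fit@context$ctx
  if (is.null(ctx))
    emufluxError("fit carries no context; refit with c13Fit()",
                 "validationError")
  emus <- normalizeTargets(emus)
  nms <- vapply(emus, emuName, character(1))
  decomp <- emuDecompose(network, emus)
  threshold <- fit@ssr + stats::qchisq(confidence, df = 1)
  evalEMU <- function(theta) {
    vfull <- ctxNetFluxes(ctx, theta[seq_len(ctx$nNet)])
    fd <- ctxCoreFluxes(ctx, vfull, theta[ctx$nNet + seq_along(ctx$revIds)])
    sim <- simulateLabeling(network, fd, targets = emus, decomp = decomp,
                            tol = Inf)
    lapply(sim, fractions)
  }
  set.seed(seed)
  k <- length(fit@freeParameters)
  pts <- list(fit@freeParameters)
  if (k) {
    for (d in seq_len(nDirections)) {
      dir <- stats::rnorm(k); dir <- dir / sqrt(sum(dir^2))
      ## exchange components must stay in [0, exchangeBound]
      okBox <- function(theta) {
        ex <- theta[ctx$nNet + seq_along(ctx$revIds)]
        all(ex >= -1e-12 & ex <= ctx$exchangeBound + 1e-12)
      }
      ok <- function(a) {
        th <- fit@freeParameters + a * dir
        okBox(th) && ctxSSR(ctx, th) <= threshold
      }
      alpha <- 1e-3
      if (!ok(alpha)) alpha <- 0
      while (alpha > 0 && alpha < 1e4 && ok(2 * alpha)) alpha <- 2 * alpha
      lo <- alpha; hi <- 2 * max(alpha, 1e-3)
      for (b in 1:30) {
        mid <- (lo + hi) / 2
        if (ok(mid)) lo <- mid else hi <- mid
      }
      pts[[length(pts) + 1L]] <- fit@freeParameters + lo * dir
      pts[[length(pts) + 1L]] <- fit@freeParameters + 0.5 * lo * dir
    }
  }
  vals <- lapply(pts, evalEMU)
  out <- lapply(seq_along(nms), function(j) {
    bestv <- vals[[1]][[j]]
    lapply(seq_along(bestv), function(mi) {
      all_m <- vapply(vals, function(v) v[[j]][mi], numeric(1))
      RangedNumber(max(0, min(all_m)), bestv[mi], min(1, max(all_m)))
    })
  })
  names(out) <- nms
  out
}

#' Carbon utilization efficiency of a community flux state
#'
#' The fraction of consumed carbon diverted into biomass rather than lost as
#' CO2: `CUE = C_biomass / (C_biomass + C_CO2)`, with the carbon rate of each
#' designated reaction computed as its net flux times the carbon atoms it
#' delivers to excreted products.
#'
#' @param fluxes A [FluxDistribution] or [FitResult].
#' @param network The [ReactionNetwork] providing stoichiometry and carbon
#'   counts.
#' @param biomassReactions,co2Reactions Reaction ids routing carbon to biomass
#'   and to CO2 respectively.
#' @return CUE in `[0, 1]`.
#' @export
communityCUE <- function(fluxes, network, biomassReactions, co2Reactions) {
  if (is(fluxes, "FitResult")) fluxes <- fittedFluxes(fluxes)
  carbons <- carbonCounts(network)
  excreted <- metaboliteIds(network)[vapply(network@metabolites,
                                            function(m) m@excreted,
                                            logical(1))]
  carbonRate <- function(rids) {
    sum(vapply(rids, function(r) {
      rxn <- getReaction(network, r)
      sink <- intersect(names(rxn@products), excreted)
      if (!length(sink))
        emufluxError(sprintf(
          "reaction '%s' has no excreted product to carry carbon", r),
          "validationError")
      netFlux(fluxes)[[r]] * sum(rxn@products[sink] * carbons[sink])
    }, numeric(1)))
  }
  cBio <- carbonRate(biomassReactions)
  cCO2 <- carbonRate(co2Reactions)
  if (cBio + cCO2 <= 0)
    emufluxError("zero total carbon flux; CUE undefined", "undefinedCUE")
  cBio / (cBio + cCO2)
}
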