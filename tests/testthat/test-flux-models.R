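test_that("FBA solves toy networks to their hand-computed optima", {
  expect_equal(objectiveValue(fba(chainToyNetwork())), 10)
  expect_equal(objectiveValue(fba(parallelToyNetwork(10, 6))), 10)
  ## uptake-limited even when both branches could carry more
  expect_equal(objectiveValue(fba(parallelToyNetwork(10, 1000))), 10)
  sol <- fba(chainToyNetwork())
  expect_equal(unname(netFlux(sol)), c(10, 10, 10))
})

test_that("FBA reports infeasible and unbounded problems", {
  ## conflicting fixed throughputs
  mets <- list(Metabolite("s", 0, source = TRUE), Metabolite("A", 0),
               Metabolite("x", 0, excreted = TRUE))
  rxns <- list(Reaction("in_", c(s = 1), c(A = 1), lowerBound = 10,
                        upperBound = 10),
               Reaction("out", c(A = 1), c(x = 1), upperBound = 5,
                        objectiveCoefficient = 1))
  expect_error(fba(ReactionNetwork(mets, rxns)), class = "infeasibleLP")

  ## free-spinning reversible loop with infinite bounds
  loop <- ReactionNetwork(
    list(Metabolite("A", 0), Metabolite("B", 0)),
    list(Reaction("f", c(A = 1), c(B = 1), reversible = TRUE,
                  lowerBound = -Inf, upperBound = Inf,
                  objectiveCoefficient = 1),
         Reaction("g", c(B = 1), c(A = 1), reversible = TRUE,
                  lowerBound = -Inf, upperBound = Inf)))
  expect_error(fba(loop), class = "unboundedLP")
})

test_that("FBA optimum dominates every enumerated polytope vertex", {
  for (net in list(chainToyNetwork(), parallelToyNetwork(10, 6),
                   branchToyNetwork())) {
    obj <- emuflux:::objectiveCoefficients(net)
    opt <- objectiveValue(fba(net))
    verts <- enumerateVertices(net)
    expect_gt(length(verts), 0)
    for (v in verts)
      expect_gte(opt + 1e-8, sum(obj * v))
  }
})

test_that("FVA brackets the FBA solution with correct widths", {
  ## parallel branches at full optimality: each branch free within capacity
  rng <- fluxRanges(fva(parallelToyNetwork(10, 10), fraction = 1.0))
  b1 <- rng[rng$reaction == "b1", ]
  expect_equal(b1$lo, 0)
  expect_equal(b1$hi, 10)
  expect_equal(rng[rng$reaction == "upt", "lo"], 10)

  ## single chain fully determined: all widths zero
  rngChain <- fluxRanges(fva(chainToyNetwork(), fraction = 1.0))
  expect_lt(max(rngChain$hi - rngChain$lo), 1e-9)

  ## fraction 0 relaxes to the stoichiometric bounds
  rng0 <- fluxRanges(fva(chainToyNetwork(), fraction = 0))
  expect_equal(rng0[rng0$reaction == "upt", c("lo", "hi")],
               data.frame(lo = 0, hi = 10, row.names = 1L))

  ## containment of the point solution
  sol <- netFlux(fba(parallelToyNetwork(10, 6)))
  rfd <- fva(parallelToyNetwork(10, 6), fraction = 1.0)
  for (r in names(sol))
    expect_true(rangeContains(rfd@ranges[[r]], sol[[r]]))
})

test_that("13C fit recovers true fluxes from noiseless measurements", {
  net <- tcaToyNetwork()
  set.seed(0)
  for (i in 1:3) {
    v4 <- runif(1, 10, 90); ex <- runif(1, 0, 30)
    truth <- tcaToyFluxes(v4 = v4, exchange6 = ex)
    m <- synthMeasurements(net, truth,
                           fragments = c("glu_12345", "fum_1234"),
                           noiseSd = 0, seed = i)
    fit <- c13Fit(m, nStarts = 4, seed = 0)
    expect_lt(ssr(fit), 1e-6)
    expect_true(fit@converged)
    expect_lt(max(abs(netFlux(fittedFluxes(fit)) - netFlux(truth))), 1e-4)
    expect_lt(abs(exchangeFlux(fittedFluxes(fit))[["v6"]] - ex), 1e-3)
  }
})

test_that("noisy-fit SSR lands in the chi-squared band across seeds", {
  net <- tcaToyNetwork()
  truth <- tcaToyFluxes(v4 = 40, exchange6 = 10)
  nOK <- 0
  nSeeds <- 10
  for (s in seq_len(nSeeds)) {
    m <- synthMeasurements(net, truth,
                           fragments = c("glu_12345", "fum_1234"),
                           noiseSd = 0.01, seed = 100 + s)
    fit <- c13Fit(m, nStarts = 4, seed = 0)
    dof <- fit@nMeasurements - fit@nFreeFluxes
    if (ssr(fit) >= qchisq(0.025, dof) && ssr(fit) <= qchisq(0.975, dof))
      nOK <- nOK + 1
  }
  expect_gte(nOK, nSeeds - 2)
})

test_that("a fully determined scenario degenerates to forward simulation", {
  net <- tcaToyNetwork()
  ## pin every net flux via bounds and fix the exchange
  truth <- tcaToyFluxes(v4 = 50, exchange6 = 50)
  rxns <- lapply(reactions(net), function(r) {
    v <- netFlux(truth)[[r@id]]
    Reaction(r@id, r@reactants, r@products, reversible = r@reversible,
             lowerBound = v, upperBound = v)
  })
  pinned <- C13ReactionNetwork(ReactionNetwork(metabolites(net), rxns),
                               net@transitions, feed = net@feed)
  m <- synthMeasurements(pinned, truth, fragments = "glu_12345",
                         noiseSd = 0.01, seed = 5)
  fit <- c13Fit(m, nStarts = 1, seed = 0, fixedExchange = c(v6 = 50))
  expect_equal(fit@nFreeFluxes, 0L)
  sim <- simulateLabeling(net, truth, targets = "glu_1_2_3_4_5")
  obs <- fractions(m@measurements[[1]]$mdv)
  sds <- mdvErrors(m@measurements[[1]]$mdv)
  expect_equal(fit@residuals,
               (obs - fractions(sim[[1]])) / sds, tolerance = 1e-9)
})

test_that("profile-likelihood intervals behave on pinned and free fluxes", {
  net <- tcaToyNetwork()
  truth <- tcaToyFluxes(v4 = 37, exchange6 = 12)
  m <- synthMeasurements(net, truth, fragments = c("glu_12345", "fum_1234"),
                         noiseSd = 0, seed = 2)
  fit <- c13Fit(m, nStarts = 4, seed = 0)
  rfd <- c13FVA(m, fit, confidence = 0.95, reactions = c("v1", "v4"))
  ## uptake is pinned by its bounds: width ~ 0
  expect_lt(rfd@ranges[["v1"]]@hi - rfd@ranges[["v1"]]@lo, 1e-6)
  ## noiseless data: the true flux lies inside its interval
  expect_true(rangeContains(rfd@ranges[["v4"]], 37))
  ## the best fit lies inside every interval
  for (r in names(rfd@ranges))
    expect_true(rangeContains(rfd@ranges[[r]],
                              netFlux(fittedFluxes(fit))[[r]]))
})

test_that("two-scale fit reduces to plain 13C MFA and respects drains", {
  net <- tcaToyNetwork()
  truth <- tcaToyFluxes(v4 = 37, exchange6 = 12)
  core <- synthMeasurements(net, truth,
                            fragments = c("glu_12345", "fum_1234"),
                            noiseSd = 0, seed = 1)
  ref <- c13Fit(core, nStarts = 4, seed = 0)

  ## reduction: genome scale == core
  ts <- TwoScaleNetwork(ReactionNetwork(metabolites(core), reactions(core)),
                        core)
  r <- twoScaleFit(ts, nStarts = 4, seed = 0)
  expect_lt(max(abs(netFlux(fittedFluxes(r$fit)) -
                    netFlux(fittedFluxes(ref)))), 1e-3)

  ## biomass drain with fixed demand shifts the glutamate output exactly
  withDrain <- function(d) {
    mets2 <- c(metabolites(core), Metabolite("biomass", 0, excreted = TRUE))
    rxns2 <- c(reactions(core),
               Reaction("drain", c(akg = 1), c(biomass = 1),
                        lowerBound = d, upperBound = d))
    TwoScaleNetwork(ReactionNetwork(mets2, rxns2), core)
  }
  r0 <- twoScaleFit(withDrain(0), nStarts = 4, seed = 0)
  expect_lt(max(abs(netFlux(fittedFluxes(r0$fit)) -
                    netFlux(fittedFluxes(ref)))), 1e-3)
  r5 <- twoScaleFit(withDrain(5), nStarts = 4, seed = 0)
  expect_equal(netFlux(r5$genomeScale)[["drain"]], 5, tolerance = 1e-6)
  expect_equal(netFlux(r5$genomeScale)[["v3"]] -
               netFlux(fittedFluxes(ref))[["v3"]], -5, tolerance = 1e-3)
  expect_equal(netFlux(r5$genomeScale)[["v4"]], 37, tolerance = 1e-3)

  ## an unmapped core reaction is a validation error
  badCore <- synthMeasurements(net, truth, fragments = "glu_12345",
                               noiseSd = 0, seed = 1)
  gsMissing <- ReactionNetwork(metabolites(core),
                               reactions(core)[-4])
  expect_error(twoScaleFit(TwoScaleNetwork(gsMissing, badCore)),
               "counterpart")
})

test_that("ELVA spans exactly the attainable labeling range", {
  net <- flipBranchNetwork()
  truth <- flipBranchFluxes(r1 = 7)
  m <- synthMeasurements(net, truth, fragments = "E_12", noiseSd = 0,
                         seed = 1)
  fit <- c13Fit(m, nStarts = 4, seed = 0)
  ## the total-MDV measurement is invariant to the branch split, so the
  ## positional EMU E_1 ranges over everything the polytope can reach;
  ## grid-search oracle over the split fraction f: m1(E_1) = 0.5 f
  grid <- vapply(seq(0, 1, by = 0.05), function(f) {
    fl <- flipBranchFluxes(r1 = 10 * f)
    fractions(simulateLabeling(net, fl, targets = "E_1")[[1]])[2]
  }, numeric(1))
  ranges <- elva(m, fit, "E_1", nDirections = 16, seed = 1)
  m1 <- ranges[["E_1"]][[2]]
  expect_equal(m1@lo, min(grid), tolerance = 0.02)
  expect_equal(m1@hi, max(grid), tolerance = 0.02)
  expect_gte(m1@lo, 0)
  expect_lte(m1@hi, 1)

  ## a feed EMU is fixed by the input: width 0
  feedRange <- elva(m, fit, "A_1", nDirections = 4, seed = 1)[["A_1"]]
  expect_lt(feedRange[[2]]@hi - feedRange[[2]]@lo, 1e-9)

  ## E_1_2 is insensitive to the split: width ~ 0 despite the free flux
  tight <- elva(m, fit, "E_1_2", nDirections = 8, seed = 1)[["E_1_2"]]
  for (rn in tight) expect_lt(rn@hi - rn@lo, 1e-6)
})

test_that("carbon use efficiency follows its defining ratio", {
  fx <- soilCommunityFixture("glucose", cue = 0.5)
  net <- fx$networks[[1]]
  expect_equal(communityCUE(fx$fluxes, net, fx$biomassReactions,
                            fx$co2Reactions), 0.5, tolerance = 1e-9)
  ## all carbon to CO2
  fx0 <- soilCommunityFixture("glucose", cue = 0)
  expect_equal(communityCUE(fx0$fluxes, fx0$networks[[1]],
                            fx0$biomassReactions, fx0$co2Reactions), 0)
  ## equal carbon fluxes
  fxh <- soilCommunityFixture("pyruvate", cue = 0.5)
  expect_equal(communityCUE(fxh$fluxes, fxh$networks[[1]],
                            fxh$biomassReactions, fxh$co2Reactions), 0.5)
  ## near the stoichiometric maximum diversion
  fx9 <- soilCommunityFixture("glucose", cue = 0.6)
  expect_equal(communityCUE(fx9$fluxes, fx9$networks[[1]],
                            fx9$biomassReactions, fx9$co2Reactions), 0.6)
  ## zero-flux state has undefined CUE
  zero <- FluxDistribution(structure(numeric(5),
                                     names = names(netFlux(fx$fluxes))))
  expect_error(communityCUE(zero, net, fx$biomassReactions, fx$co2Reactions),
               class = "undefinedCUE")
})
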