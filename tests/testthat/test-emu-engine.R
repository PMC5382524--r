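test_that("backward EMU closure finds exactly the needed units", {
  net <- condensationNetwork()
  req <- requiredEMUs(net, "D_1_2_3")
  expect_setequal(names(req), c("D_1_2_3", "B_1_2", "C_1", "A_1_2"))

  ## a feed EMU is its own closure
  req2 <- requiredEMUs(net, "A_1_2")
  expect_setequal(names(req2), "A_1_2")

  mets <- list(Metabolite("A", 1, source = TRUE),
               Metabolite("B", 1, excreted = TRUE))
  rxns <- list(Reaction("r", c(A = 1), c(B = 1)))
  one <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
                            parseAtomTransitions(text = "r\tA(a) --> B(a)"),
                            feed = list(A = data.frame(mask = "1",
                                                       fraction = 1)))
  expect_setequal(names(requiredEMUs(one, "B_1")), c("B_1", "A_1"))

  expect_error(requiredEMUs(net, "Z_1"), class = "lookupError")
})

test_that("EMU transitions carry condensation sources and directions", {
  ## citrate-synthase style condensation: carbons 3-5 of citrate come from
  ## oac carbon 2 plus both accoa carbons
  net <- tcaToyNetwork()
  trs <- emuTransitionsFor(net, "cit_3_4_5")
  cond <- Filter(function(t) t@reactionId == "v1" &&
                   emuName(t@target) == "cit_3_4_5", trs)
  expect_length(cond, 1)
  expect_setequal(vapply(cond[[1]]@sources, emuName, character(1)),
                  c("accoa_1_2", "oac_2"))

  ## transfer: single-source transition
  trsB <- emuTransitionsFor(condensationNetwork(), "B_2")
  expect_length(trsB, 1)
  expect_equal(vapply(trsB[[1]]@sources, emuName, character(1)), "A_2")

  ## reversible reactions contribute one transition per direction
  trsOac <- emuTransitionsFor(net, "fum_1_2_3_4")
  dirs <- vapply(Filter(function(t) t@reactionId == "v6", trsOac),
                 function(t) t@direction, character(1))
  expect_true("backward" %in% dirs)
  szOK <- vapply(trsOac, function(t)
    sum(vapply(t@sources, emuSize, integer(1))) == emuSize(t@target),
    logical(1))
  expect_true(all(szOK))
})

test_that("simple transfers and unlabeled feeds give trivial labelings", {
  mets <- list(Metabolite("A", 2, source = TRUE),
               Metabolite("B", 2, excreted = TRUE))
  rxns <- list(Reaction("r", c(A = 1), c(B = 1)))
  net <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = "r\tA(ab) --> B(ab)"),
    feed = list(A = data.frame(mask = "10", fraction = 1)))
  fl <- FluxDistribution(c(r = 5))
  sim <- simulateLabeling(net, fl, targets = "B_1")
  expect_equal(fractions(sim[["B_1"]]), c(0, 1))

  unl <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = "r\tA(ab) --> B(ab)"),
    feed = list(A = data.frame(mask = "00", fraction = 1)))
  sim2 <- simulateLabeling(unl, fl, targets = c("B_1_2", "B_2"))
  expect_equal(fractions(sim2[["B_1_2"]]), c(1, 0, 0))
  expect_equal(fractions(sim2[["B_2"]]), c(1, 0))
})

test_that("EMU cascade matches the brute-force isotopomer oracle on the TCA toy", {
  net <- tcaToyNetwork()
  for (fl in randomTCAFluxes(20, seed = 11)) {
    sim <- simulateLabeling(net, fl, targets = "glu_1_2_3_4_5")
    oracle <- isotopomersToMDV(bruteForceIsotopomerSimulate(net, fl)$glu)
    expect_mdv_equal(sim[["glu_1_2_3_4_5"]], oracle, tol = 1e-8)
  }
})

test_that("size-partitioned cascade equals the fully coupled solve", {
  net <- tcaToyNetwork()
  for (fl in randomTCAFluxes(5, seed = 3)) {
    a <- simulateLabeling(net, fl, targets = "glu_1_2_3_4_5")
    b <- simulateLabeling(net, fl, targets = "glu_1_2_3_4_5",
                          method = "coupled")
    expect_mdv_equal(a[[1]], b[[1]], tol = 1e-10)
  }
  cnet <- condensationNetwork()
  cf <- FluxDistribution(c(R1 = 4, R2 = 4))
  expect_mdv_equal(simulateLabeling(cnet, cf, "D_1_2_3")[[1]],
                   simulateLabeling(cnet, cf, "D_1_2_3",
                                    method = "coupled")[[1]], tol = 1e-10)
})

test_that("simulated MDVs are normalized, nonnegative and scale-invariant", {
  net <- tcaToyNetwork()
  fl <- tcaToyFluxes(v4 = 31, exchange6 = 17)
  targets <- c("glu_1_2_3_4_5", "fum_1_2_3_4", "co2_1")
  sim <- simulateLabeling(net, fl, targets = targets)
  for (m in sim) {
    expect_lt(abs(sum(fractions(m)) - 1), 1e-9)
    expect_gt(min(fractions(m)), -1e-12)
  }
  ## scaling all fluxes leaves labeling unchanged
  net3 <- tcaToyNetwork(uptake = 300)
  fl3 <- FluxDistribution(3 * netFlux(fl), exchange = 3 * exchangeFlux(fl))
  sim3 <- simulateLabeling(net3, fl3, targets = targets)
  for (t in targets) expect_mdv_equal(sim[[t]], sim3[[t]], tol = 1e-12)
})

test_that("EMU balance rows sum to zero at balanced fluxes", {
  net <- tcaToyNetwork()
  fl <- tcaToyFluxes()
  decomp <- emuDecompose(net, "glu_1_2_3_4_5")
  for (s in c(1, 2, 3)) {
    sys <- emuMatrices(decomp, net, fl, s)
    ## total inflow (B row sums plus off-diagonal A) balances the diagonal
    rowTotals <- rowSums(sys$A) + rowSums(sys$B)
    expect_lt(max(abs(rowTotals)), 1e-9)
  }
})

test_that("unbalanced fluxes and zero-throughput EMUs are diagnosed", {
  net <- tcaToyNetwork()
  bad <- FluxDistribution(c(v1 = 100, v2 = 90, v3 = 50, v4 = 50, v5 = 50,
                            v6 = 50, v7 = 50))
  expect_error(simulateLabeling(net, bad, targets = "glu_1_2_3_4_5"),
               class = "validationError")

  mets <- list(Metabolite("A", 1, source = TRUE), Metabolite("B", 1),
               Metabolite("D", 1), Metabolite("X", 1, excreted = TRUE))
  rxns <- list(Reaction("r1", c(A = 1), c(B = 1)),
               Reaction("r2", c(B = 1), c(X = 1)),
               Reaction("r3", c(B = 1), c(D = 1)),
               Reaction("r4", c(D = 1), c(X = 1)))
  net2 <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = c("r1\tA(a) --> B(a)", "r2\tB(a) --> X(a)",
                                  "r3\tB(a) --> D(a)", "r4\tD(a) --> X(a)")),
    feed = list(A = data.frame(mask = "1", fraction = 1)))
  zero <- FluxDistribution(c(r1 = 10, r2 = 10, r3 = 0, r4 = 0))
  expect_error(simulateLabeling(net2, zero, targets = "D_1"),
               class = "singularEMUSystem")
})

test_that("oracle handles trivial pools and refuses oversized networks", {
  mets <- list(Metabolite("A", 1, source = TRUE),
               Metabolite("B", 1, excreted = TRUE))
  rxns <- list(Reaction("r", c(A = 1), c(B = 1)))
  net <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = "r\tA(a) --> B(a)"),
    feed = list(A = data.frame(mask = "1", fraction = 1)))
  iso <- bruteForceIsotopomerSimulate(net, FluxDistribution(c(r = 1)))
  expect_equal(iso$B, c(0, 1))

  unl <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = "r\tA(a) --> B(a)"),
    feed = list(A = data.frame(mask = "0", fraction = 1)))
  iso2 <- bruteForceIsotopomerSimulate(unl, FluxDistribution(c(r = 1)))
  expect_equal(iso2$B, c(1, 0))

  big <- C13ReactionNetwork(ReactionNetwork(
    list(Metabolite("G", 18, source = TRUE),
         Metabolite("H", 18, excreted = TRUE)),
    list(Reaction("r", c(G = 1), c(H = 1)))),
    parseAtomTransitions(text = "r\tG(abcdefghijklmnopqr) --> H(abcdefghijklmnopqr)"),
    feed = list(G = data.frame(mask = strrep("0", 18), fraction = 1)))
  expect_error(bruteForceIsotopomerSimulate(big, FluxDistribution(c(r = 1))),
               class = "sizeGuardError")
})

test_that("isotopomer marginals respect carbon positions", {
  ## B gets A's carbons swapped; feed labeled at carbon 1 only
  net <- flipBranchNetwork()
  fl <- flipBranchFluxes(r1 = 0)
  iso <- bruteForceIsotopomerSimulate(net, fl)
  ## all E molecules came via R2 (swap): label sits at position 2
  expect_equal(fractions(isotopomersToMDV(iso$E, indices = 2)), c(0.5, 0.5))
  expect_equal(fractions(isotopomersToMDV(iso$E, indices = 1)), c(1, 0))
})
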