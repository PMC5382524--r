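#' @include c13-fit.R predictions.R
NULL

## Programmatic generators for all example and test inputs: the classic
## TCA-cycle toy network used to exercise EMU-based labeling simulation, small
## FBA/knockout toys, a lumped soil-community model with two carbon sources
## and two tracers each, synthetic noisy measurements, and synthetic
## proteomics designs. Identical arguments and seed give identical outputs.

#' TCA-cycle toy network for 13C MFA
#'
#' A minimal TCA model with acetyl-CoA and aspartate as substrates and
#' glutamate and CO2 as products: citrate synthesis (condensation), two
#' decarboxylations, the symmetric succinate/fumarate steps (half-weight
#' scrambling transitions) and a reversible fumarate/oxaloacetate
#' interconversion. The feed is 50% unlabeled, 25% \[2-13C\] and 25%
#' \[1,2-13C\] acetyl-CoA with aspartate unlabeled. Flux values are
#' representative of the classic demonstration; labeling ground truth is the
#' in-package brute-force isotopomer oracle.
#'
#' @param uptake Acetyl-CoA uptake flux; fixed via `lb = ub` (default 100).
#' @return A [C13ReactionNetwork] (glutamate MDV as the conventional target).
#' @examples
#' net <- tcaToyNetwork()
#' carbonTransitionsOK(net)  # character(0)
#' @export
tcaToyNetwork <- function(uptake = 100) {
  mets <- list(
    Metabolite("accoa", 2, source = TRUE),
    Metabolite("asp", 4, source = TRUE),
    Metabolite("oac", 4),
    Metabolite("cit", 6),
    Metabolite("akg", 5),
    Metabolite("suc", 4),
    Metabolite("fum", 4),
    Metabolite("glu", 5, excreted = TRUE),
    Metabolite("co2", 1, excreted = TRUE))
  rxns <- list(
    Reaction("v1", c(accoa = 1, oac = 1), c(cit = 1),
             lowerBound = uptake, upperBound = uptake),
    Reaction("v2", c(cit = 1), c(akg = 1, co2 = 1)),
    Reaction("v3", c(akg = 1), c(glu = 1)),
    Reaction("v4", c(akg = 1), c(suc = 1, co2 = 1)),
    Reaction("v5", c(suc = 1), c(fum = 1)),
    Reaction("v6", c(fum = 1), c(oac = 1), reversible = TRUE),
    Reaction("v7", c(asp = 1), c(oac = 1)))
  transitions <- parseAtomTransitions(text = c(
    "v1\taccoa(ab) + oac(cdef) --> cit(fedbac)",
    "v2\tcit(abcdef) --> akg(abcde) + co2(f)",
    "v3\takg(abcde) --> glu(abcde)",
    "v4\takg(abcde) --> suc(bcde) + co2(a)",
    "v4\takg(abcde) --> suc(edcb) + co2(a)",
    "v5\tsuc(abcd) --> fum(abcd)",
    "v5\tsuc(abcd) --> fum(dcba)",
    "v6\tfum(abcd) --> oac(abcd)",
    "v6\tfum(dcba) --> oac(abcd)",
    "v7\tasp(abcd) --> oac(abcd)"))
  feed <- list(
    accoa = data.frame(mask = c("00", "01", "11"),
                       fraction = c(0.50, 0.25, 0.25)),
    asp = data.frame(mask = "0000", fraction = 1))
  C13ReactionNetwork(ReactionNetwork(mets, rxns), transitions, feed = feed)
}

#' Reference flux values for the TCA toy network
#'
#' The toy has two degrees of freedom once uptake is fixed: the flux `v4`
#' splitting 2-oxoglutarate between succinate and glutamate, and the exchange
#' of the reversible fumarate/oxaloacetate step. All other net fluxes follow
#' from the balances.
#'
#' @param v4 Net flux through the succinate branch (default 50).
#' @param exchange6 Exchange flux of the reversible `v6` (default 50).
#' @param uptake Acetyl-CoA uptake (default 100; must match the network).
#' @return A balanced [FluxDistribution].
#' @export
tcaToyFluxes <- function(v4 = 50, exchange6 = 50, uptake = 100) {
  FluxDistribution(
    c(v1 = uptake, v2 = uptake, v3 = uptake - v4, v4 = v4, v5 = v4, v6 = v4,
      v7 = uptake - v4),
    exchange = c(v6 = exchange6))
}

#' Linear-chain toy network (source -> A -> B -> sink)
#'
#' Uptake capped at `uptake`; the export reaction is the objective. Every
#' internal flux is pinned to the uptake, making FVA ranges width zero at
#' full optimality.
#'
#' @param uptake Uptake capacity (default 10).
#' @return A [ReactionNetwork].
#' @export
chainToyNetwork <- function(uptake = 10) {
  mets <- list(Metabolite("src", 0, source = TRUE), Metabolite("A", 0),
               Metabolite("B", 0), Metabolite("snk", 0, excreted = TRUE))
  rxns <- list(
    Reaction("upt", c(src = 1), c(A = 1), upperBound = uptake),
    Reaction("r1", c(A = 1), c(B = 1)),
    Reaction("out", c(B = 1), c(snk = 1), objectiveCoefficient = 1))
  ReactionNetwork(mets, rxns)
}

#' Two-parallel-path toy network
#'
#' Uptake capped at `uptake`, two equivalent branches each with capacity
#' `branchCap`; at full optimality FVA leaves each branch free in
#' `[uptake - branchCap, branchCap]`.
#'
#' @param uptake Uptake capacity (default 10).
#' @param branchCap Capacity of each branch (default 10).
#' @return A [ReactionNetwork].
#' @export
parallelToyNetwork <- function(uptake = 10, branchCap = 10) {
  mets <- list(Metabolite("src", 0, source = TRUE), Metabolite("A", 0),
               Metabolite("B", 0), Metabolite("snk", 0, excreted = TRUE))
  rxns <- list(
    Reaction("upt", c(src = 1), c(A = 1), upperBound = uptake),
    Reaction("b1", c(A = 1), c(B = 1), upperBound = branchCap),
    Reaction("b2", c(A = 1), c(B = 1), upperBound = branchCap),
    Reaction("out", c(B = 1), c(snk = 1), objectiveCoefficient = 1))
  ReactionNetwork(mets, rxns)
}

#' Two-branch knockout toy with a fixed uptake
#'
#' Uptake pinned to `uptake` (lb = ub), so after knocking out one branch all
#' flux must reroute through the other — the canonical MoMA/ROOM rerouting
#' example. The reference state `branchToyReference()` splits flow 7/3.
#'
#' @param uptake Fixed uptake (default 10).
#' @return A [ReactionNetwork].
#' @export
branchToyNetwork <- function(uptake = 10) {
  mets <- list(Metabolite("src", 0, source = TRUE), Metabolite("A", 0),
               Metabolite("B", 0), Metabolite("snk", 0, excreted = TRUE))
  rxns <- list(
    Reaction("upt", c(src = 1), c(A = 1), lowerBound = uptake,
             upperBound = uptake),
    Reaction("b1", c(A = 1), c(B = 1)),
    Reaction("b2", c(A = 1), c(B = 1)),
    Reaction("out", c(B = 1), c(snk = 1), objectiveCoefficient = 1))
  ReactionNetwork(mets, rxns)
}

#' @rdname branchToyNetwork
#' @param b1,b2 Reference branch fluxes (default 7 and 3).
#' @export
branchToyReference <- function(uptake = 10, b1 = 7, b2 = 3) {
  FluxDistribution(c(upt = uptake, b1 = b1, b2 = b2, out = b1 + b2))
}

#' Lumped soil-community network with planted carbon use efficiency
#'
#' A minimal glycolysis + pyruvate-oxidation lump representing the combined
#' metabolism of a soil microbial community: carbon enters as glucose or
#' pyruvate, leaves as CO2 (pyruvate decarboxylation releases carbon 1,
#' acetyl-CoA oxidation releases carbons 2-3) or as biomass (drain from
#' acetyl-CoA). Because the two CO2 routes release different carbon
#' positions, position-specific tracers make the CO2 labeling sensitive to
#' how much carbon the biomass drain diverts — the planted carbon use
#' efficiency `CUE = C_biomass / (C_biomass + C_CO2)` sets the drain
#' (`CUE < 2/3` by stoichiometry). Each carbon source comes in two tracer
#' variants sharing identical fluxes: \[1-13C\] or fully labeled glucose,
#' \[1-13C\] or \[2,3-13C\] pyruvate.
#'
#' @param source `"glucose"` or `"pyruvate"`.
#' @param cue Planted carbon use efficiency in `[0, 2/3)` (default 0.5).
#' @param uptake Substrate uptake flux (default 10 for glucose; the pyruvate
#'   variant uses `2 * uptake` so the pyruvate supply matches).
#' @return List with `networks` (one [C13ReactionNetwork] per tracer),
#'   `fluxes` (shared true [FluxDistribution]), `cue`,
#'   `biomassReactions` and `co2Reactions`.
#' @export
soilCommunityFixture <- function(source = c("glucose", "pyruvate"), cue = 0.5,
                                 uptake = 10) {
  source <- match.arg(source)
  if (cue < 0 || cue >= 2 / 3)
    emufluxError("planted CUE must be in [0, 2/3)", "validationError")
  common <- list(
    Metabolite("pyr", 3),
    Metabolite("accoa", 2),
    Metabolite("co2", 1, excreted = TRUE),
    Metabolite("biom", 2, excreted = TRUE))
  downstream <- list(
    Reaction("pdh", c(pyr = 1), c(accoa = 1, co2 = 1)),
    Reaction("ox", c(accoa = 1), c(co2 = 2)),
    Reaction("bio", c(accoa = 1), c(biom = 1)))
  downstreamTrans <- c(
    "pdh\tpyr(abc) --> accoa(bc) + co2(a)",
    "ox\taccoa(ab) --> co2(a) + co2(b)",
    "bio\taccoa(ab) --> biom(ab)")
  if (source == "glucose") {
    mets <- c(list(Metabolite("glc", 6, source = TRUE),
                   Metabolite("g6p", 6)), common)
    rxns <- c(list(
      Reaction("upt", c(glc = 1), c(g6p = 1), lowerBound = uptake,
               upperBound = uptake),
      Reaction("emp", c(g6p = 1), c(pyr = 2))), downstream)
    trans <- c("upt\tglc(abcdef) --> g6p(abcdef)",
               "emp\tg6p(abcdef) --> pyr(cba) + pyr(def)",
               downstreamTrans)
    masks <- list(glc = c("100000", "111111"))
    pyrSupply <- 2 * uptake
    uptFlux <- uptake
    net <- c(emp = uptake)
  } else {
    mets <- c(list(Metabolite("pyrx", 3, source = TRUE)), common)
    rxns <- c(list(
      Reaction("upt", c(pyrx = 1), c(pyr = 1), lowerBound = 2 * uptake,
               upperBound = 2 * uptake)), downstream)
    trans <- c("upt\tpyrx(abc) --> pyr(abc)", downstreamTrans)
    masks <- list(pyrx = c("100", "011"))
    pyrSupply <- 2 * uptake
    uptFlux <- 2 * uptake
    net <- c()
  }
  ## CUE = 2 b / (3 pyrSupply) with b the acetyl-CoA biomass drain
  bioFlux <- 1.5 * cue * pyrSupply
  fluxes <- FluxDistribution(c(
    upt = uptFlux, net, pdh = pyrSupply, ox = pyrSupply - bioFlux,
    bio = bioFlux))
  srcMet <- names(masks)[1]
  networks <- lapply(masks[[1]], function(mask) {
    feed <- list(data.frame(mask = mask, fraction = 1))
    names(feed) <- srcMet
    C13ReactionNetwork(
      ReactionNetwork(mets, rxns), parseAtomTransitions(text = trans),
      feed = feed)
  })
  names(networks) <- masks[[1]]
  list(networks = networks, fluxes = fluxes, cue = cue,
       biomassReactions = "bio", co2Reactions = c("pdh", "ox"))
}

#' Generate synthetic labeling measurements from known fluxes
#'
#' Simulates the MDVs of the requested fragments at the true fluxes, adds
#' iid Gaussian noise of standard deviation `noiseSd` truncated to `[0, 1]`,
#' renormalizes, and attaches the result (with `errors = noiseSd`) as the
#' network's measurements. Deterministic per seed. With `dir` given, the
#' labeling and feed CSV files are also written.
#'
#' @param network A [C13ReactionNetwork].
#' @param trueFluxes Balanced [FluxDistribution] used as ground truth.
#' @param fragments Fragment names (`"<met>_<positions>"`); default
#'   `"glu_12345"`-style full fragments of all excreted carbon products is not
#'   assumed — pass explicitly.
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed Random seed.
#' @param sdFloor Reported measurement error floor (default 0.003).
#' @param dir Optional directory to also write `labeling.csv` and `feed.csv`.
#' @return The network with measurements attached; file paths (if written) in
#'   attribute `"files"`.
#' @export
synthMeasurements <- function(network, trueFluxes, fragments, noiseSd = 0,
                              seed = 1, sdFloor = 0.003, dir = NULL) {
  if (noiseSd < 0)
    emufluxError("noiseSd must be nonnegative", "validationError")
  set.seed(seed)
  sim <- simulateLabeling(network, trueFluxes,
                          targets = lapply(fragments, fragmentEMU))
  meas <- lapply(seq_along(fragments), function(i) {
    f <- fractions(sim[[i]])
    noisy <- pmin(1, pmax(0, f + stats::rnorm(length(f), 0, noiseSd)))
    list(fragment = fragments[i],
         mdv = MDV(noisy, errors = rep(max(noiseSd, sdFloor), length(f))))
  })
  out <- C13ReactionNetwork(ReactionNetwork(network@metabolites,
                                            network@reactions),
                            network@transitions, feed = network@feed,
                            measurements = meas)
  if (!is.null(dir)) {
    files <- c(labeling = file.path(dir, "labeling.csv"),
               feed = file.path(dir, "feed.csv"))
    writeLabelingCSV(meas, files[["labeling"]])
    writeFeedCSV(network@feed, files[["feed"]])
    attr(out, "files") <- files
  }
  out
}

#' Synthetic proteomics design with planted signal
#'
#' Emulates a combinatorial pathway-engineering proteomics study (promoter
#' strength x induction strength x induction time): `nInformative` proteins
#' differ between high and low producers by `effect` (on the standardized
#' abundance scale), all other proteins are noise, and production tracks the
#' informative proteins plus Gaussian noise.
#'
#' @param nStrains Number of strains/conditions (default 27, a 3x3x3 design).
#' @param nProteins Number of measured proteins (default 20).
#' @param nInformative Number of planted signal proteins (default 3).
#' @param effect Mean abundance difference of informative proteins between
#'   high and low producers (default 2).
#' @param noiseSd Abundance noise standard deviation (default 0.3).
#' @param seed Random seed.
#' @return List with `abundance` (strains x proteins matrix), `production`,
#'   and `informative` (planted protein names).
#' @export
syntheticProteomics <- function(nStrains = 27, nProteins = 20,
                                nInformative = 3, effect = 2, noiseSd = 0.3,
                                seed = 0) {
  set.seed(seed)
  high <- rep(c(0, 1), length.out = nStrains)[sample(nStrains)]
  x <- matrix(stats::rnorm(nStrains * nProteins, 0, noiseSd),
              nStrains, nProteins,
              dimnames = list(paste0("strain", seq_len(nStrains)),
                              paste0("P", seq_len(nProteins))))
  inf <- paste0("P", seq_len(nInformative))
  x[, inf] <- x[, inf] + effect * high
  production <- 1 + high + stats::rnorm(nStrains, 0, 0.1)
  list(abundance = x, production = production, informative = inf)
}
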