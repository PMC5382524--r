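## Shared builders and tiny independent oracles used across the test files.

## two-carbon branch network where R2 flips the carbon order; measuring the
## total MDV of E leaves the branch ratio free while positional EMUs move
flipBranchNetwork <- function(uptake = 10) {
  mets <- list(Metabolite("A", 2, source = TRUE), Metabolite("B", 2),
               Metabolite("E", 2, excreted = TRUE))
  rxns <- list(
    Reaction("upt", c(A = 1), c(B = 1), lowerBound = uptake,
             upperBound = uptake),
    Reaction("R1", c(B = 1), c(E = 1)),
    Reaction("R2", c(B = 1), c(E = 1)))
  trans <- parseAtomTransitions(text = c(
    "upt\tA(ab) --> B(ab)",
    "R1\tB(ab) --> E(ab)",
    "R2\tB(ab) --> E(ba)"))
  feed <- list(A = data.frame(mask = c("00", "10"), fraction = c(0.5, 0.5)))
  C13ReactionNetwork(ReactionNetwork(mets, rxns), trans, feed = feed)
}

flipBranchFluxes <- function(r1 = 7, uptake = 10) {
  FluxDistribution(c(upt = uptake, R1 = r1, R2 = uptake - r1))
}

## condensation toy: A(ab) -> B(ab); B(ab) + C(c) -> D(abc)
condensationNetwork <- function() {
  mets <- list(Metabolite("A", 2, source = TRUE),
               Metabolite("C", 1, source = TRUE),
               Metabolite("B", 2), Metabolite("D", 3, excreted = TRUE))
  rxns <- list(Reaction("R1", c(A = 1), c(B = 1)),
               Reaction("R2", c(B = 1, C = 1), c(D = 1)))
  trans <- parseAtomTransitions(text = c(
    "R1\tA(ab) --> B(ab)",
    "R2\tB(ab) + C(c) --> D(abc)"))
  feed <- list(A = data.frame(mask = c("00", "10"), fraction = c(0.4, 0.6)),
               C = data.frame(mask = c("0", "1"), fraction = c(0.3, 0.7)))
  C13ReactionNetwork(ReactionNetwork(mets, rxns), trans, feed = feed)
}

## enumerate the vertices of {v : S v = 0, lb <= v <= ub} by fixing
## (n - rank) variables at a bound and solving the equality system;
## an independent optimality oracle for the LP-based solvers
enumerateVertices <- function(network) {
  S <- stoichiometricMatrix(network)
  b <- emuflux:::fluxBounds(network)
  n <- ncol(S)
  rank <- qr(S)$rank
  nfix <- n - rank
  verts <- list()
  if (nfix == 0) return(verts)
  for (idx in utils::combn(n, nfix, simplify = FALSE)) {
    grid <- expand.grid(rep(list(c("lb", "ub")), nfix),
                        stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      fixVals <- vapply(seq_len(nfix), function(j)
        if (grid[g, j] == "lb") b$lb[idx[j]] else b$ub[idx[j]], numeric(1))
      if (any(!is.finite(fixVals))) next
      E <- matrix(0, nfix, n)
      E[cbind(seq_len(nfix), idx)] <- 1
      A <- rbind(S, E)
      rhs <- c(numeric(nrow(S)), fixVals)
      if (qr(A)$rank < n) next
      v <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
      if (is.null(v)) next
      if (all(v >= b$lb - 1e-8 & v <= b$ub + 1e-8))
        verts[[length(verts) + 1L]] <- structure(v, names = colnames(S))
    }
  }
  verts
}

## random balanced TCA flux distributions over the two degrees of freedom
randomTCAFluxes <- function(n, seed, v4range = c(5, 95),
                            exchRange = c(0, 50)) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    tcaToyFluxes(v4 = runif(1, v4range[1], v4range[2]),
                 exchange6 = runif(1, exchRange[1], exchRange[2])))
}

expect_mdv_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(fractions(a) - fractions(b))), tol)
}
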