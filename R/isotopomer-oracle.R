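#' @include emu-engine.R
NULL

## Full positional-isotopomer steady-state simulation. Deliberately
## independent of the EMU engine: it enumerates all 2^n isotopomers per
## metabolite and solves the balances by damped successive substitution, so it
## serves as a ground-truth oracle for the EMU path on small networks.

#' Brute-force isotopomer simulation
#'
#' Solves the steady-state positional-isotopomer balances of every
#' carbon-bearing metabolite by fixed-point iteration, enumerating all `2^n`
#' isotopomers. Tractable only for small networks; refuses when the total
#' state count `sum(2^n)` exceeds 2^16.
#'
#' @param network A [C13ReactionNetwork].
#' @param fluxes A balanced [FluxDistribution].
#' @param maxIter,tol Fixed-point iteration controls.
#' @return Named list: metabolite id -> numeric vector of length `2^n` with
#'   isotopomer fractions. Bit `j` (value `2^(j-1)`) of the 0-based vector
#'   index marks carbon `j` as labeled.
#' @export
bruteForceIsotopomerSimulate <- function(network, fluxes, maxIter = 100000,
                                         tol = 1e-14) {
  carbons <- carbonCounts(network)
  withC <- names(carbons)[carbons > 0]
  if (sum(2^carbons[withC]) > 2^16)
    emufluxError(sprintf(
      "isotopomer state space too large (sum 2^n = %d > %d)",
      sum(2^carbons[withC]), 2^16), "sizeGuardError")
  checkBalanced(network, fluxes)
  dir <- directionalFluxes(network, fluxes)
  sourceOf <- structure(vapply(network@metabolites, function(m) m@source,
                               logical(1)), names = metaboliteIds(network))

  state <- list()
  for (m in withC) {
    n <- carbons[[m]]
    v <- numeric(2^n)
    if (sourceOf[[m]]) {
      spec <- network@feed[[m]]
      if (is.null(spec))
        emufluxError(sprintf("no feed labeling specified for source '%s'", m),
                     "validationError")
      for (i in seq_len(nrow(spec))) {
        bits <- as.integer(strsplit(spec$mask[i], "")[[1]])
        idx <- sum(bits * 2^(seq_len(n) - 1L)) + 1L
        v[idx] <- v[idx] + spec$fraction[i]
      }
      v <- v / sum(v)
    } else {
      v[1] <- 1  # start unlabeled
    }
    state[[m]] <- v
  }

  ## precompute production routes: per internal metabolite, list of
  ## (phi-index, per-combined-state product index map, reactant met list)
  occ <- productionOccurrences(network)
  routes <- list()
  for (m in withC[!sourceOf[withC]]) {
    if (is.null(occ[[m]]))
      emufluxError(sprintf(
        "metabolite '%s' is produced by no carbon transition", m),
        "carbonBalanceError")
    routes[[m]] <- lapply(occ[[m]], function(o) {
      rmets <- o$reac$met
      rsz <- nchar(o$reac$pattern)
      offsets <- c(0L, cumsum(rsz))[seq_along(rsz)]  # bit offset per reactant
      total <- sum(rsz)
      prodLetters <- strsplit(o$pattern, "")[[1]]
      allLetters <- strsplit(paste(o$reac$pattern, collapse = ""), "")[[1]]
      srcBit <- match(prodLetters, allLetters)  # combined-bit for each product carbon
      comb <- 0:(2^total - 1L)
      prodIdx <- integer(length(comb))
      for (k in seq_along(prodLetters))
        prodIdx <- prodIdx +
          bitwAnd(bitwShiftR(comb, srcBit[k] - 1L), 1L) * 2^(k - 1L)
      list(rid = o$rid, dir = o$dir, weight = o$weight, rmets = rmets,
           rsz = rsz, offsets = offsets, total = total,
           comb = comb, prodIdx = prodIdx + 1L, nProd = nchar(o$pattern))
    })
  }

  internal <- withC[!sourceOf[withC]]
  for (iter in seq_len(maxIter)) {
    delta <- 0
    for (m in internal) {
      acc <- numeric(2^carbons[[m]])
      tot <- 0
      for (ro in routes[[m]]) {
        phi <- dir[[ro$dir]][[ro$rid]] * ro$weight
        if (phi <= 0) next
        ## joint probability of each combined reactant state
        p <- rep(1, 2^ro$total)
        for (j in seq_along(ro$rmets)) {
          bitsj <- bitwAnd(bitwShiftR(ro$comb, ro$offsets[j]),
                           2^ro$rsz[j] - 1L)
          p <- p * state[[ro$rmets[j]]][bitsj + 1L]
        }
        dist <- numeric(2^ro$nProd)
        for (ci in seq_along(p))
          dist[ro$prodIdx[ci]] <- dist[ro$prodIdx[ci]] + p[ci]
        acc <- acc + phi * dist
        tot <- tot + phi
      }
      if (tot <= 0)
        emufluxError(sprintf(
          "metabolite '%s' has zero production at these fluxes", m),
          "singularEMUSystem")
      newv <- acc / tot
      delta <- max(delta, max(abs(newv - state[[m]])))
      state[[m]] <- newv
    }
    if (delta < tol) break
  }
  state
}

#' Marginalize isotopomer fractions to an EMU mass distribution
#'
#' @param isotopomers Numeric vector of length `2^n` (see
#'   [bruteForceIsotopomerSimulate()]).
#' @param indices 1-based carbon positions of the EMU (default: all carbons).
#' @return An [MDV] over those positions.
#' @export
isotopomersToMDV <- function(isotopomers, indices = NULL) {
  n <- round(log2(length(isotopomers)))
  if (2^n != length(isotopomers))
    emufluxError("isotopomer vector length must be a power of 2",
                 "validationError")
  if (is.null(indices)) indices <- seq_len(n)
  idx <- 0:(length(isotopomers) - 1L)
  m <- integer(length(idx))
  for (j in indices)
    m <- m + bitwAnd(bitwShiftR(idx, j - 1L), 1L)
  MDV(vapply(0:length(indices), function(k) sum(isotopomers[m == k]),
             numeric(1)))
}
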