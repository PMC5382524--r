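#' @include utils.R
NULL

## Thin LP contract over pracma::linprog. The backend expects x >= 0 and
## inequality constraints only, so the wrapper shifts variables by their lower
## bounds and expands equalities and upper bounds into inequality rows.
## Returns list(x, objective, status) with status "optimal", "infeasible" or
## "unbounded".

solveLP <- function(obj, Aeq = NULL, beq = NULL, lb, ub,
                    Aineq = NULL, bineq = NULL, maximize = FALSE,
                    maxiter = 500) {
  n <- length(obj)
  if (any(lb > ub + 1e-12))
    return(list(x = NULL, objective = NA_real_, status = "infeasible"))
  if (any(!is.finite(lb)))
    lb[!is.finite(lb)] <- -1e6  # backend needs finite shifts
  ## shift: x = v - lb >= 0
  rows <- NULL; rhs <- NULL
  addRows <- function(A, b) {
    rows <<- rbind(rows, A)
    rhs <<- c(rhs, b)
  }
  if (!is.null(Aeq) && nrow(Aeq)) {
    bshift <- beq - as.numeric(Aeq %*% lb)
    addRows(Aeq, bshift)
    addRows(-Aeq, -bshift)
  }
  finUb <- which(is.finite(ub))
  if (length(finUb))
    addRows(diag(n)[finUb, , drop = FALSE], (ub - lb)[finUb])
  if (!is.null(Aineq) && nrow(Aineq))
    addRows(Aineq, bineq - as.numeric(Aineq %*% lb))
  scale <- max(1, abs(rhs))
  ## the backend simplex breaks pivot ties randomly; run it under isolated,
  ## deterministic seeds (restoring the caller's RNG state) and retry a few
  ## tie-break sequences before accepting a failure
  runBackend <- function(cc) {
    for (seed in c(1L, 7L, 42L, 4242L)) {
      res <- withSeed(seed, tryCatch(
        pracma::linprog(cc, A = rows, b = rhs, maximize = maximize,
                        maxiter = maxiter, bigM = 100 * scale),
        error = function(e) NULL))
      if (!is.null(res) && res$errno == 1 && !any(is.na(res$x))) return(res)
    }
    NULL
  }
  res <- runBackend(obj)
  if (is.null(res)) {
    ## distinguish infeasible from unbounded with a zero-objective probe
    maximize <- FALSE
    probe <- runBackend(numeric(n))
    return(list(x = NULL, objective = NA_real_,
                status = if (!is.null(probe)) "unbounded" else "infeasible"))
  }
  x <- res$x + lb
  list(x = x, objective = sum(obj * x), status = "optimal")
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}
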