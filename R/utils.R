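## Small internal helpers shared across modules.

sortLetters <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")

emufluxError <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "emufluxError"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## popcount over the lowest `n` bits of integer x
bitCount <- function(x, n) {
  cnt <- integer(length(x))
  for (j in seq_len(n) - 1L)
    cnt <- cnt + bitwAnd(bitwShiftR(x, j), 1L)
  cnt
}

## null space of a dense matrix via QR of the transpose (base R only)
nullSpace <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  positive <- sv$d > tol * max(sv$d, 1)
  rank <- sum(positive)
  if (rank == ncol(A)) matrix(0, ncol(A), 0) else
    sv$v[, seq(rank + 1L, ncol(A)), drop = FALSE]
}
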