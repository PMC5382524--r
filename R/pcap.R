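#' @include core.R
NULL

## Principal component analysis of proteomics with a production-level overlay:
## find the direction of proteome variation most associated with bioproduct
## titer and rank the proteins driving it.

#' PCA of a proteomics matrix with production overlay
#'
#' Performs PCA on the column-centered (and by default unit-variance scaled)
#' protein abundance matrix. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are deterministic.
#'
#' @param x Numeric matrix: rows are strains/conditions, columns are proteins
#'   (dimnames recommended). No missing entries.
#' @param production Numeric vector of bioproduct titers, one per row.
#' @param k Number of components to keep (default 2).
#' @param scale Unit-variance scale the columns (default `TRUE`).
#' @param log Log-transform (`log1p`) abundances first (default `FALSE`).
#' @return A `PCAPResult` with scores (rows x k), loadings (proteins x k),
#'   explained variance fractions and the production vector.
#' @export
pcapAnalyze <- function(x, production, k = 2, scale = TRUE, log = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x))
    emufluxError("abundance matrix contains missing entries", "validationError")
  if (nrow(x) < 3)
    emufluxError("need at least 3 strains/conditions", "validationError")
  if (length(production) != nrow(x))
    emufluxError("production length must equal the number of rows",
                 "validationError")
  if (k > min(nrow(x) - 1L, ncol(x)))
    emufluxError("k exceeds min(rows - 1, proteins)", "validationError")
  if (log) x <- log1p(x)
  sds <- apply(x, 2, stats::sd)
  if (all(sds < 1e-12))
    emufluxError("abundance matrix has no variance", "degenerateVariance")
  if (scale && any(sds < 1e-12)) {
    ## constant proteins carry no information; leave them unscaled
    scale <- ifelse(sds < 1e-12, FALSE, TRUE)
    pc <- stats::prcomp(x[, , drop = FALSE], center = TRUE,
                        scale. = ifelse(sds < 1e-12, 1, sds))
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  }
  keep <- seq_len(k)
  loadings <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  flip <- vapply(keep, function(j)
    sign(loadings[which.max(abs(loadings[, j])), j]), numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  new("PCAPResult", scores = scores, loadings = loadings,
      explainedVariance = ev[keep], production = as.numeric(production),
      centers = pc$center,
      scales = if (is.logical(pc$scale) && !pc$scale)
        rep(1, ncol(x)) else as.numeric(pc$scale))
}

setMethod("show", "PCAPResult", function(object) {
  cat(sprintf("PCAPResult: %d strains x %d proteins, %d components\n",
              nrow(object@scores), nrow(object@loadings),
              ncol(object@scores)))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * object@explainedVariance),
            collapse = ", "), "\n")
})

#' Rank protein engineering targets from a PCAP analysis
#'
#' Orders proteins by loading magnitude on the component whose scores
#' correlate most with production, and reports the recommended direction of
#' change (increase or decrease expression to raise production, from the sign
#' of loading times score-production correlation).
#'
#' @param result A `PCAPResult` from [pcapAnalyze()].
#' @param component Component to use; default picks the one most correlated
#'   with production.
#' @return Data frame (protein, loading, correlation, direction), ordered by
#'   decreasing `abs(loading)`; attribute `"component"` records the component
#'   used.
#' @export
rankTargets <- function(result, component = NULL) {
  if (stats::sd(result@production) < 1e-12)
    emufluxError("production levels have zero variance", "degenerateVariance")
  ## components with zero score variance (exactly captured data) carry no
  ## production association
  cors <- suppressWarnings(
    apply(result@scores, 2, stats::cor, y = result@production))
  cors[is.na(cors)] <- 0
  j <- component %||% which.max(abs(cors))
  if (j > ncol(result@scores))
    emufluxError("component exceeds the number kept", "validationError")
  ld <- result@loadings[, j]
  ord <- order(abs(ld), decreasing = TRUE)
  out <- data.frame(protein = rownames(result@loadings)[ord] %||%
                      as.character(ord),
                    loading = ld[ord], correlation = cors[j],
                    direction = ifelse(ld[ord] * cors[j] > 0,
                                       "increase", "decrease"),
                    row.names = NULL)
  attr(out, "component") <- j
  out
}
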