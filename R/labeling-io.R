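#' @include reaction-network.R
NULL

#' Read a labeling-measurement CSV
#'
#' Expected columns: `fragment`, then the mass fractions `m0..mk`, then the
#' standard deviations `sd0..sdk`. Each row becomes a fragment/MDV pair. Rows
#' whose fractions deviate from sum 1 by more than 0.05 trigger a warning
#' before normalization. Reported standard deviations are floored at
#' `sdFloor` (default 0.003, typical MS precision) to avoid zero-weight
#' divisions in fitting.
#'
#' @param path CSV file path.
#' @param sdFloor Lower bound applied to the standard deviations.
#' @return List of `list(fragment = <name>, mdv = <MDV>)` entries.
#' @export
readLabelingCSV <- function(path, sdFloor = 0.003) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  mCols <- grep("^m[0-9]+$", names(df), value = TRUE)
  sdCols <- grep("^sd[0-9]+$", names(df), value = TRUE)
  if (!"fragment" %in% names(df) || !length(mCols))
    emufluxError("labeling CSV needs 'fragment' and m0.. columns",
                 "parseError")
  lapply(seq_len(nrow(df)), function(i) {
    frac <- as.numeric(df[i, mCols])
    if (any(is.na(frac)))
      emufluxError(sprintf("non-numeric mass fraction in row %d", i),
                   "parseError")
    frag <- df$fragment[i]
    nPos <- nchar(sub("^.*_", "", frag))
    if (length(frac) != nPos + 1L)
      emufluxError(sprintf(
        "row %d: fragment '%s' measures %d carbons but has %d fractions",
        i, frag, nPos, length(frac)), "validationError")
    if (abs(sum(frac) - 1) > 0.05)
      warning(sprintf("row %d ('%s'): fractions sum to %.3f; normalizing",
                      i, frag, sum(frac)))
    sds <- if (length(sdCols)) pmax(as.numeric(df[i, sdCols]), sdFloor)
           else rep(sdFloor, length(frac))
    list(fragment = frag, mdv = MDV(frac, errors = sds))
  })
}

#' Write labeling measurements to CSV
#'
#' @param measurements List of `list(fragment, mdv)` entries (equal fragment
#'   sizes are not required; shorter rows are padded with `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLabelingCSV <- function(measurements, path) {
  kmax <- max(vapply(measurements,
                     function(m) length(fractions(m$mdv)), integer(1)))
  pad <- function(v) c(v, rep(NA, kmax - length(v)))
  rows <- lapply(measurements, function(m) {
    sds <- mdvErrors(m$mdv)
    if (!length(sds)) sds <- rep(0, length(fractions(m$mdv)))
    c(list(fragment = m$fragment),
      as.list(pad(fractions(m$mdv))), as.list(pad(sds)))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  names(df) <- c("fragment", paste0("m", seq_len(kmax) - 1L),
                 paste0("sd", seq_len(kmax) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feed-labeling CSV
#'
#' Columns `metabolite, mask, fraction`: each row contributes a positional
#' isotopomer (mask `"01"` means carbon 2 labeled) with its mixture fraction.
#' Fractions must sum to 1 per metabolite.
#'
#' @param path CSV file path.
#' @return Named list of data frames (`mask`, `fraction`) per metabolite, the
#'   feed format of [C13ReactionNetwork()].
#' @export
readFeedCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(metabolite = "character",
                                       mask = "character",
                                       fraction = "numeric"),
                        strip.white = TRUE)
  feed <- lapply(split(df, df$metabolite), function(d)
    data.frame(mask = d$mask, fraction = d$fraction,
               stringsAsFactors = FALSE))
  for (m in names(feed))
    if (abs(sum(feed[[m]]$fraction) - 1) > 1e-6)
      emufluxError(sprintf("feed fractions for '%s' sum to %g, not 1",
                           m, sum(feed[[m]]$fraction)), "validationError")
  feed
}

#' Write a feed-labeling CSV
#'
#' @param feed Named list of data frames (`mask`, `fraction`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeedCSV <- function(feed, path) {
  df <- do.call(rbind, lapply(names(feed), function(m)
    data.frame(metabolite = m, mask = feed[[m]]$mask,
               fraction = feed[[m]]$fraction)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parse a fragment name into its EMU
#'
#' Fragment names use the `"<met>_<positions>"` convention: `"glu_12345"` is
#' carbons 1-5 of glutamate.
#'
#' @param name Fragment name.
#' @return An [EMU].
#' @export
fragmentEMU <- function(name) {
  pos <- sub("^.*_", "", name)
  met <- sub("_[0-9]+$", "", name)
  if (!grepl("^[0-9]+$", pos))
    emufluxError(sprintf("'%s' is not a '<met>_<positions>' fragment name",
                         name), "parseError")
  EMU(met, as.integer(strsplit(pos, "")[[1]]))
}
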