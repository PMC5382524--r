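#' @include core.R
NULL

#' Carbon atom transition for a reaction
#'
#' Records the fate of each carbon atom in a reaction as letter patterns, e.g.
#' citrate synthase `accoa(ab) + oac(cdef) --> cit(fedbac)`. The multiset of
#' letters on the product side must be a permutation of the reactant side
#' (carbon conservation). Symmetric molecules (succinate, fumarate) are handled
#' by emitting duplicate transitions for one reaction, each carrying a
#' fractional `weight`; weights for a reaction sum to 1.
#'
#' @param reactionId Reaction this transition belongs to.
#' @param reactants,products Data frames with columns `met` (metabolite id) and
#'   `pattern` (lowercase letter string, one letter per carbon). A list of
#'   `c(met, pattern)` character pairs is also accepted.
#' @param weight Fractional weight in (0, 1]; 1 unless the reaction carries
#'   duplicate rows for a symmetric molecule.
#' @return An `AtomTransition` object.
#' @examples
#' AtomTransition("CS",
#'   reactants = data.frame(met = c("accoa", "oac"), pattern = c("ab", "cdef")),
#'   products  = data.frame(met = "cit", pattern = "fedbac"))
#' @export
AtomTransition <- function(reactionId, reactants, products, weight = 1) {
  asSide <- function(x) {
    if (is.data.frame(x)) {
      data.frame(met = as.character(x$met), pattern = as.character(x$pattern),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(met = vapply(x, `[`, character(1), 1),
                 pattern = vapply(x, `[`, character(1), 2),
                 stringsAsFactors = FALSE)
    }
  }
  new("AtomTransition", reactionId = reactionId, reactants = asSide(reactants),
      products = asSide(products), weight = weight)
}

setMethod("show", "AtomTransition", function(object) {
  fmt <- function(side)
    paste(sprintf("%s(%s)", side$met, side$pattern), collapse = " + ")
  cat(sprintf("%s\t%s --> %s", object@reactionId, fmt(object@reactants),
              fmt(object@products)))
  if (object@weight != 1) cat(sprintf("   [weight %g]", object@weight))
  cat("\n")
})

#' Elementary metabolite unit
#'
#' An EMU is a distinct subset of a metabolite's carbon atoms, e.g. carbons
#' 3-5 of citrate. Carbon positions are 1-based; the canonical name appends
#' the ascending indices to the metabolite id: `"cit_c_3_4_5"`.
#'
#' @param metaboliteId Metabolite id.
#' @param indices Integer vector of distinct 1-based carbon positions (sorted
#'   on construction).
#' @return An `EMU` object.
#' @examples
#' emuName(EMU("cit_c", c(5, 3, 4)))  # "cit_c_3_4_5"
#' @export
EMU <- function(metaboliteId, indices) {
  new("EMU", metaboliteId = metaboliteId,
      indices = sort(as.integer(indices)))
}

#' @describeIn EMU canonical name, metabolite id plus ascending indices
#' @param x An `EMU`.
#' @export
setMethod("emuName", "EMU", function(x)
  paste(c(x@metaboliteId, x@indices), collapse = "_"))

#' @describeIn EMU number of carbons in the unit
#' @export
setMethod("emuSize", "EMU", function(x) length(x@indices))

setMethod("show", "EMU", function(object)
  cat("EMU", emuName(object), "\n"))

#' Parse a canonical EMU name
#'
#' Splits a name like `"cit_c_3_4_5"` into metabolite id (`"cit_c"`) and carbon
#' indices by stripping trailing `_<number>` groups, so metabolite ids that
#' contain underscores are handled.
#'
#' @param name Canonical EMU name.
#' @return An `EMU` object.
#' @export
emuFromName <- function(name) {
  parts <- strsplit(name, "_")[[1]]
  isNum <- grepl("^[0-9]+$", parts)
  k <- length(parts)
  while (k >= 1L && isNum[k]) k <- k - 1L
  if (k == length(parts) || k == 0L)
    emufluxError(sprintf("'%s' is not a canonical EMU name", name),
                 "parseError")
  EMU(paste(parts[seq_len(k)], collapse = "_"),
      as.integer(parts[seq(k + 1L, length(parts))]))
}

#' EMU-level image of an atom transition
#'
#' Describes how source EMUs map onto a target EMU for one direction of a
#' reaction: a single source is a transfer, two or more sources condense (their
#' MDVs convolve).
#'
#' @param reactionId Reaction id.
#' @param direction `"forward"` or `"backward"` (backward only for reversible
#'   reactions); selects the directional flux weighting the transition.
#' @param sources List of source `EMU`s.
#' @param target Target `EMU`; source sizes must sum to the target size.
#' @param weight Weight inherited from the atom transition (symmetry handling).
#' @return An `EMUTransition` object.
#' @export
EMUTransition <- function(reactionId, direction, sources, target, weight = 1) {
  new("EMUTransition", reactionId = reactionId, direction = direction,
      sources = sources, target = target, weight = weight)
}

setMethod("show", "EMUTransition", function(object) {
  cat(sprintf("%s (%s%s): %s --> %s\n", object@reactionId,
              object@direction,
              if (object@weight != 1) sprintf(", w=%g", object@weight) else "",
              paste(vapply(object@sources, emuName, character(1)),
                    collapse = " + "),
              emuName(object@target)))
})

#' Parse an atom-transition file
#'
#' Each non-blank, non-comment (`#`) line has the form
#' `"<reaction_id>\t<reactants> --> <products>"` where each side lists
#' `met(pattern)` terms joined by `+`, e.g.
#' `"CS\taccoa(ab) + oac(cdef) --> cit(fedbac)"`. Repeated lines for one
#' reaction encode symmetric-molecule scrambling and receive equal fractional
#' weights.
#'
#' @param path Path to the file, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return List of [AtomTransition] objects.
#' @export
parseAtomTransitions <- function(path, text = NULL) {
  lines <- text %||% readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parseSide <- function(s, where) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    m <- regmatches(terms, regexec("^([^()[:space:]]+)\\(([a-z]+)\\)$", terms))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
      emufluxError(sprintf("cannot parse pattern term '%s' in '%s'",
                           terms[bad][1], where), "parseError")
    data.frame(met = vapply(m, `[`, character(1), 2),
               pattern = vapply(m, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  }
  parsed <- lapply(lines, function(ln) {
    halves <- strsplit(ln, "\t")[[1]]
    if (length(halves) < 2L)
      emufluxError(sprintf("missing tab separator in line '%s'", ln),
                   "parseError")
    rid <- trimws(halves[1])
    body <- trimws(paste(halves[-1], collapse = " "))
    sides <- strsplit(body, "-->", fixed = TRUE)[[1]]
    if (length(sides) != 2L)
      emufluxError(sprintf("expected a single '-->' in line '%s'", ln),
                   "parseError")
    list(rid = rid, r = parseSide(sides[1], ln), p = parseSide(sides[2], ln))
  })
  rids <- vapply(parsed, `[[`, character(1), "rid")
  lapply(seq_along(parsed), function(i) {
    w <- 1 / sum(rids == rids[i])
    AtomTransition(rids[i], parsed[[i]]$r, parsed[[i]]$p, weight = w)
  })
}

#' Write atom transitions in the canonical text dialect
#'
#' @param transitions List of [AtomTransition] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAtomTransitions <- function(transitions, path) {
  fmt <- function(side)
    paste(sprintf("%s(%s)", side$met, side$pattern), collapse = " + ")
  lines <- vapply(transitions, function(tr)
    sprintf("%s\t%s --> %s", tr@reactionId, fmt(tr@reactants),
            fmt(tr@products)), character(1))
  writeLines(lines, path)
  invisible(path)
}

## validate a transition's patterns against metabolite carbon counts
checkTransitionPatterns <- function(tr, carbonsOf) {
  msgs <- character(0)
  for (side in list(tr@reactants, tr@products)) {
    for (i in seq_len(nrow(side))) {
      met <- side$met[i]
      if (!met %in% names(carbonsOf)) {
        msgs <- c(msgs, sprintf(
          "reaction '%s': transition names unknown metabolite '%s'",
          tr@reactionId, met))
      } else if (nchar(side$pattern[i]) != carbonsOf[[met]]) {
        msgs <- c(msgs, sprintf(
          "reaction '%s': pattern '%s' for '%s' has %d letters but the metabolite has %d carbons",
          tr@reactionId, side$pattern[i], met, nchar(side$pattern[i]),
          carbonsOf[[met]]))
      }
    }
  }
  msgs
}
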