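#' @include reaction-network.R
NULL

## SBML subset I/O. Output is SBML Level 2 Version 1 with COBRA-style
## notes-encoded bounds and objective coefficients; carbon counts travel in a
## CARBONS note on each species. On input, fbc attribute bounds
## (fbc:lowerFluxBound referencing listOfParameters) are also accepted.
## Kinetic laws, events and rules are out of scope.

SBML_NS <- "http://www.sbml.org/sbml/level2"

#' Read a reaction network from an SBML file
#'
#' Supports the SBML Level 2/3 core subset used for constraint-based models:
#' species (with `boundaryCondition` marking source/excreted metabolites),
#' reactions with stoichiometry and reversibility, and flux bounds either in
#' COBRA-style notes (`LOWER_BOUND`, `UPPER_BOUND`, `OBJECTIVE_COEFFICIENT`)
#' or as fbc attributes referencing parameters. Missing bounds default to
#' `[0, 1000]` (irreversible) or `[-1000, 1000]` (reversible) with a warning.
#' Carbon counts are taken from a `CARBONS:` note or from a `FORMULA:` note /
#' fbc chemical formula.
#'
#' @param path Path to the SBML file.
#' @return A [ReactionNetwork].
#' @export
readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    emufluxError(sprintf("malformed SBML file '%s': %s", path,
                         conditionMessage(e)), "parseError"))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model)))
    emufluxError("no <model> element found", "parseError")

  noteField <- function(node, key) {
    ps <- xml2::xml_find_all(node, ".//notes//*")
    txts <- trimws(vapply(ps, xml2::xml_text, character(1)))
    hit <- grep(paste0("^", key, ":"), txts, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }

  params <- new.env()
  for (p in xml2::xml_find_all(model, ".//listOfParameters/parameter")) {
    id <- xml2::xml_attr(p, "id")
    if (!is.na(id)) assign(id, as.numeric(xml2::xml_attr(p, "value")), params)
  }

  mets <- lapply(xml2::xml_find_all(model, ".//listOfSpecies/species"),
    function(sp) {
      id <- xml2::xml_attr(sp, "id")
      boundary <- identical(xml2::xml_attr(sp, "boundaryCondition"), "true")
      carbons <- 0L
      cNote <- noteField(sp, "CARBONS")
      if (!is.na(cNote)) {
        carbons <- as.integer(cNote)
      } else {
        formula <- noteField(sp, "FORMULA")
        if (is.na(formula))
          formula <- xml2::xml_attr(sp, "chemicalFormula")
        if (!is.na(formula) && nzchar(formula)) {
          cf <- parseFormula(formula)
          if ("C" %in% names(cf)) carbons <- cf[["C"]]
        }
      }
      role <- noteField(sp, "ROLE")
      Metabolite(id, carbons,
                 name = xml2::xml_attr(sp, "name") %||% id,
                 compartment = xml2::xml_attr(sp, "compartment") %||% "",
                 source = if (!is.na(role)) role == "source" else FALSE,
                 excreted = if (!is.na(role)) role == "excreted" else boundary)
    })

  rxnNodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  missingBounds <- character(0)
  rxns <- lapply(rxnNodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    reversible <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    readSide <- function(which) {
      refs <- xml2::xml_find_all(rn, paste0(".//", which, "/speciesReference"))
      if (!length(refs)) return(numeric(0))
      v <- vapply(refs, function(s) {
        st <- xml2::xml_attr(s, "stoichiometry")
        if (is.na(st)) 1 else as.numeric(st)
      }, numeric(1))
      names(v) <- vapply(refs, xml2::xml_attr, character(1), "species")
      c(tapply(v, names(v), sum)[unique(names(v))])
    }
    boundFrom <- function(key, fbcAttr) {
      noteVal <- noteField(rn, key)
      if (!is.na(noteVal)) return(as.numeric(noteVal))
      ref <- xml2::xml_attr(rn, fbcAttr)
      if (!is.na(ref) && exists(ref, params)) return(get(ref, params))
      NA_real_
    }
    lb <- boundFrom("LOWER_BOUND", "lowerFluxBound")
    ub <- boundFrom("UPPER_BOUND", "upperFluxBound")
    if (is.na(lb) || is.na(ub)) missingBounds <<- c(missingBounds, id)
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000
    obj <- noteField(rn, "OBJECTIVE_COEFFICIENT")
    Reaction(id, reactants = readSide("listOfReactants"),
             products = readSide("listOfProducts"),
             reversible = reversible, lowerBound = lb, upperBound = ub,
             objectiveCoefficient = if (is.na(obj)) 0 else as.numeric(obj))
  })
  if (length(missingBounds))
    warning(sprintf("no bounds found for reaction(s) %s; using defaults",
                    paste(missingBounds, collapse = ", ")))
  ReactionNetwork(mets, rxns)
}

#' Write a reaction network to an SBML file
#'
#' Emits the Level 2 subset read back identically by [readSBML()]:
#' notes-encoded bounds, objective coefficients, carbon counts and
#' source/excreted roles.
#'
#' @param network A [ReactionNetwork].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSBML <- function(network, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  notes <- function(fields) {
    body <- paste(sprintf("        <html:p>%s: %s</html:p>",
                          names(fields), fields), collapse = "\n")
    sprintf("      <notes>\n%s\n      </notes>", body)
  }
  compartments <- unique(vapply(network@metabolites,
                                function(m) m@compartment, character(1)))
  compartments[!nzchar(compartments)] <- "default"
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" ",
                   "xmlns:html=\"http://www.w3.org/1999/xhtml\" ",
                   "level=\"2\" version=\"1\">"), SBML_NS),
    "  <model id=\"model\">",
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\"/>", unique(compartments)),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (m in network@metabolites) {
    role <- if (m@source) "source" else if (m@excreted) "excreted" else "internal"
    comp <- if (nzchar(m@compartment)) m@compartment else "default"
    lines <- c(lines, sprintf(
      "      <species id=\"%s\" name=\"%s\" compartment=\"%s\" boundaryCondition=\"%s\">",
      esc(m@id), esc(m@name), esc(comp),
      if (m@source || m@excreted) "true" else "false"),
      notes(c(CARBONS = m@carbons, ROLE = role)),
      "      </species>")
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  side <- function(v, tag) {
    if (!length(v)) return(character(0))
    c(sprintf("        <%s>", tag),
      sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\"/>",
              esc(names(v)), format(unname(v), digits = 15)),
      sprintf("        </%s>", tag))
  }
  for (r in network@reactions) {
    lines <- c(lines, sprintf(
      "      <reaction id=\"%s\" reversible=\"%s\">",
      esc(r@id), if (r@reversible) "true" else "false"),
      notes(c(LOWER_BOUND = format(r@lowerBound, digits = 15),
              UPPER_BOUND = format(r@upperBound, digits = 15),
              OBJECTIVE_COEFFICIENT = format(r@objectiveCoefficient,
                                             digits = 15))),
      side(r@reactants, "listOfReactants"),
      side(r@products, "listOfProducts"),
      "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
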