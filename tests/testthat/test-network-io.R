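test_that("stoichiometric matrix balances internal metabolites only", {
  mets <- list(Metabolite("A", 0, source = TRUE), Metabolite("B", 0),
               Metabolite("C", 0), Metabolite("D", 0, excreted = TRUE))
  rxns <- list(Reaction("r1", c(A = 1), c(B = 1)),
               Reaction("r2", c(B = 1), c(C = 1)),
               Reaction("r3", c(C = 1), c(D = 1)))
  S <- stoichiometricMatrix(ReactionNetwork(mets, rxns))
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(rownames(S), c("B", "C"))
  expect_equal(unname(S["B", ]), c(1, -1, 0))

  S2 <- stoichiometricMatrix(ReactionNetwork(
    list(Metabolite("A", 0), Metabolite("B", 0, excreted = TRUE)),
    list(Reaction("r", c(A = 2), c(B = 1)))))
  expect_equal(unname(S2["A", "r"]), -2)

  expect_equal(dim(stoichiometricMatrix(ReactionNetwork(list(), list()))),
               c(0L, 0L))
})

test_that("duplicate ids are rejected", {
  expect_error(ReactionNetwork(
    list(Metabolite("A", 0), Metabolite("A", 0)), list()), "duplicate")
  expect_error(ReactionNetwork(
    list(Metabolite("A", 0, source = TRUE), Metabolite("B", 0, excreted = TRUE)),
    list(Reaction("r", c(A = 1), c(B = 1)),
         Reaction("r", c(A = 1), c(B = 1)))), "duplicate")
})

test_that("SBML subset round-trips exactly", {
  net <- tcaToyNetwork()
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, f1)
  net2 <- readSBML(f1)
  expect_equal(length(metabolites(net2)), length(metabolites(net)))
  expect_equal(length(reactions(net2)), length(reactions(net)))
  expect_identical(stoichiometricMatrix(net2), stoichiometricMatrix(net))
  expect_identical(emuflux:::fluxBounds(net2), emuflux:::fluxBounds(net))
  expect_identical(emuflux:::carbonCounts(net2), emuflux:::carbonCounts(net))
  expect_identical(
    vapply(metabolites(net2), function(m) m@source, logical(1)),
    vapply(metabolites(net), function(m) m@source, logical(1)))
  writeSBML(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed SBML raises a parse error; missing bounds warn", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeSBML(chainToyNetwork(), f)
  truncated <- withr::local_tempfile(fileext = ".xml")
  writeLines(head(readLines(f), 8), truncated)
  expect_error(readSBML(truncated), class = "parseError")

  nobounds <- withr::local_tempfile(fileext = ".xml")
  lines <- readLines(f)
  writeLines(grep("_BOUND", lines, invert = TRUE, value = TRUE), nobounds)
  expect_warning(net <- readSBML(nobounds), "defaults")
  b <- emuflux:::fluxBounds(net)
  expect_equal(unname(b$lb[["r1"]]), 0)
  expect_equal(unname(b$ub[["r1"]]), 1000)
})

test_that("atom-transition files parse, validate and round-trip", {
  trans <- parseAtomTransitions(text = "R1\tA(ab) --> B(ab)")
  expect_length(trans, 1)
  expect_equal(trans[[1]]@reactants$pattern, "ab")
  expect_equal(trans[[1]]@weight, 1)

  cs <- parseAtomTransitions(
    text = "CS\taccoa(ab) + oac(cdef) --> cit(fedbac)")[[1]]
  expect_equal(cs@reactants$met, c("accoa", "oac"))
  expect_equal(cs@products$pattern, "fedbac")

  expect_error(parseAtomTransitions(text = "BAD\tA(ab) --> B(abc)"),
               "permutation")
  expect_error(parseAtomTransitions(text = "NOTAB A(ab) --> B(ab)"),
               class = "parseError")

  ## symmetric duplicates get equal fractional weights
  dup <- parseAtomTransitions(text = c("v5\tsuc(abcd) --> fum(abcd)",
                                       "v5\tsuc(abcd) --> fum(dcba)"))
  expect_equal(vapply(dup, function(t) t@weight, numeric(1)), c(0.5, 0.5))

  f <- withr::local_tempfile()
  net <- tcaToyNetwork()
  writeAtomTransitions(net@transitions, f)
  again <- parseAtomTransitions(f)
  expect_equal(lapply(again, function(t) t@reactants),
               lapply(net@transitions, function(t) t@reactants))
  expect_equal(lapply(again, function(t) t@products),
               lapply(net@transitions, function(t) t@products))
})

test_that("carbon-transition consistency checker reports defects", {
  expect_length(carbonTransitionsOK(tcaToyNetwork()), 0)

  mets <- list(Metabolite("A", 2, source = TRUE), Metabolite("B", 2),
               Metabolite("X", 2, excreted = TRUE))
  rxns <- list(Reaction("r1", c(A = 1), c(B = 1)),
               Reaction("r2", c(B = 1), c(X = 1)))
  ## transition names a product absent from the reaction
  bad <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = c("r1\tA(ab) --> X(ab)",
                                  "r2\tB(ab) --> X(ab)")),
    validate = FALSE)
  reports <- carbonTransitionsOK(bad)
  expect_true(any(grepl("r1", reports) & grepl("X", reports)))

  ## carbon-bearing internal metabolite produced by no transition
  missing <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = "r2\tB(ab) --> X(ab)"),
    validate = FALSE)
  reports2 <- carbonTransitionsOK(missing)
  expect_true(any(grepl("'B'", reports2)))

  ## wrong pattern length against the metabolite's carbon count
  shortPat <- C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = c("r1\tA(a) --> B(a)",
                                  "r2\tB(ab) --> X(ab)")),
    validate = FALSE)
  expect_true(any(grepl("carbons", carbonTransitionsOK(shortPat))))

  ## the constructor enforces consistency by default
  expect_error(C13ReactionNetwork(ReactionNetwork(mets, rxns),
    parseAtomTransitions(text = "r1\tA(ab) --> X(ab)")),
    class = "carbonBalanceError")
})

test_that("labeling CSV reading validates, normalizes and floors errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fragment,m0,m1,m2,m3,m4,m5,sd0,sd1,sd2,sd3,sd4,sd5",
               "glu_12345,0.25,0.25,0.25,0.25,0,0,0.01,0.01,0.01,0.01,0.01,0.001"),
             f)
  meas <- readLabelingCSV(f)
  expect_length(meas, 1)
  expect_equal(length(fractions(meas[[1]]$mdv)), 6)
  expect_equal(mdvErrors(meas[[1]]$mdv)[6], 0.003)  # floored

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fragment,m0,m1,sd0,sd1", "x_1,0.48,0.44,0.01,0.01"), f2)
  expect_warning(m2 <- readLabelingCSV(f2), "normalizing")
  expect_equal(sum(fractions(m2[[1]]$mdv)), 1)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fragment,m0,m1,m2,sd0,sd1,sd2", "glu_12345,0.5,0.25,0.25,0,0,0"),
             f3)
  expect_error(readLabelingCSV(f3), class = "validationError")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fragment,m0,m1,sd0,sd1", "x_1,abc,0.5,0.01,0.01"), f4)
  expect_error(suppressWarnings(readLabelingCSV(f4)), class = "parseError")
})

test_that("feed CSV round-trips and validates fraction sums", {
  feed <- list(accoa = data.frame(mask = c("00", "01", "11"),
                                  fraction = c(0.5, 0.25, 0.25)),
               asp = data.frame(mask = "0000", fraction = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeedCSV(feed, f)
  feed2 <- readFeedCSV(f)
  expect_equal(feed2[order(names(feed2))], feed[order(names(feed))])

  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("metabolite,mask,fraction", "glc,10,0.5", "glc,01,0.4"), fbad)
  expect_error(readFeedCSV(fbad), class = "validationError")
})

test_that("fragment names map to EMUs", {
  e <- fragmentEMU("glu_12345")
  expect_equal(e@metaboliteId, "glu")
  expect_equal(e@indices, 1:5)
  expect_equal(fragmentEMU("fum_c_24")@indices, c(2L, 4L))
  expect_equal(fragmentEMU("fum_c_24")@metaboliteId, "fum_c")
  expect_error(fragmentEMU("nodigits"), class = "parseError")
})
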