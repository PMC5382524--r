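test_that("flux net/exchange decomposition follows the standard convention", {
  f <- Flux(net = 2, exchange = 0)
  expect_equal(forwardFlux(f), 2)
  expect_equal(backwardFlux(f), 0)

  f <- Flux(net = -1, exchange = 0.5)
  expect_equal(forwardFlux(f), 0.5)
  expect_equal(backwardFlux(f), 1.5)

  f <- Flux(net = 0, exchange = 3)
  expect_equal(forwardFlux(f), 3)
  expect_equal(backwardFlux(f), 3)

  expect_error(Flux(1, exchange = -0.1), class = "validationError")
})

test_that("forward/backward and net/exchange are mutually inverse", {
  set.seed(42)
  for (i in 1:50) {
    net <- rnorm(1, sd = 10); exch <- abs(rnorm(1, sd = 5))
    f <- Flux(net, exch)
    expect_equal(forwardFlux(f) - backwardFlux(f), net)
    expect_equal(min(forwardFlux(f), backwardFlux(f)), exch)
    g <- fluxFromForwardBackward(forwardFlux(f), backwardFlux(f))
    expect_equal(netFlux(g), net)
    expect_equal(exchangeFlux(g), exch)
  }
})

test_that("ranged numbers validate ordering and test containment", {
  r <- RangedNumber(0.3, 0.5, 0.6)
  expect_true(rangeContains(r, 0.5))
  expect_true(rangeContains(r, 0.3))
  expect_false(rangeContains(r, 0.61))
  expect_s4_class(RangedNumber(0.5, 0.5, 0.5), "RangedNumber")
  expect_error(RangedNumber(0.6, 0.5, 0.3), class = "validationError")
})

test_that("MDV construction normalizes and validates", {
  m <- MDV(c(0.5, 0.25, 0.25))
  expect_equal(sum(fractions(m)), 1)
  m2 <- MDV(c(2, 1, 1))
  expect_equal(fractions(m2), c(0.5, 0.25, 0.25))
  expect_error(MDV(c(0.5, -0.2, 0.7)), class = "validationError")
  expect_error(MDV(c(0, 0)), class = "validationError")
})

test_that("MDV convolution is the Cauchy product", {
  expect_equal(fractions(convolveMDV(MDV(c(1, 0)), MDV(c(0, 1)))), c(0, 1, 0))
  expect_equal(fractions(convolveMDV(MDV(c(0.5, 0.5)), MDV(c(0.5, 0.5)))),
               c(0.25, 0.5, 0.25))
  expect_equal(fractions(convolveMDV(MDV(c(0.5, 0.25, 0.25)), MDV(c(1, 0)))),
               c(0.5, 0.25, 0.25, 0))
})

test_that("convolution is commutative, associative and mass-conserving", {
  set.seed(7)
  for (i in 1:20) {
    a <- MDV(runif(3)); b <- MDV(runif(4)); c_ <- MDV(runif(2))
    expect_mdv_equal(convolveMDV(a, b), convolveMDV(b, a), tol = 1e-12)
    expect_mdv_equal(convolveMDV(convolveMDV(a, b), c_),
                     convolveMDV(a, convolveMDV(b, c_)), tol = 1e-12)
    expect_equal(sum(fractions(convolveMDV(a, b))), 1)
  }
})

test_that("elemental composition strings parse and reserialize", {
  expect_equal(parseFormula("H6NO2Si"),
               c(H = 6L, N = 1L, O = 2L, Si = 1L))
  expect_equal(parseFormula("C2H3O"), c(C = 2L, H = 3L, O = 1L))
  expect_equal(parseFormula(""), structure(integer(0), names = character(0)))
  expect_error(parseFormula("C2h"), class = "parseError")
  expect_error(parseFormula("2C"), class = "parseError")
  for (s in c("H6NO2Si", "C19H40NO4Si2", "CO2", "C6H12O6")) {
    p <- parseFormula(s)
    expect_equal(parseFormula(formulaString(p)), p)
  }
})

test_that("atom transitions enforce carbon conservation and pattern sanity", {
  expect_s4_class(AtomTransition("R1",
    data.frame(met = "A", pattern = "ab"),
    data.frame(met = "B", pattern = "ba")), "AtomTransition")
  expect_error(AtomTransition("BAD",
    data.frame(met = "A", pattern = "ab"),
    data.frame(met = "B", pattern = "abc")), "permutation")
  expect_error(AtomTransition("BAD2",
    data.frame(met = "A", pattern = "aa"),
    data.frame(met = "B", pattern = "aa")), "distinct")
})

test_that("EMU names are canonical and parse back", {
  e <- EMU("cit_c", c(5, 3, 4))
  expect_equal(emuName(e), "cit_c_3_4_5")
  expect_equal(emuSize(e), 3L)
  e2 <- emuFromName("cit_c_3_4_5")
  expect_equal(e2@metaboliteId, "cit_c")
  expect_equal(e2@indices, c(3L, 4L, 5L))
  expect_error(emuFromName("justaname"), class = "parseError")
  expect_error(EMU("x", c(1, 1)), "distinct")
})

test_that("metabolite and reaction validity catch contract violations", {
  expect_error(Metabolite("m", -1), "nonnegative")
  expect_error(Reaction("r", lowerBound = 5, upperBound = 1), "lowerBound")
  expect_error(Reaction("r", lowerBound = -5, reversible = FALSE),
               "irreversible")
  expect_error(Reaction("r", reactants = c(A = -1), products = c(B = 1)),
               "coefficients")
})
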