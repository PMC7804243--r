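# Formula arithmetic, mass computation and constrained enumeration.

test_that("monoisotopic masses and m/z follow the anion convention", {
  expect_equal(monoisotopic_mass(chem_formula()), 0)

  # independent sum from the reference constants (N + 3 O + electron)
  mc <- mass_constants()
  no3_expected <- mc$elements[["N"]] + 3 * mc$elements[["O"]] + mc$electron
  no3 <- parse_formula("NO3-")
  expect_equal(mz(no3), no3_expected, tolerance = 1e-12)
  expect_equal(mz(no3), 61.98837, tolerance = 1e-7)

  # electron-exclusive convention differs by exactly one electron mass
  expect_equal(mz(no3) - mz(no3, include_electron = FALSE), mc$electron)

  # reported precursor adduct within the 5 ppm matching window
  expect_lt(abs(ppm_error(mz(parse_formula("C10H15NO11-")), 325.0644)), 5)
  expect_lt(abs(ppm_error(mz(parse_formula("C9H11O2-")), 151.0764)), 5)

  expect_error(mz(parse_formula("O2")), "no m/z")
})

test_that("subtraction derives neutral losses and round-trips", {
  parent <- parse_formula("C10H15NO11-")
  o2 <- formula_subtract(parent, parse_formula("C10H15NO9-"))
  expect_identical(format(o2), "O2")
  expect_equal(formula_charge(o2), 0L)

  h2no4 <- formula_subtract(parse_formula("C10H15NO9-"),
                            parse_formula("C10H13O5-"))
  expect_identical(format(h2no4), format(parse_formula("H2NO4")))

  expect_identical(format(parent - parent), "(empty)")
  expect_error(formula_subtract(parse_formula("CH4"), parse_formula("O2")),
               "not a sub-formula")

  # subtract then add back reproduces the parent composition
  set.seed(41)
  for (i in 1:25) {
    a <- random_formula()
    b <- chem_formula(sample(0:a[["C"]], 1), sample(0:a[["H"]], 1),
                      sample(0:a[["N"]], 1), sample(0:a[["O"]], 1))
    back <- formula_add(formula_subtract(a, b), b)
    expect_equal(unclass(back)[1:4], unclass(a)[1:4])
  }
})

test_that("mass is conserved across parent = product + loss", {
  set.seed(42)
  for (i in 1:20) {
    parent <- chem_formula(sample(5:20, 1), sample(5:40, 1), sample(0:2, 1),
                           sample(2:20, 1), charge = -1L)
    prod <- chem_formula(sample(0:parent[["C"]], 1), sample(0:parent[["H"]], 1),
                         sample(0:parent[["N"]], 1), sample(0:parent[["O"]], 1),
                         charge = -1L)
    loss <- formula_subtract(parent, prod)
    expect_equal(monoisotopic_mass(parent),
                 monoisotopic_mass(prod) + monoisotopic_mass(loss),
                 tolerance = 1e-12)
  }
})

test_that("ppm error is signed and relative to the theoretical mass", {
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(ppm_error(100, 100.0005), 5)
  expect_equal(ppm_error(325.0651, 325.0644), -2.1, tolerance = 0.05)
})

test_that("RDBE handles saturated, aromatic and adduct compositions", {
  expect_equal(rdbe(parse_formula("CH4")), 0)
  expect_equal(rdbe(parse_formula("C6H6")), 4)
  expect_equal(rdbe(parse_formula("C10H15NO11-")), 4)
  expect_equal(rdbe(parse_formula("HO")), 0.5)  # half-integer permitted
})

test_that("formula strings parse in combined and adduct spellings", {
  combined <- parse_formula("C10H15NO11-")
  adducted <- parse_formula("C10H15O8.NO3-")
  expect_true(combined == adducted)
  expect_identical(format(adducted), "C10H15NO11-")
  expect_identical(format(adducted, style = "adduct"), "C10H15O8.NO3-")
  rad <- parse_formula("C10H15NO11*-")
  expect_true(attr(rad, "radical"))
  set.seed(43)
  for (i in 1:20) {
    f <- random_formula()
    expect_true(parse_formula(format(f)) == f)
  }
})

test_that("formula enumeration finds reported ions and respects bounds", {
  hits <- enumerate_formulas(61.9884)
  expect_true("NO3-" %in% hits$formula)

  hits <- enumerate_formulas(325.0644)
  expect_identical(hits$formula[1], "C10H15NO11-")

  expect_equal(nrow(enumerate_formulas(5.0)), 0L)

  b <- enumeration_bounds()
  set.seed(44)
  for (m in stats::runif(8, 60, 600)) {
    res <- enumerate_formulas(m, b)
    if (nrow(res) == 0) next
    expect_true(all(res$C >= b$c[1] & res$C <= b$c[2]))
    expect_true(all(res$H >= b$h[1] & res$H <= b$h[2]))
    expect_true(all(res$N <= 2))
    expect_true(all(res$O >= b$o[1] & res$O <= b$o[2]))
    expect_true(all(res$rdbe >= b$rdbe[1] & res$rdbe <= b$rdbe[2]))
    # recomputed ppm of every candidate stays inside the tolerance
    recomputed <- vapply(res$formula,
                         function(f) ppm_error(mz(parse_formula(f)), m),
                         numeric(1))
    expect_true(all(abs(recomputed) <= b$tol_ppm))
    expect_false(is.unsorted(abs(res$ppm)))
  }
})

test_that("enumeration agrees with the exhaustive nested-loop oracle", {
  for (m in c(61.9884, 213.0766, 325.0644)) {
    expect_identical(sort(enumerate_formulas(m)$formula),
                     brute_force_formulas(m))
  }
})
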