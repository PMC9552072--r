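test_that("formula parsing handles plain and subscripted forms and round-trips", {
  expect_equal(parseFormula("C26H31O14"), c(C = 26L, H = 31L, O = 14L))
  expect_equal(parseFormula("C_26_H_31_O_14_"), c(C = 26L, H = 31L, O = 14L))
  expect_equal(parseFormula("H2O"), c(H = 2L, O = 1L))
  expect_equal(formatFormula(parseFormula("O14C26H31")), "C26H31O14")

  # format(parse(s)) is canonical and parse(format(c)) == c
  t1 <- mulberrosideMetabolites()
  for (f in unique(t1$ion_formula)) {
    comp <- parseFormula(f)
    expect_identical(formatFormula(comp), f)
    expect_equal(parseFormula(formatFormula(comp))[names(comp)], comp)
  }
})

test_that("formula parsing rejects malformed input", {
  expect_error(parseFormula("C26Hx"), "unknown element|malformed")
  expect_error(parseFormula(""), "empty")
  expect_error(parseFormula("Xy12"), "unknown element|malformed")
  expect_error(parseFormula("C0H2"), "positive")
})

test_that("monoisotopic mass is correct and linear in composition", {
  expect_equal(monoisotopicMass("C6H10O5"), 162.0528, tolerance = 1e-4)
  expect_equal(monoisotopicMass("SO3"), 79.9568, tolerance = 1e-4)
  expect_equal(monoisotopicMass(integer(0)), 0)

  set.seed(42)
  els <- c("C", "H", "N", "O", "S")
  for (i in 1:25) {
    a <- setNames(sample(0:20, 5, replace = TRUE), els)
    b <- setNames(sample(0:20, 5, replace = TRUE), els)
    expect_equal(monoisotopicMass(a) + monoisotopicMass(b),
                 monoisotopicMass(a + b), tolerance = 1e-9)
  }
})

test_that("ion m/z follows the reported-value electron-mass convention", {
  expect_equal(round(ionMz("C26H31O14", "negative"), 4), 567.1708)
  expect_equal(round(ionMz("C14H11O4", "negative"), 4), 243.0652)
  # the physically correct anion mass is two electron masses heavier
  d <- ionMz("C14H11O4", "negative", convention = "physical") -
    ionMz("C14H11O4", "negative", convention = "reported")
  expect_equal(d, 2 * 0.00054858, tolerance = 1e-6)
  # positive-ion m/z is identical under both conventions
  expect_equal(ionMz("C26H33O14", "positive", convention = "physical"),
               ionMz("C26H33O14", "positive", convention = "reported"))
  expect_error(ionMz("C26H31O14", charge = 2L), "singly charged")
})

test_that("reported theoretical masses reproduce for all consistent reference rows", {
  t1 <- mulberrosideMetabolites()
  consistent <- !grepl("mass", t1$inconsistent)
  expect_gte(sum(consistent), 69)
  for (i in which(consistent)) {
    expect_equal(round(ionMz(t1$ion_formula[i], "negative"), 4),
                 t1$theoretical_mz[i],
                 info = t1$peak_id[i])
  }
})

test_that("RDB equivalents match the reference table for every row", {
  expect_equal(rdbEquivalent("C26H31O14"), 11.5)
  expect_equal(rdbEquivalent("C14H13O7S"), 8.5)
  expect_equal(rdbEquivalent("C6H14"), 0)
  t1 <- mulberrosideMetabolites()
  expect_equal(vapply(t1$ion_formula, rdbEquivalent, numeric(1),
                      USE.NAMES = FALSE),
               t1$rdb)
})

test_that("ppm error has the documented sign convention", {
  expect_equal(ppmError(567.1707, 567.1708), -0.176, tolerance = 0.01)
  expect_equal(ppmError(243.0651, 243.0652), -0.41, tolerance = 0.01)
  expect_equal(ppmError(500, 500), 0)
  expect_error(ppmError(100, 0), "positive")

  # recomputed errors agree with printed errors within 0.5 ppm, and the
  # sign matches whenever |printed| > 0.3 ppm (consistent rows only)
  t1 <- mulberrosideMetabolites()
  t1 <- t1[!nzchar(t1$inconsistent), ]
  err <- ppmError(t1$experimental_mz, t1$theoretical_mz)
  expect_true(all(abs(err - t1$error_ppm) <= 0.5))
  big <- abs(t1$error_ppm) > 0.3
  expect_true(all(sign(err[big]) == sign(t1$error_ppm[big])))
})

test_that("formula constraints flag out-of-range elements and RDB", {
  cc <- formulaConstraints()
  expect_true(checkConstraints("C26H31O14", cc)$pass)
  expect_true(checkConstraints("C20H21O13S", cc)$pass)
  res <- checkConstraints("C4H5O2", cc)
  expect_false(res$pass)
  expect_match(res$violations, "C=4", all = FALSE)
  expect_false(checkConstraints(c(C = 20L, H = 20L, O = 5L, S = 3L), cc)$pass)
})

test_that("composition deltas apply element-wise and refuse negatives", {
  out <- composeFormula("C26H31O14", -parseFormula("C6H10O5"))
  expect_equal(formatFormula(out), "C20H21O9")
  x <- parseFormula("C14H11O4")
  expect_equal(composeFormula(x, integer(0)), x)
  expect_error(composeFormula("C14H11O4", -parseFormula("C6H10O5")),
               "not applicable")
})
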