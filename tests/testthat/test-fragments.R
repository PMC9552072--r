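test_that("loss library carries exact and nominal masses for both polarities", {
  lib <- defaultLossLibrary()
  nom <- setNames(lib$nominal, lib$name)
  expect_equal(nom[["Glu"]], 162L)
  expect_equal(nom[["GluA"]], 176L)
  expect_equal(nom[["SO3"]], 80L)
  expect_equal(nom[["CH2O"]], 30L)
  expect_equal(lib$exact_mass[lib$name == "C3O2"], 67.9898,
               tolerance = 1e-4)
  # exact mass always equals the monoisotopic mass of the loss formula
  expect_equal(lib$exact_mass,
               vapply(lib$formula, monoisotopicMass, numeric(1),
                      USE.NAMES = FALSE))
  expect_false("C6H6O2" %in% lib$name)
  expect_true("C6H6O2" %in% defaultLossLibrary("positive")$name)
})

test_that("neutral-loss ladders are assigned greedily from the precursor down", {
  one <- assignNeutralLosses(567.1695, 405.12)
  expect_equal(one$loss, "Glu")
  expect_equal(one$nominal, 162L)

  ladder <- assignNeutralLosses(583.1658, c(421.1129, 245.0813))
  expect_equal(ladder$loss, c("Glu", "GluA"))
  expect_equal(ladder$nominal, c(162L, 176L))
  expect_equal(ladder$parent_mz, c(583.1658, 421.1129))
  expect_true(all(abs(ladder$error_da) <= 0.01))

  expect_error(assignNeutralLosses(567, 600), "smaller than the precursor")
})

test_that("ladder assignment is independent of fragment input order", {
  frags <- c(421.11, 245.08, 175.02, 135.04)
  a <- assignNeutralLosses(597.1450, frags)
  set.seed(1)
  for (i in 1:5) {
    b <- assignNeutralLosses(597.1450, sample(frags))
    expect_identical(a, b)
  }
  # unexplained fragments are reported, not dropped
  u <- assignNeutralLosses(500, c(400, 123.456))
  expect_true(any(!u$explained))
  expect_true(all(is.na(u$loss[!u$explained])))
})

test_that("diagnostic flags fire on published fragment patterns", {
  # sulfate conjugate: hydrogen sulfate base peak plus aglycone ion
  f1 <- diagnosticEvidence(data.frame(mz = c(96.96, 243.07, 567.17),
                                      abundance = c(100, 5.6, 4.23)))
  expect_true(f1[["sulfate"]])
  expect_true(f1[["aglycone"]])

  # glucuronate marker ion alone
  f2 <- diagnosticEvidence(175.02)
  expect_true(f2[["glucuronide"]])
  expect_false(f2[["sulfate"]])

  # 175.07 is the aglycone-series ion, not the glucuronate ion
  f3 <- diagnosticEvidence(175.07)
  expect_false(f3[["glucuronide"]])
  expect_true(f3[["aglycone"]])

  # losses detected between fragment pairs (sulfate 80, glucoside 162)
  f4 <- diagnosticEvidence(c(323.02, 243.06))
  expect_true(f4[["sulfate"]])
  f5 <- diagnosticEvidence(c(405.12, 243.07), precursor = 567.17)
  expect_true(f5[["glucoside"]])

  expect_false(any(diagnosticEvidence(numeric(0))))
})

test_that("glucuronide/sulfate/glucoside flags fire on the matching fixture rows", {
  t1 <- mulberrosideMetabolites()
  for (i in seq_len(nrow(t1))) {
    ms <- parseReactionList(t1$reactions[i])
    frag <- parseMs2String(t1$ms2[i])
    flags <- diagnosticEvidence(frag, tol = 0.02,
                                precursor = t1$experimental_mz[i])
    # sulfation rows whose spectra contain the 80 Da step or 96.96 ion
    if ("sulfation" %in% names(ms)) {
      has <- any(abs(outer(c(frag$mz, t1$experimental_mz[i]), frag$mz, `-`) -
                       79.9568) <= 0.02) ||
        any(abs(frag$mz - 96.96) <= 0.02)
      if (has) expect_true(flags[["sulfate"]], info = t1$peak_id[i])
    }
    if ("glucuronidation" %in% names(ms)) {
      has <- any(abs(outer(c(frag$mz, t1$experimental_mz[i]), frag$mz, `-`) -
                       176.0321) <= 0.02) ||
        any(abs(frag$mz - 175.0237) <= 0.02)
      if (has) expect_true(flags[["glucuronide"]], info = t1$peak_id[i])
    }
  }
})

test_that("evidence scores are supported-fraction and monotone in evidence", {
  flagsAll <- c(aglycone = TRUE, glucuronide = TRUE, sulfate = TRUE,
                methoxy = FALSE, glucoside = FALSE)
  ms <- c(hydrolysis = 2L, glucuronidation = 1L, sulfation = 1L)
  expect_equal(evidenceScore(ms, flagsAll), 1)

  flagsNone <- c(aglycone = FALSE, glucuronide = FALSE, sulfate = FALSE,
                 methoxy = FALSE, glucoside = FALSE)
  expect_equal(evidenceScore(c(glucuronidation = 2L), flagsNone), 0)

  # adding a supporting fragment never decreases the score
  base <- c(243.06, 419.10)
  more <- c(base, 323.02)  # adds the sulfate loss pair 499-176... 323-243=80
  s1 <- evidenceScore(ms, diagnosticEvidence(base, precursor = 499.05))
  s2 <- evidenceScore(ms, diagnosticEvidence(more, precursor = 499.05))
  expect_gte(s2, s1)
  expect_equal(s2, 1)  # GluA loss (499->323), SO3 loss (323->243), skeleton
})
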