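test_that("default reaction library has the expected deltas and shifts", {
  lib <- defaultReactionLibrary()
  expect_setequal(lib$name, c("hydrolysis", "glucuronidation", "sulfation",
                              "hydroxylation", "dehydroxylation",
                              "hydrogenation", "dehydrogenation",
                              "methylation", "acetylation", "hydration"))
  gluA <- lib$delta[[match("glucuronidation", lib$name)]]
  expect_equal(monoisotopicMass(gluA), 176.0321, tolerance = 1e-4)
  # per-step nominal shift equals the rounded delta mass
  for (i in seq_len(nrow(lib))) {
    m <- sum(c(12, 1.007825, 14.003074, 15.994915, 31.972071)[
      match(names(lib$delta[[i]]), c("C", "H", "N", "O", "S"))] *
      lib$delta[[i]])
    expect_equal(lib$nominal[i], round(m), info = lib$name[i])
  }
  nominal <- setNames(lib$nominal, lib$name)
  expect_equal(nominal[["dehydrogenation"]] + nominal[["methylation"]], 12)
  expect_equal(nominal[["hydrogenation"]] + nominal[["hydroxylation"]] +
                 nominal[["sulfation"]], 98)
})

test_that("candidate enumeration obeys the step budget and includes known products", {
  parent <- mulberrosideIon()
  only <- enumerateCandidates(parent, maxSteps = 0, cleavage = NULL)
  expect_equal(nrow(only), 1L)
  expect_equal(only$formula, "C26H31O14")

  lib <- defaultReactionLibrary()
  sub <- lib[lib$name %in% c("hydrolysis", "glucuronidation"), ]
  cand <- enumerateCandidates(parent, sub, maxSteps = 2,
                              constraints = openConstraints(),
                              cleavage = NULL)
  expect_true("C26H29O15" %in% cand$formula)  # hydrolysis + glucuronidation
  expect_true("C14H11O4" %in% cand$formula)   # hydrolysis x2 (aglycone)

  # deterministic ordering across runs
  again <- enumerateCandidates(parent, sub, maxSteps = 2,
                               constraints = openConstraints(),
                               cleavage = NULL)
  expect_identical(cand, again)
})

test_that("enumeration agrees with a brute-force single-step oracle", {
  lib <- defaultReactionLibrary()
  cases <- list(
    lib[lib$name %in% c("hydrolysis", "glucuronidation", "sulfation",
                        "methylation"), ],
    lib[lib$name %in% c("hydroxylation", "dehydroxylation", "hydrogenation",
                        "hydration", "acetylation"), ],
    lib[lib$name %in% c("hydrolysis", "hydrogenation", "dehydrogenation"), ]
  )
  for (library in cases) {
    for (maxSteps in 0:3) {
      got <- enumerateCandidates(mulberrosideIon(), library, maxSteps,
                                 constraints = openConstraints(),
                                 cleavage = NULL)
      gotKeys <- sort(paste(got$formula, got$label))
      wantKeys <- bruteForceCandidates("C26H31O14", library, maxSteps)
      # the oracle labels the parent "(none)" too
      expect_identical(gotKeys, wantKeys,
                       info = sprintf("%d steps, %d reactions",
                                      maxSteps, nrow(library)))
    }
  }
})

test_that("candidate mass and RDB bookkeeping are exact", {
  parent <- mulberrosideIon()
  cand <- enumerateCandidates(parent, maxSteps = 3,
                              constraints = openConstraints(),
                              cleavage = NULL)
  lib <- defaultReactionLibrary()
  pMz <- ionMz(parent)
  pRdb <- rdbEquivalent(composition(parent))
  for (i in seq_len(nrow(cand))) {
    m <- cand$multiset[[i]]
    dC <- 0; dH <- 0; dN <- 0
    for (nm in names(m)) {
      d <- lib$delta[[match(nm, lib$name)]] * m[[nm]]
      dC <- dC + (if ("C" %in% names(d)) d[["C"]] else 0)
      dH <- dH + (if ("H" %in% names(d)) d[["H"]] else 0)
      dN <- dN + (if ("N" %in% names(d)) d[["N"]] else 0)
    }
    # mass bookkeeping via independent per-element sums
    masses <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                O = 15.9949146196, S = 31.9720711744)
    comp <- parseFormula(cand$formula[i])
    expect_equal(cand$mz[i],
                 sum(masses[names(comp)] * comp) - 0.00054857990907,
                 tolerance = 1e-9)
    expect_equal(cand$rdb[i] - pRdb, dC - dH / 2 + dN / 2, tolerance = 1e-9)
  }
})

test_that("peak matching finds published products and sorts by error then steps", {
  cand <- enumerateCandidates(mulberrosideIon())
  m <- matchPeaks(cand, data.frame(peak_id = "p421", mz = 421.1131))
  expect_true(all(abs(m$ppm) <= 5))
  hit <- m[m$formula == "C20H21O10", ]
  expect_gt(nrow(hit), 0)
  expect_true(any(vapply(hit$multiset, function(ms) {
    identical(ms[order(names(ms))],
              c(glucuronidation = 1L, hydrogenation = 1L, hydrolysis = 2L))
  }, logical(1))))

  mp <- matchPeaks(cand, data.frame(mz = 567.1707))
  expect_equal(mp$formula[1], "C26H31O14")
  expect_equal(mp$steps[1], 0L)

  none <- matchPeaks(cand, data.frame(mz = 1000))
  expect_equal(nrow(none), 0L)
})

test_that("transformation explanation recovers published reaction multisets", {
  parent <- mulberrosideIon()
  ex3 <- explainTransformation(parent, "C26H29O15")
  expect_true(any(vapply(ex3, function(m) {
    identical(m, c(glucuronidation = 1L, hydrolysis = 1L))
  }, logical(1))))

  same <- explainTransformation(parent, "C26H31O14")
  expect_equal(length(same[[1]]), 0L)

  ex14 <- explainTransformation(parent, "C32H39O21")
  expect_true(any(vapply(ex14, function(m) {
    identical(m, c(glucuronidation = 2L, hydrogenation = 1L,
                   hydrolysis = 1L))
  }, logical(1))))

  expect_length(explainTransformation(parent, "C5H5N5"), 0L)

  # minimal-only filtering keeps the lowest step count
  exMin <- explainTransformation(parent, "C26H29O15", onlyMinimal = TRUE)
  n <- vapply(exMin, reactionStepCount, integer(1))
  expect_true(all(n == min(vapply(ex3, reactionStepCount, integer(1)))))
})

test_that("reaction library serializes to a plain-text table and back", {
  lib <- defaultReactionLibrary()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeReactionLibrary(lib, path)
  back <- readReactionLibrary(path)
  expect_equal(back$name, lib$name)
  expect_equal(back$cap, lib$cap)
  expect_equal(back$nominal, lib$nominal)
  expect_equal(back$delta, lib$delta)
})
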