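peakRow <- function(id, rt, mz, matrix, area = 1e6) {
  data.frame(peak_id = id, rt_min = rt, mz = mz, polarity = "-",
             matrix = matrix, area = area, stringsAsFactors = FALSE)
}

test_that("noiseless simulation is annotated back to the full ground truth", {
  sim <- simulatePeakTables(config = simulationConfig(seed = 1, ppmSd = 0,
                                                      decoyCount = 0))
  rec <- annotateDataset(sim$peaks, ms2 = sim$ms2, tolPpm = 1)
  t1 <- mulberrosideMetabolites()
  expect_equal(nrow(rec), nrow(t1))
  truthKey <- sort(paste(t1$ion_formula, round(t1$rt_min, 2)))
  gotKey <- sort(paste(rec$ion_formula, round(rec$rt_min, 2)))
  expect_equal(gotKey, truthKey)
  # presence flags reproduce the ground-truth design
  expect_equal(unname(matrixCounts(rec)), unname(matrixCounts(t1)))
})

test_that("records merge across matrices and split isomers by retention time", {
  pk <- rbind(
    peakRow("u1", 9.19, 421.1129, "U", 2e6),
    peakRow("ps1", 9.19, 421.1130, "PS", 1e6),
    peakRow("m0", 8.18, 567.1707, "PS", 5e5),
    peakRow("m27", 9.35, 567.1707, "PM", 4e5)
  )
  rec <- annotateDataset(pk)
  expect_equal(nrow(rec), 3L)
  merged <- rec[rec$ion_formula == "C20H21O10", ]
  expect_equal(nrow(merged), 1L)
  expect_true(merged$U && merged$PS)
  expect_equal(merged$max_area_matrix, "U")
  isomers <- rec[rec$ion_formula == "C26H31O14", ]
  expect_equal(nrow(isomers), 2L)
  expect_equal(sort(isomers$rt_min), c(8.18, 9.35))
})

test_that("annotation is idempotent under matrix partitioning", {
  sim <- simulatePeakTables(config = simulationConfig(seed = 3, ppmSd = 0.5,
                                                      decoyCount = 0))
  whole <- annotateDataset(sim$peaks)
  parts <- annotateDataset(split(sim$peaks, sim$peaks$matrix))
  expect_equal(nrow(whole), nrow(parts))
  key <- function(r) paste(r$ion_formula, round(r$rt_min, 2))
  expect_setequal(key(whole), key(parts))
  # processing order does not lose the best match
  expect_equal(whole$error_ppm[order(key(whole))],
               parts$error_ppm[order(key(parts))], tolerance = 1e-9)
})

test_that("matrix counts aggregate blood and report per-matrix totals", {
  t1 <- mulberrosideMetabolites()
  mc <- matrixCounts(t1)
  expect_equal(mc[["blood"]], 40L)
  expect_equal(mc[["urine"]], 37L)
  expect_equal(mc[["liver"]], 9L)
  expect_equal(mc[["liver_microsomes"]], 10L)
  empty <- t1[0, ]
  expect_true(all(matrixCounts(empty) == 0L))
})

test_that("plasma preparation comparison reproduces the published ordering", {
  t1 <- mulberrosideMetabolites()
  pc <- preparationComparison(t1)
  expect_equal(unname(pc), c(36L, 17L, 15L))
  expect_gte(pc[["PS"]], pc[["PM"]])
  expect_gte(pc[["PS"]], pc[["PA"]])
  noProto <- preparationComparison(t1, includePrototype = FALSE)
  expect_equal(unname(noProto), c(34L, 15L, 14L))  # drops M0 and its isomer

  # constructed nesting PS > PM > PA gives strictly ordered counts
  des <- t1[1:6, ]
  des$reactions <- "hydroxylation"
  des[, c("PS", "PM", "PA")] <- FALSE
  des$PS <- TRUE
  des$PM[1:4] <- TRUE
  des$PA[1:2] <- TRUE
  pc2 <- preparationComparison(des)
  expect_true(pc2[["PS"]] > pc2[["PM"]] && pc2[["PM"]] > pc2[["PA"]])
})

test_that("reaction-class proportions are area-weighted and normalized", {
  one <- data.frame(reactions = "sulfation", max_area = 10)
  expect_equal(reactionClassProportions(one), c(sulfation = 1))

  two <- data.frame(reactions = c("sulfation", "methylation"),
                    max_area = c(5, 5))
  expect_equal(sort(unname(reactionClassProportions(two))), c(0.5, 0.5))

  t1 <- mulberrosideMetabolites()
  p <- reactionClassProportions(t1)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(names(p)[1], "hydrolysis")
  pf <- reactionClassProportions(t1, split = "fractional")
  expect_equal(sum(pf), 1, tolerance = 1e-9)

  zero <- data.frame(reactions = "sulfation", max_area = 0)
  expect_error(reactionClassProportions(zero), "no positive peak areas")
})

test_that("annotation tables export to CSV and re-import losslessly", {
  sim <- simulatePeakTables(config = simulationConfig(seed = 1, ppmSd = 0,
                                                      decoyCount = 0))
  rec <- annotateDataset(sim$peaks, ms2 = sim$ms2)
  path <- withr::local_tempfile(fileext = ".csv")
  exportAnnotationTable(rec, path, config = runConfig(seed = 1))
  expect_equal(sum(!startsWith(readLines(path), "#")) - 1L, nrow(rec))
  back <- readAnnotationTable(path)
  expect_equal(back, rec, tolerance = 1e-12)

  empty <- rec[0, ]
  exportAnnotationTable(empty, path)
  expect_equal(nrow(readAnnotationTable(path)), 0L)
})
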