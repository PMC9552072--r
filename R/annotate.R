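## End-to-end annotation of multi-matrix peak tables into a metabolite
## record set, plus the downstream summary statistics (matrix counts,
## plasma-preparation comparison, reaction-class peak-area proportions).

#' Annotate multi-matrix peak tables against a parent compound
#'
#' Candidate metabolite formulas are enumerated once from the parent,
#' every peak is matched by accurate mass, and matched peaks are merged
#' across matrices into one record per (formula, retention-time cluster):
#' isomers (same formula, distinct retention time) stay separate, and a
#' metabolite seen in several matrices becomes one record with multiple
#' presence flags. Each record keeps its best (lowest |ppm|) match, its
#' maximum peak area and the matrix it occurred in, and -- when MS/MS
#' fragments are supplied -- diagnostic-ion evidence flags and an
#' evidence score.
#'
#' @param peaks A peak-table data.frame (`peak_id`, `rt_min`, `mz`,
#'   `polarity`, `matrix`, `area`) or a list of such tables (one per
#'   matrix) that are concatenated.
#' @param parent Parent [ionSpecies()] or ion formula string.
#' @param library Reaction library ([defaultReactionLibrary()]).
#' @param constraints Formula constraints ([formulaConstraints()]).
#' @param tolPpm Accurate-mass tolerance in ppm.
#' @param maxSteps Reaction step budget (see [reactionStepCount()]).
#' @param rtWindow Retention-time merge window in minutes; peaks of the
#'   same formula within this window are one metabolite across matrices.
#' @param ms2 Optional long-format fragment table (`peak_id`,
#'   `fragment_mz`, `relative_abundance`) or data.frame from [readMgf()].
#' @param cleavage Special cleavage products, see [cleavageProducts()].
#' @return data.frame with one row per metabolite: `metabolite_id`,
#'   `rt_min`, `ion_formula`, `reactions` (semicolon list),
#'   `reaction_label`, `theoretical_mz`, `experimental_mz`, `rdb`,
#'   `error_ppm`, `steps`, logical presence columns `PS`...`LM`,
#'   `max_area`, `max_area_matrix`, evidence flag columns
#'   `ev_aglycone`...`ev_glucoside`, `evidence_score`, `ms2` (summary
#'   string), ordered by retention time then m/z.
#' @examples
#' sim <- simulatePeakTables(config = simulationConfig(seed = 1, ppmSd = 0,
#'                                                     decoyCount = 0))
#' rec <- annotateDataset(sim$peaks, ms2 = sim$ms2)
#' nrow(rec)
#' @export
annotateDataset <- function(peaks, parent = mulberrosideIon(),
                            library = defaultReactionLibrary(),
                            constraints = formulaConstraints(),
                            tolPpm = 5, maxSteps = 4L, rtWindow = 0.05,
                            ms2 = NULL, cleavage = cleavageProducts()) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  if (length(peaks) == 0L) stop("no peak tables supplied")
  peaks <- do.call(rbind, lapply(peaks, function(p) {
    p[, c("peak_id", "rt_min", "mz", "polarity", "matrix", "area")]
  }))
  if (!is(parent, "IonSpecies")) parent <- ionSpecies(parent)

  cand <- enumerateCandidates(parent, library, maxSteps, constraints,
                              cleavage)
  matches <- matchPeaks(cand, peaks, tolPpm)
  if (nrow(matches) == 0L) {
    return(.emptyAnnotation())
  }
  ## best candidate per peak: matchPeaks orders by |ppm|, steps, label
  best <- matches[!duplicated(matches$peak_id), , drop = FALSE]
  pk <- peaks[match(best$peak_id, peaks$peak_id), , drop = FALSE]
  best$rt_min <- pk$rt_min
  best$matrix <- pk$matrix
  best$area <- pk$area

  ## group by (formula, RT cluster): greedy chaining within rtWindow
  best <- best[order(best$formula, best$rt_min), , drop = FALSE]
  grp <- integer(nrow(best))
  g <- 0L
  for (i in seq_len(nrow(best))) {
    if (i == 1L || best$formula[i] != best$formula[i - 1L] ||
        best$rt_min[i] - best$rt_min[i - 1L] > rtWindow) {
      g <- g + 1L
    }
    grp[i] <- g
  }

  recs <- lapply(split(seq_len(nrow(best)), grp), function(idx) {
    sub <- best[idx, , drop = FALSE]
    ibest <- idx[which.min(abs(sub$ppm))]
    imax <- idx[which.max(sub$area)]
    pres <- stats::setNames(.MATRIX_CODES %in% sub$matrix, .MATRIX_CODES)
    multiset <- sub$multiset[[which.min(abs(sub$ppm))]]
    frag <- if (!is.null(ms2)) {
      ms2[ms2$peak_id %in% sub$peak_id, , drop = FALSE]
    }
    flags <- c(aglycone = NA, glucuronide = NA, sulfate = NA,
               methoxy = NA, glucoside = NA)
    score <- NA_real_
    ms2sum <- ""
    if (!is.null(frag) && nrow(frag)) {
      fr <- data.frame(mz = frag$fragment_mz,
                       abundance = frag$relative_abundance)
      fr <- fr[!duplicated(round(fr$mz, 4L)), , drop = FALSE]
      flags <- diagnosticEvidence(fr, precursor = best$peak_mz[ibest])
      score <- evidenceScore(multiset, flags)
      fr <- fr[order(-fr$abundance), , drop = FALSE]
      ms2sum <- paste(sprintf("%.2f(%.2f)", fr$mz, fr$abundance),
                      collapse = ";")
    }
    data.frame(
      rt_min = stats::median(sub$rt_min),
      ion_formula = sub$formula[1],
      reactions = paste(rep(names(multiset), multiset), collapse = ";"),
      reaction_label = reactionLabel(multiset),
      theoretical_mz = sub$theoretical_mz[1],
      experimental_mz = best$peak_mz[ibest],
      rdb = rdbEquivalent(sub$formula[1]),
      error_ppm = best$ppm[ibest],
      steps = sub$steps[1],
      PS = pres[["PS"]], PM = pres[["PM"]], PA = pres[["PA"]],
      U = pres[["U"]], F = pres[["F"]], L = pres[["L"]],
      LM = pres[["LM"]],
      max_area = best$area[imax],
      max_area_matrix = best$matrix[imax],
      ev_aglycone = flags[["aglycone"]],
      ev_glucuronide = flags[["glucuronide"]],
      ev_sulfate = flags[["sulfate"]],
      ev_methoxy = flags[["methoxy"]],
      ev_glucoside = flags[["glucoside"]],
      evidence_score = score,
      ms2 = ms2sum,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$rt_min, out$theoretical_mz), , drop = FALSE]
  out <- cbind(metabolite_id = sprintf("A%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.emptyAnnotation <- function() {
  out <- data.frame(metabolite_id = character(0), rt_min = numeric(0),
                    ion_formula = character(0), reactions = character(0),
                    reaction_label = character(0),
                    theoretical_mz = numeric(0),
                    experimental_mz = numeric(0), rdb = numeric(0),
                    error_ppm = numeric(0), steps = integer(0),
                    stringsAsFactors = FALSE)
  for (m in .MATRIX_CODES) out[[m]] <- logical(0)
  out$max_area <- numeric(0)
  out$max_area_matrix <- character(0)
  for (f in c("ev_aglycone", "ev_glucuronide", "ev_sulfate", "ev_methoxy",
              "ev_glucoside")) out[[f]] <- logical(0)
  out$evidence_score <- numeric(0)
  out$ms2 <- character(0)
  out
}

#' Distinct metabolite counts per biological matrix group
#'
#' Blood aggregates the three plasma preparations (PS, PM, PA); the
#' remaining groups are single matrices. The prototype (if present in
#' the records) is counted like any other metabolite.
#'
#' @param records Annotation records ([annotateDataset()]) or the
#'   packaged fixture ([mulberrosideMetabolites()]): any data.frame with
#'   logical presence columns `PS`, `PM`, `PA`, `U`, `F`, `L`, `LM`.
#' @return Named integer vector: `blood`, `urine`, `feces`, `liver`,
#'   `liver_microsomes`, plus the seven per-matrix counts.
#' @examples
#' matrixCounts(mulberrosideMetabolites())[["urine"]]  # 37
#' @export
matrixCounts <- function(records) {
  stopifnot(all(.MATRIX_CODES %in% names(records)))
  per <- vapply(.MATRIX_CODES, function(m) sum(records[[m]]), integer(1))
  c(blood = sum(records$PS | records$PM | records$PA),
    urine = per[["U"]], feces = per[["F"]], liver = per[["L"]],
    liver_microsomes = per[["LM"]], per)
}

#' Compare the three plasma preparation methods
#'
#' Distinct metabolite counts for plasma treated by solid-phase
#' extraction (PS), methanol precipitation (PM) and acetonitrile
#' precipitation (PA).
#'
#' @inheritParams matrixCounts
#' @param includePrototype Whether the parent prototype row (reaction
#'   list empty and not a cleavage product) counts; published totals
#'   include it.
#' @return Named integer vector `c(PS = , PM = , PA = )`.
#' @examples
#' preparationComparison(mulberrosideMetabolites())  # 36 17 15
#' @export
preparationComparison <- function(records, includePrototype = TRUE) {
  if (!includePrototype) {
    proto <- !nzchar(records$reactions)
    if ("cleavage" %in% names(records)) proto <- proto & !records$cleavage
    records <- records[!proto, , drop = FALSE]
  }
  c(PS = sum(records$PS), PM = sum(records$PM), PA = sum(records$PA))
}

#' Peak-area proportion of each metabolic reaction class
#'
#' Each record contributes its (maximum) peak area to every reaction
#' class appearing in its multiset -- a record formed by, say,
#' hydrolysis + glucuronidation is counted under both classes, because
#' the printed per-class decomposition of composite metabolites is not
#' available (`split = "fractional"` divides the area evenly among the
#' classes instead). Proportions are over the total contributed area.
#'
#' @inheritParams matrixCounts
#' @param split `"full"` (default) or `"fractional"`.
#' @return Named numeric vector of proportions, decreasing; sums to 1.
#' @examples
#' p <- reactionClassProportions(mulberrosideMetabolites())
#' names(p)[1]  # "hydrolysis"
#' @export
reactionClassProportions <- function(records, split = c("full", "fractional")) {
  split <- match.arg(split)
  stopifnot(all(c("reactions", "max_area") %in% names(records)))
  contrib <- list()
  for (i in seq_len(nrow(records))) {
    m <- parseReactionList(records$reactions[i])
    cls <- unique(names(m))
    if (!length(cls) || is.na(records$max_area[i])) next
    a <- records$max_area[i]
    if (split == "fractional") a <- a / length(cls)
    for (cl in cls) {
      contrib[[cl]] <- (contrib[[cl]] %||% 0) + a
    }
  }
  v <- unlist(contrib)
  if (is.null(v) || sum(v) <= 0) {
    stop("no positive peak areas to summarize")
  }
  sort(v / sum(v), decreasing = TRUE)
}

#' Export / re-import an annotation table
#'
#' CSV with the annotation record column set (stable order); an optional
#' provenance header records the run configuration. `readAnnotationTable()`
#' restores column types so that export -> import round-trips.
#'
#' @param records Annotation records from [annotateDataset()].
#' @param path CSV file path.
#' @param config Optional [runConfig()] provenance header.
#' @return `exportAnnotationTable()` invisibly returns `path`.
#' @export
exportAnnotationTable <- function(records, path, config = NULL) {
  .writeCsv(records, path, config)
  invisible(path)
}

#' @rdname exportAnnotationTable
#' @export
readAnnotationTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = c(metabolite_id = "character"))
  for (m in intersect(.MATRIX_CODES, names(tab))) {
    tab[[m]] <- as.logical(tab[[m]])
  }
  for (f in grep("^ev_", names(tab), value = TRUE)) {
    tab[[f]] <- as.logical(tab[[f]])
  }
  for (ch in intersect(c("reactions", "ms2", "reaction_label"), names(tab))) {
    tab[[ch]][is.na(tab[[ch]])] <- ""
  }
  tab
}
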