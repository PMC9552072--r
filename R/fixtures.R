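## Packaged reference tables: a transcription of the published
## mulberroside A metabolite survey (72 metabolites, M0-M71) and the
## per-metabolite target counts of its network-pharmacology follow-up.

#' Packaged mulberroside A metabolite table
#'
#' A transcription of the published summary table of mulberroside A
#' metabolites in rat plasma (three preparations), urine, feces, liver
#' and liver microsomes: 72 rows (M0 = the parent prototype, M1-M71
#' metabolites) with ion formulas, printed theoretical and experimental
#' `[M-H]-` masses, RDB values, ppm errors, MS/MS fragment lists,
#' reaction assignments, per-matrix detection and maximum peak areas.
#'
#' Rows whose printed values are internally inconsistent carry a
#' non-empty `inconsistent` marker rather than a silently corrected
#' value: `mass` (printed theoretical mass does not reproduce from the
#' formula at 4 decimals), `error` (printed ppm error does not reproduce
#' from the printed mass pair within 0.5 ppm), `matrix` (detection
#' checkmarks garbled in the source and resolved from the printed
#' per-matrix totals). The feces column transcribes to 13 detections
#' while the source prose says 12; the 13 checkmarks are unambiguous and
#' are kept as printed.
#'
#' @return data.frame with one row per metabolite. Matrix presence
#'   columns `PS`, `PM`, `PA`, `U`, `F`, `L`, `LM` are logical;
#'   `max_area` is numeric; `reactions` is a semicolon-separated list of
#'   reaction names (multiplicity spelled out, e.g.
#'   `"hydroxylation;hydroxylation;methylation"`; hydrolysis listed once
#'   regardless of how many residues are lost); `cleavage` marks the two
#'   anomeric-bond cleavage products.
#' @examples
#' t1 <- mulberrosideMetabolites()
#' nrow(t1)            # 72
#' sum(t1$U)           # 37 detected in urine
#' @export
mulberrosideMetabolites <- function() {
  path <- system.file("extdata", "metabolite_survey.csv",
                      package = "BiotransMS", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(rt_min = "numeric",
                                        theoretical_mz = "numeric",
                                        experimental_mz = "numeric",
                                        rdb = "numeric",
                                        error_ppm = "numeric",
                                        max_area = "numeric"))
  for (m in .MATRIX_CODES) tab[[m]] <- tab[[m]] == 1L
  tab$cleavage <- tab$cleavage == "yes"
  tab$adme_selected <- tab$adme_selected == "yes"
  tab
}

#' Packaged per-metabolite target counts
#'
#' The seven metabolites (N1-N7) that passed gastrointestinal-absorption
#' and drug-likeness screening, with the number of predicted protein
#' targets of each. The identities of the individual targets are not
#' public; [simulateTargetAssignment()] generates labeled assignments
#' honoring these counts and a prescribed distinct-target union.
#'
#' @return data.frame with columns `node_id`, `metabolite`,
#'   `target_number`, `identification`.
#' @examples
#' mulberrosideTargetCounts()$target_number  # 102 78 76 65 19 7 3
#' @export
mulberrosideTargetCounts <- function() {
  path <- system.file("extdata", "target_counts.csv",
                      package = "BiotransMS", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname mulberrosideMetabolites
#' @return `loadFixtures()` returns `list(metabolites = , targetCounts = )`.
#' @export
loadFixtures <- function() {
  list(metabolites = mulberrosideMetabolites(),
       targetCounts = mulberrosideTargetCounts())
}

#' Parent ion of the packaged fixtures
#'
#' The deprotonated molecule of mulberroside A (neutral C26H32O14), i.e.
#' ion formula C26H31O14 in negative mode.
#'
#' @return An [ionSpecies()] object.
#' @export
mulberrosideIon <- function() {
  ionSpecies("C26H31O14", polarity = "negative")
}

#' Parse a reaction list string into a multiset
#'
#' Converts a semicolon-separated reaction list (the fixture's
#' `reactions` column) into a named multiplicity vector.
#'
#' @param s String such as `"hydrolysis;hydrogenation;glucuronidation"`;
#'   empty or `NA` gives the empty multiset.
#' @return Named integer vector, step name -> multiplicity.
#' @export
parseReactionList <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(structure(integer(0), names = character(0)))
  }
  parts <- tolower(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  tab <- table(parts)
  stats::setNames(as.integer(tab), names(tab))
}

#' Parse the fixture MS/MS string into a fragment table
#'
#' @param s String such as `"243.06(100.00);567.17(27.20)"`.
#' @return data.frame with columns `mz` and `abundance`.
#' @export
parseMs2String <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(mz = numeric(0), abundance = numeric(0)))
  }
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  m <- regmatches(parts, regexec("^([0-9.]+)\\(([0-9.]+)\\)$", parts))
  ok <- lengths(m) == 3L
  data.frame(mz = as.numeric(vapply(m[ok], `[`, character(1), 2L)),
             abundance = as.numeric(vapply(m[ok], `[`, character(1), 3L)))
}
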