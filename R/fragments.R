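## Neutral-loss assignment along MS/MS fragment ladders and the
## diagnostic-ion evidence flags used to confirm metabolite assignments.

#' Default neutral-loss library
#'
#' Losses characteristic of glycoside metabolites and their phase-II
#' conjugates: glucose residue (Glu, 162), glucuronic acid residue
#' (GluA, 176), sulfur trioxide (80), water, CO, CO2, carbon suboxide,
#' formaldehyde (methoxy evidence, 30) and, in positive mode only, the
#' catechol-type C6H6O2 ring loss.
#'
#' @param polarity `"negative"` (default) or `"positive"`.
#' @return data.frame with columns `name`, `formula`, `exact_mass`,
#'   `nominal`, `polarity`.
#' @examples
#' defaultLossLibrary()[, c("name", "nominal")]
#' @export
defaultLossLibrary <- function(polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  spec <- list(
    c("Glu",  "C6H10O5", "both"),
    c("GluA", "C6H8O6",  "both"),
    c("SO3",  "SO3",     "both"),
    c("H2O",  "H2O",     "both"),
    c("CO",   "CO",      "both"),
    c("CO2",  "CO2",     "both"),
    c("C3O2", "C3O2",    "both"),
    c("CH2O", "CH2O",    "both"),
    c("C6H6O2", "C6H6O2", "positive")
  )
  out <- data.frame(
    name = vapply(spec, `[`, character(1), 1L),
    formula = vapply(spec, `[`, character(1), 2L),
    polarity = vapply(spec, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  out$exact_mass <- vapply(out$formula, monoisotopicMass, numeric(1))
  out$nominal <- as.integer(round(out$exact_mass))
  out <- out[out$polarity %in% c("both", polarity), ]
  rownames(out) <- NULL
  out[, c("name", "formula", "exact_mass", "nominal", "polarity")]
}

## Diagnostic product ions (negative mode), computed from curated ion
## formulas: the dihydrostilbene/stilbene aglycone series, plus the
## glucuronate and hydrogen-sulfate marker ions.
.diagnosticIons <- function() {
  agly <- c("C14H11O4", "C14H13O4", "C14H9O3", "C14H11O3",
            "C13H11O2", "C11H11O2")
  data.frame(
    class = c(rep("aglycone", length(agly)), "glucuronide", "sulfate"),
    formula = c(agly, "C6H7O6", "HSO4"),
    mz = vapply(c(agly, "C6H7O6", "HSO4"),
                function(f) ionMz(f, "negative"), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Assign neutral losses along a fragment ladder
#'
#' Builds a ladder from the precursor downward: each fragment is linked
#' to the closest heavier ion (precursor or previously placed fragment)
#' whose mass difference matches a single library loss within `tol`;
#' failing that, combinations of up to two losses are tried, then
#' heavier ancestors. Unmatched fragments are reported as unexplained.
#' Results do not depend on the input ordering of `fragments`.
#'
#' @param precursor Precursor m/z.
#' @param fragments Numeric vector of fragment m/z values, all less than
#'   `precursor`.
#' @param library Loss library, see [defaultLossLibrary()].
#' @param tol Absolute matching tolerance in Da. 0.01 Da accommodates
#'   published fragment tables rounded to two decimals; tighten for
#'   profile-accuracy data.
#' @param maxCombo Maximum number of simultaneous losses per step (1 or 2).
#' @return data.frame with one row per fragment: `parent_mz`,
#'   `fragment_mz`, `loss` (e.g. `"Glu"` or `"GluA+H2O"`, `NA` if
#'   unexplained), `nominal` (summed nominal loss mass), `error_da`,
#'   `explained`.
#' @examples
#' assignNeutralLosses(583.1658, c(421.1129, 245.0813))
#' @export
assignNeutralLosses <- function(precursor, fragments,
                                library = defaultLossLibrary(),
                                tol = 0.01, maxCombo = 2L) {
  stopifnot(is.numeric(precursor), length(precursor) == 1L, tol > 0)
  if (any(fragments >= precursor)) {
    stop("fragment m/z must be smaller than the precursor m/z")
  }
  fragments <- sort(unique(fragments), decreasing = TRUE)

  ## single losses and (optionally) pairs
  single <- data.frame(loss = library$name, mass = library$exact_mass,
                       nominal = library$nominal, stringsAsFactors = FALSE)
  combos <- single
  if (maxCombo >= 2L && nrow(library) > 0L) {
    ij <- expand.grid(i = seq_len(nrow(library)), j = seq_len(nrow(library)))
    ij <- ij[ij$i <= ij$j, , drop = FALSE]
    pairs <- data.frame(
      loss = paste(library$name[ij$i], library$name[ij$j], sep = "+"),
      mass = library$exact_mass[ij$i] + library$exact_mass[ij$j],
      nominal = library$nominal[ij$i] + library$nominal[ij$j],
      stringsAsFactors = FALSE
    )
    combos <- rbind(single, pairs)
  }

  ancestors <- precursor
  out <- vector("list", length(fragments))
  for (k in seq_along(fragments)) {
    f <- fragments[k]
    parents <- sort(ancestors[ancestors > f])  # nearest first
    hit <- NULL
    for (tier in list(single, combos)) {
      for (p in parents) {
        d <- p - f
        err <- abs(d - tier$mass)
        i <- which(err <= tol)
        if (length(i)) {
          i <- i[which.min(err[i])]
          hit <- data.frame(parent_mz = p, fragment_mz = f,
                            loss = tier$loss[i], nominal = tier$nominal[i],
                            error_da = d - tier$mass[i], explained = TRUE,
                            stringsAsFactors = FALSE)
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      hit <- data.frame(parent_mz = min(parents), fragment_mz = f,
                        loss = NA_character_, nominal = NA_integer_,
                        error_da = NA_real_, explained = FALSE,
                        stringsAsFactors = FALSE)
    }
    out[[k]] <- hit
    ancestors <- c(ancestors, f)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(parent_mz = numeric(0), fragment_mz = numeric(0),
                      loss = character(0), nominal = integer(0),
                      error_da = numeric(0), explained = logical(0))
  }
  res
}

#' Diagnostic-ion evidence flags from an MS/MS spectrum
#'
#' Raises boolean evidence flags from a fragment list: the aglycone
#' skeleton series (stilbene / dihydrostilbene product ions), the
#' glucuronide markers (176 Da loss or the glucuronate anion near
#' 175.02), the sulfate markers (80 Da loss or hydrogen sulfate near
#' 96.96), the methoxy marker (30 Da loss) and the glucoside marker
#' (162 Da loss). Losses are detected between any pair of observed ions
#' (optionally including the precursor).
#'
#' @param fragments data.frame with columns `mz` and optionally
#'   `abundance` (percent of base peak), or a bare numeric vector of m/z.
#' @param tol Absolute tolerance in Da for both ion and loss matching.
#' @param precursor Optional precursor m/z included as a loss partner.
#' @return Named logical vector with elements `aglycone`, `glucuronide`,
#'   `sulfate`, `methoxy`, `glucoside`.
#' @examples
#' diagnosticEvidence(data.frame(mz = c(96.96, 243.07, 567.17),
#'                               abundance = c(100, 5.6, 4.2)))
#' @export
diagnosticEvidence <- function(fragments, tol = 0.01, precursor = NULL) {
  if (is.numeric(fragments)) {
    fragments <- data.frame(mz = as.numeric(fragments))
  }
  flags <- c(aglycone = FALSE, glucuronide = FALSE, sulfate = FALSE,
             methoxy = FALSE, glucoside = FALSE)
  if (nrow(fragments) == 0L) {
    return(flags)
  }
  mz <- fragments$mz
  ions <- .diagnosticIons()
  near <- function(target) any(abs(mz - target) <= tol)
  flags[["aglycone"]] <- any(vapply(ions$mz[ions$class == "aglycone"], near,
                                    logical(1)))
  gluA_ion <- ions$mz[ions$class == "glucuronide"]
  so4_ion <- ions$mz[ions$class == "sulfate"]

  all_mz <- sort(unique(c(mz, precursor)), decreasing = TRUE)
  diffs <- if (length(all_mz) > 1L) {
    d <- as.numeric(outer(all_mz, all_mz, `-`))
    d[d > 0]
  } else {
    numeric(0)
  }
  lossSeen <- function(mass) any(abs(diffs - mass) <= tol)
  flags[["glucuronide"]] <- near(gluA_ion) ||
    lossSeen(monoisotopicMass("C6H8O6"))
  flags[["sulfate"]] <- near(so4_ion) || lossSeen(monoisotopicMass("SO3"))
  flags[["methoxy"]] <- lossSeen(monoisotopicMass("CH2O"))
  flags[["glucoside"]] <- lossSeen(monoisotopicMass("C6H10O5"))
  flags
}

#' Evidence score of a candidate against observed MS/MS evidence
#'
#' The candidate's reaction multiset implies a set of expected evidence
#' items: the aglycone skeleton, plus one item per conjugation class
#' with a spectral signature (glucuronidation -> glucuronide marker,
#' sulfation -> sulfate marker, methylation -> methoxy loss, and a
#' retained glucoside -- hydrolysis of only one of two residues -- ->
#' glucose loss). The score is the fraction of expected items observed.
#'
#' @param multiset Reaction multiset (named integer vector) of the
#'   candidate, e.g. from [explainTransformation()].
#' @param flags Evidence flags from [diagnosticEvidence()].
#' @param glucoseResidues Number of glycosidic residues on the parent
#'   (2 for a diglucoside): a retained glucoside is expected when the
#'   hydrolysis multiplicity is below this.
#' @return Score in \[0, 1\]; 1 when every expected item is supported.
#'   A candidate with no scoreable expectation beyond the skeleton
#'   returns the skeleton indicator alone.
#' @examples
#' flags <- diagnosticEvidence(data.frame(mz = c(243.07, 419.10, 323.02),
#'                                        abundance = c(100, 10, 55)),
#'                             precursor = 499.05)
#' evidenceScore(c(hydrolysis = 2L, glucuronidation = 1L, sulfation = 1L),
#'               flags)
#' @export
evidenceScore <- function(multiset, flags, glucoseResidues = 2L) {
  expected <- c(aglycone = TRUE)
  nm <- names(multiset)
  if ("glucuronidation" %in% nm) expected[["glucuronide"]] <- TRUE
  if ("sulfation" %in% nm) expected[["sulfate"]] <- TRUE
  if ("methylation" %in% nm) expected[["methoxy"]] <- TRUE
  if ("hydrolysis" %in% nm &&
      multiset[["hydrolysis"]] < glucoseResidues) {
    expected[["glucoside"]] <- TRUE
  }
  items <- names(expected)
  mean(vapply(items, function(i) isTRUE(flags[[i]]), logical(1)))
}
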