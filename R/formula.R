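## Elemental-formula arithmetic: parsing, monoisotopic mass, ion m/z,
## ring-double-bond equivalents, ppm errors and element-range constraints.

## Monoisotopic atomic masses (CODATA/IUPAC, most abundant isotope).
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.9720711744
)

## Electron rest mass in Da.
.ELECTRON_MASS <- 0.00054857990907

#' Parse an elemental formula string
#'
#' Accepts concatenated element symbols, each optionally followed by a
#' positive integer count. Underscore-subscripted forms as found in
#' publication tables (`"C_26_H_31_O_14_"`) are tolerated and stripped.
#'
#' @param text A single formula string, e.g. `"C26H31O14"` or `"H2O"`.
#' @return A named integer vector of element counts (an elemental
#'   composition). Elements appear in the order first seen; use
#'   [formatFormula()] for the canonical Hill-order string.
#' @examples
#' parseFormula("C26H31O14")
#' parseFormula("C_26_H_31_O_14_")
#' @seealso [formatFormula()], [monoisotopicMass()]
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("[_[:space:]]", "", text)
  if (!nzchar(s)) {
    stop("empty formula string")
  }
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s)) {
    stop("malformed formula string: ", sQuote(text))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  comp <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    nc <- sub("^[A-Za-z]+", "", tok)
    if (!el %in% names(.ATOMIC_MASS)) {
      stop("unknown element symbol: ", sQuote(el))
    }
    n <- if (nzchar(nc)) as.integer(nc) else 1L
    if (n <= 0L) {
      stop("element count must be a positive integer: ", sQuote(tok))
    }
    comp[el] <- (if (el %in% names(comp)) comp[[el]] else 0L) + n
  }
  comp
}

#' Format an elemental composition in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' counts of one are implicit and zero counts are dropped.
#'
#' @param comp Named integer vector of non-negative element counts.
#' @return A single formula string.
#' @examples
#' formatFormula(c(O = 14, C = 26, H = 31))
#' @export
formatFormula <- function(comp) {
  comp <- .checkComposition(comp)
  comp <- comp[comp != 0L]
  if (length(comp) == 0L) {
    return("")
  }
  els <- names(comp)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  paste0(vapply(ord, function(e) {
    if (comp[[e]] == 1L) e else paste0(e, comp[[e]])
  }, character(1)), collapse = "")
}

## Validate a composition vector; signed = TRUE allows negative counts
## (reaction deltas); otherwise all counts must be >= 0.
.checkComposition <- function(comp, signed = FALSE) {
  if (length(comp) == 0L) {
    return(integer(0))
  }
  stopifnot(is.numeric(comp), !is.null(names(comp)), all(nzchar(names(comp))))
  bad <- setdiff(names(comp), names(.ATOMIC_MASS))
  if (length(bad)) {
    stop("unknown element symbol: ", paste(sQuote(bad), collapse = ", "))
  }
  if (any(comp != round(comp))) {
    stop("element counts must be integers")
  }
  if (!signed && any(comp < 0)) {
    stop("negative element count in composition: ",
         paste(names(comp)[comp < 0], collapse = ", "))
  }
  storage.mode(comp) <- "integer"
  comp
}

## Coerce a formula string or composition vector to a composition.
.asComposition <- function(x, signed = FALSE) {
  if (is.character(x)) parseFormula(x) else .checkComposition(x, signed = signed)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Named integer vector of non-negative element counts, or a
#'   formula string.
#' @return Mass in Da (sum of monoisotopic atomic masses).
#' @examples
#' monoisotopicMass("C6H10O5")  # glucose residue, 162.0528
#' @export
monoisotopicMass <- function(comp) {
  comp <- .asComposition(comp)
  if (length(comp) == 0L) {
    return(0)
  }
  sum(.ATOMIC_MASS[names(comp)] * comp)
}

## Signed delta mass; negative counts allowed.
.deltaMass <- function(delta) {
  delta <- .asComposition(delta, signed = TRUE)
  if (length(delta) == 0L) return(0)
  sum(.ATOMIC_MASS[names(delta)] * delta)
}

#' Ring-double-bond (RDB) equivalent
#'
#' Degrees of unsaturation of a composition: `C - H/2 + N/2 + 1` (oxygen
#' and sulfur contribute zero). Applied to an even-electron ion formula
#' the value is a half-integer, which is reported as such (no charge
#' correction), matching common deconvolution-software output.
#'
#' @inheritParams monoisotopicMass
#' @return RDB value (possibly half-integer).
#' @examples
#' rdbEquivalent("C26H31O14")  # 11.5
#' rdbEquivalent("C6H14")      # 0
#' @export
rdbEquivalent <- function(comp) {
  comp <- .asComposition(comp)
  n <- function(e) if (e %in% names(comp)) comp[[e]] else 0L
  n("C") - n("H") / 2 + n("N") / 2 + 1
}

#' Theoretical m/z of a singly charged ion formula
#'
#' The composition is the ion formula as printed in annotation tables
#' (e.g. `C26H31O14` for the deprotonated molecule). Two electron-mass
#' conventions are supported:
#' \describe{
#'   \item{`"reported"`}{sum of atomic masses minus the electron mass,
#'     regardless of polarity. This is the convention many vendor tools
#'     print for both ion modes and is the default because it reproduces
#'     published reference tables.}
#'   \item{`"physical"`}{subtracts the electron mass for positive ions and
#'     adds it for negative ions (the physically correct anion mass).}
#' }
#'
#' @param comp Ion formula (string or composition), or an [IonSpecies].
#' @param polarity `"negative"` or `"positive"`. Ignored when `comp` is an
#'   `IonSpecies`.
#' @param convention `"reported"` (default) or `"physical"`.
#' @param charge Absolute charge; only 1 is supported.
#' @return Theoretical m/z in Da.
#' @examples
#' round(ionMz("C26H31O14", "negative"), 4)               # 567.1708
#' ionMz("C14H11O4", "negative", convention = "physical") -
#'   ionMz("C14H11O4", "negative")                        # two electron masses
#' @export
ionMz <- function(comp, polarity = c("negative", "positive"),
                  convention = c("reported", "physical"), charge = 1L) {
  if (is(comp, "IonSpecies")) {
    polarity <- polarity(comp)
    convention <- mzConvention(comp)
    comp <- composition(comp)
  }
  polarity <- match.arg(polarity)
  convention <- match.arg(convention)
  if (charge != 1L) {
    stop("only singly charged ions are supported")
  }
  m <- monoisotopicMass(comp)
  if (convention == "reported" || polarity == "positive") {
    m - .ELECTRON_MASS
  } else {
    m + .ELECTRON_MASS
  }
}

#' Parts-per-million mass error
#'
#' @param experimental Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(experimental - theoretical) / theoretical * 1e6`, vectorised.
#' @examples
#' ppmError(567.1707, 567.1708)
#' @export
ppmError <- function(experimental, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be positive")
  }
  (experimental - theoretical) / theoretical * 1e6
}

#' Elemental-formula constraints
#'
#' Per-element count ranges plus an RDB range, used to filter candidate
#' formulas. The defaults are typical small-molecule ranges for a
#' C/H/O/S/N phytochemical and its phase-I/II metabolites: C 5--40,
#' H 5--60, O 2--30, S 0--2, N 0--3, RDB 3--20.
#'
#' @param C,H,O,S,N Length-2 numeric `c(min, max)` count ranges.
#' @param rdb Length-2 numeric RDB range (half-integers allowed).
#' @return A `FormulaConstraints` object.
#' @examples
#' checkConstraints("C26H31O14", formulaConstraints())
#' @export
formulaConstraints <- function(C = c(5, 40), H = c(5, 60), O = c(2, 30),
                               S = c(0, 2), N = c(0, 3), rdb = c(3, 20)) {
  el <- rbind(C = C, H = H, O = O, S = S, N = N)
  colnames(el) <- c("min", "max")
  new("FormulaConstraints", elements = el, rdb = as.numeric(rdb))
}

#' Check a composition against formula constraints
#'
#' @param comp Ion formula (string or composition).
#' @param constraints A [formulaConstraints()] object.
#' @return A list with `pass` (logical) and `violations` (character vector
#'   describing each out-of-range element or RDB value; empty on pass).
#' @examples
#' checkConstraints("C4H5O2", formulaConstraints())$violations
#' @export
checkConstraints <- function(comp, constraints = formulaConstraints()) {
  stopifnot(is(constraints, "FormulaConstraints"))
  comp <- .asComposition(comp)
  el <- constraints@elements
  viol <- character(0)
  for (e in rownames(el)) {
    n <- if (e %in% names(comp)) comp[[e]] else 0L
    if (n < el[e, "min"] || n > el[e, "max"]) {
      viol <- c(viol, sprintf("%s=%d outside [%g, %g]", e, n,
                              el[e, "min"], el[e, "max"]))
    }
  }
  extra <- setdiff(names(comp)[comp > 0L], rownames(el))
  if (length(extra)) {
    viol <- c(viol, sprintf("element %s not allowed", extra))
  }
  r <- rdbEquivalent(comp)
  if (r < constraints@rdb[1] || r > constraints@rdb[2]) {
    viol <- c(viol, sprintf("RDB=%g outside [%g, %g]", r,
                            constraints@rdb[1], constraints@rdb[2]))
  }
  list(pass = length(viol) == 0L, violations = viol)
}

#' Apply a signed composition delta
#'
#' Element-wise sum of a composition and a signed reaction delta; errors
#' if any resulting count would be negative (the reaction does not apply).
#'
#' @param comp Base composition (string or named integer vector).
#' @param delta Signed composition (named integer vector, negative counts
#'   allowed) or formula string (taken as positive).
#' @return The resulting composition with zero counts dropped.
#' @examples
#' composeFormula("C26H31O14", c(C = -6L, H = -10L, O = -5L))  # C20H21O9
#' @export
composeFormula <- function(comp, delta) {
  comp <- .asComposition(comp)
  delta <- .asComposition(delta, signed = TRUE)
  els <- union(names(comp), names(delta))
  out <- integer(length(els))
  names(out) <- els
  out[names(comp)] <- out[names(comp)] + comp
  out[names(delta)] <- out[names(delta)] + delta
  if (any(out < 0L)) {
    stop("delta not applicable: negative count for ",
         paste(names(out)[out < 0L], collapse = ", "))
  }
  hill <- c("C", "H", setdiff(sort(els), c("C", "H")))
  out <- out[order(match(names(out), hill))]
  out[out != 0L]
}
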