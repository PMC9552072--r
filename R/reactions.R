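## Biotransformation reaction library, candidate enumeration, peak
## matching, and reaction-multiset explanation of observed formulas.

#' Default biotransformation reaction library
#'
#' Phase-I/II reactions modeled as signed elemental-composition deltas
#' with per-reaction multiplicity caps. Caps reflect the maximum
#' multiplicities seen in glycoside metabolite surveys ("bis-"
#' glucuronides, "di-" hydroxylation / methylation); all are configurable
#' by editing the returned table or via [readReactionLibrary()].
#'
#' Hydrolysis of a glycoside may remove one or two glucose residues; it is
#' treated as a single metabolic event either way (see
#' [reactionStepCount()]), with the multiplicity reported in labels.
#'
#' @return A data.frame with columns `name`, `delta` (list of signed
#'   compositions), `formula` (signed formula string), `nominal` (integer
#'   Da shift per application), `cap` (max multiplicity), and `exclusive`
#'   (name of a mutually exclusive reaction or `NA`).
#' @examples
#' defaultReactionLibrary()[, c("name", "formula", "nominal", "cap")]
#' @export
defaultReactionLibrary <- function() {
  spec <- list(
    list("hydrolysis",      "-C6H10O5", 2L, NA),
    list("glucuronidation", "+C6H8O6",  2L, NA),
    list("sulfation",       "+SO3",     1L, NA),
    list("hydroxylation",   "+O",       2L, "dehydroxylation"),
    list("dehydroxylation", "-O",       1L, "hydroxylation"),
    list("hydrogenation",   "+H2",      1L, "dehydrogenation"),
    list("dehydrogenation", "-H2",      1L, "hydrogenation"),
    list("methylation",     "+CH2",     2L, NA),
    list("acetylation",     "+C2H2O",   1L, NA),
    list("hydration",       "+H2O",     1L, NA)
  )
  name <- vapply(spec, `[[`, character(1), 1L)
  fstr <- vapply(spec, `[[`, character(1), 2L)
  delta <- lapply(fstr, .parseSignedFormula)
  out <- data.frame(name = name, formula = fstr,
                    nominal = vapply(delta, function(d) as.integer(round(.deltaMass(d))), integer(1)),
                    cap = vapply(spec, `[[`, integer(1), 3L),
                    exclusive = vapply(spec, function(s) {
                      if (is.na(s[[4]][1])) NA_character_ else s[[4]]
                    }, character(1)),
                    stringsAsFactors = FALSE)
  out$delta <- delta
  out
}

## "+C6H8O6" / "-C6H10O5" -> signed composition.
.parseSignedFormula <- function(s) {
  sgn <- 1L
  if (startsWith(s, "-")) {
    sgn <- -1L
    s <- substring(s, 2L)
  } else if (startsWith(s, "+")) {
    s <- substring(s, 2L)
  }
  comp <- parseFormula(s)
  comp * sgn
}

.formatSignedFormula <- function(delta) {
  sgn <- if (all(delta <= 0L)) "-" else "+"
  paste0(sgn, formatFormula(abs(delta)))
}

#' Cleavage product ion formulas
#'
#' Glycoside parents can also break at the anomeric C--O bonds, yielding
#' phenol fragments that are then conjugated; these products are not
#' reachable by whole-molecule composition deltas and are modeled as
#' named special cases with fixed product ion formulas.
#'
#' @return data.frame with columns `name` and `ion_formula`.
#' @export
cleavageProducts <- function() {
  data.frame(
    name = c("cleavage (phenol glucuronide)",
             "cleavage (vinylphenol glucuronide)"),
    ion_formula = c("C12H13O8", "C14H15O8"),
    stringsAsFactors = FALSE
  )
}

## ---- reaction multisets ----------------------------------------------

## A multiset is a named integer vector (step name -> multiplicity > 0).

#' Effective step count of a reaction multiset
#'
#' The total multiplicity, except that hydrolysis counts once whether one
#' or two glucose residues are removed (complete deglycosylation is a
#' single hydrolytic event).
#'
#' @param multiset Named integer vector, step name -> multiplicity.
#' @return Integer step count.
#' @export
reactionStepCount <- function(multiset) {
  if (length(multiset) == 0L) {
    return(0L)
  }
  n <- sum(multiset)
  if ("hydrolysis" %in% names(multiset)) {
    n <- n - (multiset[["hydrolysis"]] - 1L)
  }
  as.integer(n)
}

#' Human-readable label of a reaction multiset
#'
#' @param multiset Named integer vector, step name -> multiplicity.
#' @return A string such as `"hydrolysis x2 + hydrogenation +
#'   glucuronidation"`; `"(none)"` for the empty multiset.
#' @export
reactionLabel <- function(multiset) {
  multiset <- multiset[multiset > 0L]
  if (length(multiset) == 0L) {
    return("(none)")
  }
  multiset <- multiset[order(names(multiset))]
  paste(ifelse(multiset > 1L,
               sprintf("%s x%d", names(multiset), multiset),
               names(multiset)),
        collapse = " + ")
}

## Net signed delta of a multiset over a library.
.netDelta <- function(multiset, library) {
  delta <- integer(0)
  names(delta) <- character(0)
  for (nm in names(multiset)) {
    i <- match(nm, library$name)
    if (is.na(i)) stop("unknown reaction: ", sQuote(nm))
    d <- library$delta[[i]] * multiset[[nm]]
    els <- union(names(delta), names(d))
    out <- integer(length(els))
    names(out) <- els
    out[names(delta)] <- out[names(delta)] + delta
    out[names(d)] <- out[names(d)] + d
    delta <- out
  }
  delta[delta != 0L]
}

## Multiset enumeration is the hot path (called per record in batch
## explanation); results are matrix-valued and memoized per
## (library, maxSteps).
.multisetCache <- new.env(parent = emptyenv())

## All multiplicity combinations within caps, exclusivity and step
## budget, as a list: counts (n x k multiplicity matrix), delta (n x 5
## element-delta matrix over C,H,N,O,S), steps, labels. Rows ordered by
## step count then label.
.multisetTable <- function(library, maxSteps) {
  key <- paste(c(library$name, library$formula, library$cap,
                 library$exclusive, maxSteps), collapse = "|")
  hit <- .multisetCache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  els <- names(.ATOMIC_MASS)
  k <- nrow(library)
  if (k == 0L) {
    res <- list(counts = matrix(integer(0), 1L, 0L),
                delta = matrix(0L, 1L, length(els),
                               dimnames = list(NULL, els)),
                steps = 0L, labels = "(none)")
    .multisetCache[[key]] <- res
    return(res)
  }
  grid <- as.matrix(expand.grid(lapply(stats::setNames(library$cap,
                                                       library$name),
                                       function(cap) 0:cap),
                                KEEP.OUT.ATTRS = FALSE))
  storage.mode(grid) <- "integer"
  steps <- rowSums(grid)
  if ("hydrolysis" %in% colnames(grid)) {
    steps <- steps - pmax(grid[, "hydrolysis"] - 1L, 0L)
  }
  keep <- steps <= maxSteps
  for (i in seq_len(k)) {
    ex <- library$exclusive[i]
    if (!is.na(ex) && ex %in% colnames(grid)) {
      keep <- keep & !(grid[, i] > 0L & grid[, ex] > 0L)
    }
  }
  grid <- grid[keep, , drop = FALSE]
  steps <- steps[keep]
  deltaMat <- matrix(0L, k, length(els), dimnames = list(library$name, els))
  for (i in seq_len(k)) {
    d <- library$delta[[i]]
    deltaMat[i, names(d)] <- d
  }
  delta <- grid %*% deltaMat
  labels <- vapply(seq_len(nrow(grid)), function(i) {
    m <- grid[i, ]
    reactionLabel(m[m > 0L])
  }, character(1))
  ord <- order(steps, labels)
  res <- list(counts = grid[ord, , drop = FALSE],
              delta = delta[ord, , drop = FALSE],
              steps = as.integer(steps[ord]), labels = labels[ord])
  .multisetCache[[key]] <- res
  res
}

## row of the multiset table -> named multiplicity vector
.rowMultiset <- function(tab, i) {
  m <- tab$counts[i, ]
  m <- m[m > 0L]
  if (length(m)) m[order(names(m))] else structure(integer(0),
                                                   names = character(0))
}

.enumerateMultisets <- function(library, maxSteps) {
  tab <- .multisetTable(library, maxSteps)
  lapply(seq_along(tab$steps), function(i) .rowMultiset(tab, i))
}

#' Enumerate candidate metabolite formulas from a parent ion
#'
#' Applies every admissible combination of library reactions (respecting
#' per-reaction caps, mutual exclusivity of forward/reverse redox pairs,
#' and the step budget) to the parent ion formula, keeping compositions
#' that remain valid and pass the formula constraints.
#'
#' @param parent Parent [ionSpecies()] (or ion formula string, taken as
#'   negative mode).
#' @param library Reaction library, see [defaultReactionLibrary()].
#' @param maxSteps Maximum effective step count (see
#'   [reactionStepCount()]).
#' @param constraints [formulaConstraints()] filter; the unmodified parent
#'   is always retained.
#' @param cleavage Optional data.frame of special cleavage products as
#'   from [cleavageProducts()]; `NULL` to disable.
#' @return data.frame with one row per distinct (composition, multiset)
#'   pair: `formula`, `mz`, `rdb`, `steps`, `label`, and list-column
#'   `multiset`. Rows are ordered by m/z then label, stably across runs.
#' @examples
#' cand <- enumerateCandidates(ionSpecies("C26H31O14"), maxSteps = 2)
#' head(cand[, c("formula", "mz", "steps", "label")])
#' @export
enumerateCandidates <- function(parent,
                                library = defaultReactionLibrary(),
                                maxSteps = 4L,
                                constraints = formulaConstraints(),
                                cleavage = cleavageProducts()) {
  if (!is(parent, "IonSpecies")) parent <- ionSpecies(parent)
  stopifnot(maxSteps >= 0L)
  els <- names(.ATOMIC_MASS)
  pvec <- stats::setNames(integer(length(els)), els)
  pcomp <- composition(parent)
  pvec[names(pcomp)] <- pcomp

  tab <- .multisetTable(library, maxSteps)
  counts <- sweep(tab$delta, 2L, pvec, `+`)
  ok <- rowSums(counts < 0L) == 0L
  ## constraint filter, vectorised; the unmodified parent always stays
  el <- constraints@elements
  pass <- rep(TRUE, nrow(counts))
  for (e in rownames(el)) {
    pass <- pass & counts[, e] >= el[e, "min"] & counts[, e] <= el[e, "max"]
  }
  extra <- setdiff(els, rownames(el))
  for (e in extra) pass <- pass & counts[, e] == 0L
  rdb <- counts[, "C"] - counts[, "H"] / 2 + counts[, "N"] / 2 + 1
  pass <- pass & rdb >= constraints@rdb[1] & rdb <= constraints@rdb[2]
  keep <- ok & (pass | tab$steps == 0L)

  idx <- which(keep)
  mzAll <- as.numeric(counts %*% .ATOMIC_MASS[els])
  eSign <- if (mzConvention(parent) == "reported" ||
               polarity(parent) == "positive") -1 else 1
  out <- data.frame(
    formula = vapply(idx, function(i) {
      v <- counts[i, ]
      formatFormula(v[v > 0L])
    }, character(1)),
    mz = mzAll[idx] + eSign * .ELECTRON_MASS,
    rdb = rdb[idx],
    steps = tab$steps[idx],
    label = tab$labels[idx],
    stringsAsFactors = FALSE
  )
  out$multiset <- lapply(idx, function(i) .rowMultiset(tab, i))
  if (!is.null(cleavage) && nrow(cleavage)) {
    cl <- data.frame(
      formula = vapply(cleavage$ion_formula, function(f) {
        formatFormula(parseFormula(f))
      }, character(1), USE.NAMES = FALSE),
      mz = vapply(cleavage$ion_formula, function(f) {
        ionMz(f, polarity(parent), mzConvention(parent))
      }, numeric(1), USE.NAMES = FALSE),
      rdb = vapply(cleavage$ion_formula, rdbEquivalent, numeric(1),
                   USE.NAMES = FALSE),
      steps = 1L,
      label = cleavage$name,
      stringsAsFactors = FALSE
    )
    cl$multiset <- rep(list(stats::setNames(1L, "cleavage")), nrow(cl))
    out <- rbind(out, cl)
  }
  out <- out[!duplicated(paste(out$formula, out$label)), , drop = FALSE]
  out <- out[order(out$mz, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match observed peaks to candidate metabolites by accurate mass
#'
#' @param candidates Candidate table from [enumerateCandidates()].
#' @param peaks data.frame of observed peaks with at least `mz`;
#'   `peak_id` is carried through if present.
#' @param tolPpm Mass tolerance in ppm (> 0). The default of 5 ppm is a
#'   typical Orbitrap full-scan accuracy bound.
#' @return data.frame of all (peak, candidate) pairs within tolerance:
#'   `peak_id`, `peak_mz`, `formula`, `theoretical_mz`, `ppm`, `steps`,
#'   `label`, list-column `multiset`; within each peak, rows are sorted by
#'   |ppm| then fewest steps then label.
#' @examples
#' cand <- enumerateCandidates(ionSpecies("C26H31O14"))
#' matchPeaks(cand, data.frame(peak_id = "p1", mz = 421.1131))
#' @export
matchPeaks <- function(candidates, peaks, tolPpm = 5) {
  stopifnot(tolPpm > 0, is.data.frame(peaks), "mz" %in% names(peaks))
  ids <- if ("peak_id" %in% names(peaks)) as.character(peaks$peak_id)
         else as.character(seq_len(nrow(peaks)))
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    ppm <- ppmError(peaks$mz[i], candidates$mz)
    hit <- which(abs(ppm) <= tolPpm)
    if (!length(hit)) next
    hit <- hit[order(abs(ppm[hit]), candidates$steps[hit],
                     candidates$label[hit])]
    df <- data.frame(peak_id = ids[i], peak_mz = peaks$mz[i],
                     formula = candidates$formula[hit],
                     theoretical_mz = candidates$mz[hit],
                     ppm = ppm[hit],
                     steps = candidates$steps[hit],
                     label = candidates$label[hit],
                     stringsAsFactors = FALSE)
    df$multiset <- candidates$multiset[hit]
    res[[length(res) + 1L]] <- df
  }
  if (!length(res)) {
    out <- data.frame(peak_id = character(0), peak_mz = numeric(0),
                      formula = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0), steps = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
    out$multiset <- list()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Explain an observed formula as reaction multisets over a parent
#'
#' Finds reaction multisets whose net composition delta maps the parent
#' ion formula onto the target composition. All admissible multisets
#' within the step budget are returned, ordered by step count then label:
#' published assignments are frequently not step-minimal (MS/MS evidence,
#' not parsimony, decides among mass-equivalent explanations), so callers
#' that want only the most parsimonious explanations should set
#' `onlyMinimal = TRUE`.
#'
#' @inheritParams enumerateCandidates
#' @param target Target ion composition (formula string or named vector).
#' @param onlyMinimal If `TRUE`, keep only multisets with the minimal
#'   step count.
#' @return A list of reaction multisets (named integer vectors); empty
#'   if the target is unreachable. The empty multiset is returned when
#'   the target equals the parent composition.
#' @examples
#' explainTransformation(ionSpecies("C26H31O14"), "C26H29O15")
#' @export
explainTransformation <- function(parent, target,
                                  library = defaultReactionLibrary(),
                                  maxSteps = 4L, onlyMinimal = FALSE) {
  if (!is(parent, "IonSpecies")) parent <- ionSpecies(parent)
  target <- .asComposition(target)
  els <- names(.ATOMIC_MASS)
  pvec <- stats::setNames(integer(length(els)), els)
  pcomp <- composition(parent)
  pvec[names(pcomp)] <- pcomp
  tvec <- stats::setNames(integer(length(els)), els)
  tvec[names(target)] <- target
  resid <- tvec - pvec

  tab <- .multisetTable(library, maxSteps)
  hit <- rep(TRUE, length(tab$steps))
  for (e in els) hit <- hit & tab$delta[, e] == resid[[e]]
  idx <- which(hit)
  if (onlyMinimal && length(idx)) {
    idx <- idx[tab$steps[idx] == min(tab$steps[idx])]
  }
  lapply(idx, function(i) .rowMultiset(tab, i))
}

#' Read / write a reaction library as a plain-text table
#'
#' Tab-separated with columns `name`, `formula` (signed, e.g.
#' `-C6H10O5`), `cap`, and optional `exclusive`.
#'
#' @param path File path.
#' @return `readReactionLibrary()` returns a reaction library data.frame;
#'   `writeReactionLibrary()` invisibly returns `path`.
#' @export
readReactionLibrary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "formula", "cap")
  if (!all(need %in% names(tab))) {
    stop("reaction library table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"exclusive" %in% names(tab)) tab$exclusive <- NA_character_
  tab$exclusive[!is.na(tab$exclusive) & !nzchar(tab$exclusive)] <- NA_character_
  tab$delta <- lapply(tab$formula, .parseSignedFormula)
  tab$nominal <- vapply(tab$delta, function(d) as.integer(round(.deltaMass(d))),
                        integer(1))
  tab$cap <- as.integer(tab$cap)
  tab[, c("name", "formula", "nominal", "cap", "exclusive", "delta")]
}

#' @rdname readReactionLibrary
#' @param library Reaction library data.frame.
#' @export
writeReactionLibrary <- function(library, path) {
  out <- library[, c("name", "formula", "cap", "exclusive")]
  out$exclusive[is.na(out$exclusive)] <- ""
  .atomicWrite(path, function(tmp) {
    utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(path)
}
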