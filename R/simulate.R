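## Seeded synthetic-data generation: peak tables with ppm-scale mass
## error, log-normal intensity spread, per-matrix detection and decoy
## peaks; MS/MS ladders implied by reaction multisets; and bipartite
## target assignments with prescribed degrees and union size.

#' Simulation configuration
#'
#' All stochastic draws across the simulators are driven by the single
#' integer `seed` through R's default generator, so identical
#' configurations give identical outputs.
#'
#' @param seed Integer seed.
#' @param ppmSd Standard deviation of the relative mass error in ppm
#'   (default 1 ppm, a typical externally calibrated Orbitrap spread).
#' @param logAreaMean,logAreaSd Location/scale of the log-normal peak
#'   area model (natural log). The defaults (log 1e6, 2.3) span roughly
#'   1e4--1e8, the spread seen in real multi-matrix surveys.
#' @param detectionProb Named numeric vector of per-matrix detection
#'   probabilities applied on top of the ground-truth presence design
#'   (default all 1: the design is reproduced exactly).
#' @param decoyCount Number of decoy peaks per matrix (default 100).
#' @param decoyRange m/z range decoys are drawn from (default the
#'   full-scan window 80--1200).
#' @param ms2Dropout Probability in `[0, 1)` that an individual MS/MS
#'   ladder fragment is dropped.
#' @return Validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, ppmSd = 1,
                             logAreaMean = log(1e6), logAreaSd = 2.3,
                             detectionProb = NULL,
                             decoyCount = 100L, decoyRange = c(80, 1200),
                             ms2Dropout = 0) {
  if (is.null(detectionProb)) {
    detectionProb <- stats::setNames(rep(1, length(.MATRIX_CODES)),
                                     .MATRIX_CODES)
  }
  stopifnot(ppmSd >= 0, logAreaSd >= 0,
            all(detectionProb >= 0 & detectionProb <= 1),
            decoyCount >= 0, length(decoyRange) == 2L,
            decoyRange[1] < decoyRange[2],
            ms2Dropout >= 0, ms2Dropout < 1)
  structure(list(seed = as.integer(seed), ppmSd = ppmSd,
                 logAreaMean = logAreaMean, logAreaSd = logAreaSd,
                 detectionProb = detectionProb,
                 decoyCount = as.integer(decoyCount),
                 decoyRange = decoyRange, ms2Dropout = ms2Dropout),
            class = "SimulationConfig")
}

## run code under a locally seeded RNG, restoring global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate multi-matrix peak tables from a ground-truth metabolite set
#'
#' Each ground-truth metabolite emits one peak per detected matrix with
#' `mz = theoretical * (1 + e)`, `e ~ Normal(0, ppmSd * 1e-6)`, a
#' log-normal peak area, and the true retention time. Decoy peaks are
#' drawn uniformly in m/z while avoiding a +/-10 ppm exclusion window
#' around every true mass, so recovery statistics remain interpretable.
#' MS/MS ladders are generated per metabolite from its reaction multiset
#' via [simulateMs2()].
#'
#' @param groundTruth data.frame with columns `peak_id`, `rt_min`,
#'   `ion_formula`, `reactions`, and logical matrix presence columns;
#'   defaults to the packaged metabolite table
#'   ([mulberrosideMetabolites()]), i.e. the published study design.
#' @param config A [simulationConfig()].
#' @return list with elements `peaks` (peak-table data.frame including a
#'   `decoy` flag), `ms2` (long-format fragment table keyed by peak id),
#'   and `truth` (peak id, true metabolite, theoretical m/z).
#' @examples
#' sim <- simulatePeakTables(config = simulationConfig(seed = 7))
#' head(sim$peaks)
#' @export
simulatePeakTables <- function(groundTruth = mulberrosideMetabolites(),
                               config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    truthMz <- vapply(groundTruth$ion_formula,
                      function(f) ionMz(f, "negative"), numeric(1))
    rows <- list()
    ms2 <- list()
    truth <- list()
    for (i in seq_len(nrow(groundTruth))) {
      present <- .MATRIX_CODES[vapply(.MATRIX_CODES, function(m) {
        isTRUE(groundTruth[[m]][i]) &&
          stats::runif(1) <= config$detectionProb[[m]]
      }, logical(1))]
      if (!length(present)) next
      frag <- simulateMs2(groundTruth$reactions[i], truthMz[i],
                          dropout = config$ms2Dropout)
      for (m in present) {
        id <- sprintf("%s_%s", groundTruth$peak_id[i], m)
        eps <- stats::rnorm(1, 0, config$ppmSd * 1e-6)
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = id, rt_min = groundTruth$rt_min[i],
          mz = truthMz[i] * (1 + eps), polarity = "-", matrix = m,
          area = stats::rlnorm(1, config$logAreaMean, config$logAreaSd),
          decoy = FALSE, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          peak_id = id, metabolite = groundTruth$peak_id[i],
          ion_formula = groundTruth$ion_formula[i],
          theoretical_mz = truthMz[i], matrix = m,
          stringsAsFactors = FALSE)
        if (nrow(frag)) {
          ms2[[length(ms2) + 1L]] <- data.frame(
            peak_id = id, fragment_mz = frag$mz,
            relative_abundance = frag$abundance, stringsAsFactors = FALSE)
        }
      }
    }
    ## decoys, rejection-sampled outside +/-10 ppm of any true mass
    if (config$decoyCount > 0L) {
      for (m in .MATRIX_CODES) {
        k <- 0L
        while (k < config$decoyCount) {
          mz <- stats::runif(1, config$decoyRange[1], config$decoyRange[2])
          if (any(abs(ppmError(mz, truthMz)) <= 10)) next
          k <- k + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            peak_id = sprintf("DEC_%s_%03d", m, k),
            rt_min = stats::runif(1, 1, 30), mz = mz, polarity = "-",
            matrix = m,
            area = stats::rlnorm(1, config$logAreaMean, config$logAreaSd),
            decoy = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    peaks <- do.call(rbind, rows)
    rownames(peaks) <- NULL
    list(peaks = peaks,
         ms2 = if (length(ms2)) do.call(rbind, ms2) else
           data.frame(peak_id = character(0), fragment_mz = numeric(0),
                      relative_abundance = numeric(0)),
         truth = do.call(rbind, truth))
  })
}

#' Simulate an MS/MS ladder implied by a reaction multiset
#'
#' Emits the successive neutral-loss ladder a conjugated metabolite is
#' expected to show: sulfate (80), glucuronide (176, once per residue),
#' retained glucoside (162), and a methoxy formaldehyde loss (30),
#' applied in that fixed order from the precursor downward, each at its
#' exact loss mass. The precursor is the base peak (abundance 100) and
#' successive fragments decay geometrically. Fragments (not the
#' precursor) are independently dropped with probability `dropout`.
#'
#' @param reactions Reaction multiset (named integer vector) or
#'   semicolon string as in the fixture `reactions` column.
#' @param precursorMz Precursor m/z.
#' @param dropout Per-fragment dropout probability in `[0, 1)`.
#' @param seed Optional integer; when supplied the draw is locally
#'   seeded and the global RNG state is untouched. When `NULL` the
#'   current RNG stream is used (as inside [simulatePeakTables()]).
#' @param glucoseResidues Residues on the parent (2 for a diglucoside).
#' @return data.frame with columns `mz` and `abundance` (percent of base
#'   peak), precursor first.
#' @examples
#' simulateMs2(c(glucuronidation = 1L, sulfation = 1L), 499.0541,
#'             dropout = 0, seed = 1)
#' @export
simulateMs2 <- function(reactions, precursorMz, dropout = 0, seed = NULL,
                        glucoseResidues = 2L) {
  if (is.character(reactions)) reactions <- parseReactionList(reactions)
  stopifnot(dropout >= 0, dropout < 1)
  build <- function() {
    losses <- character(0)
    nm <- names(reactions)
    if ("sulfation" %in% nm) losses <- c(losses, rep("SO3", reactions[["sulfation"]]))
    if ("glucuronidation" %in% nm) {
      losses <- c(losses, rep("C6H8O6", reactions[["glucuronidation"]]))
    }
    gluLeft <- if ("hydrolysis" %in% nm) {
      max(glucoseResidues - reactions[["hydrolysis"]], 0L)
    } else if (length(reactions) == 0L || !"cleavage" %in% nm) {
      ## unhydrolyzed records (e.g. the prototype) retain all residues
      glucoseResidues
    } else 0L
    losses <- c(losses, rep("C6H10O5", gluLeft))
    if ("methylation" %in% nm) losses <- c(losses, "CH2O")
    mz <- precursorMz
    ab <- 100
    out <- data.frame(mz = precursorMz, abundance = 100)
    for (l in losses) {
      mz <- mz - monoisotopicMass(l)
      ab <- ab * 0.6
      if (mz <= 50) break
      keep <- dropout == 0 || stats::runif(1) >= dropout
      if (keep) out <- rbind(out, data.frame(mz = mz, abundance = ab))
    }
    out
  }
  if (!is.null(seed)) {
    .withSeed(seed, build())
  } else {
    build()
  }
}

#' Simulate a metabolite--target assignment with prescribed degrees
#'
#' Produces, for each metabolite, exactly its prescribed number of
#' distinct targets, such that the union of all targets has exactly the
#' prescribed size. Metabolites are processed in decreasing degree
#' order; each draws as many previously unused targets as the remaining
#' union budget allows and fills the rest by seeded sampling from the
#' already used pool.
#'
#' @param counts Named integer vector: metabolite -> target count.
#' @param total Required distinct-target union size; feasible iff
#'   `max(counts) <= total <= sum(counts)`.
#' @param seed Integer seed.
#' @return data.frame with columns `metabolite`, `target`; one row per
#'   edge.
#' @examples
#' t2 <- mulberrosideTargetCounts()
#' asg <- simulateTargetAssignment(
#'   setNames(t2$target_number, t2$node_id), 167, seed = 1)
#' nrow(asg)                    # 350
#' length(unique(asg$target))   # 167
#' @export
simulateTargetAssignment <- function(counts, total, seed = 1L) {
  stopifnot(length(counts) > 0, all(counts >= 1), !is.null(names(counts)))
  total <- as.integer(total)
  if (total > sum(counts) || total < max(counts)) {
    stop(sprintf("infeasible assignment: need max(counts) <= total <= sum(counts), got total = %d", total))
  }
  .withSeed(seed, {
    targets <- sprintf("T%03d", seq_len(total))
    used <- character(0)
    ord <- order(-counts, names(counts))
    edges <- list()
    for (i in ord) {
      k <- counts[[i]]
      nNew <- min(k, total - length(used))
      ## ensure remaining metabolites can still cover the unused pool
      newT <- if (nNew > 0) targets[length(used) + seq_len(nNew)] else character(0)
      nOld <- k - nNew
      oldT <- if (nOld > 0) sample(used, nOld) else character(0)
      used <- c(used, newT)
      edges[[length(edges) + 1L]] <- data.frame(
        metabolite = names(counts)[i], target = c(newT, oldT),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, edges)
    rownames(out) <- NULL
    out
  })
}

#' Mass-recovery rate of a simulated dataset
#'
#' Fraction of true (non-decoy) peaks whose observed m/z lies within
#' `tolPpm` of the theoretical m/z of their generating metabolite --
#' the quantity whose expectation under the simulator's Normal mass
#' error model is `P(|e| <= tolPpm) = 2 * pnorm(tolPpm / ppmSd) - 1`.
#'
#' @param sim Result of [simulatePeakTables()].
#' @param tolPpm Matching tolerance in ppm.
#' @return Recovery rate in `[0, 1]`.
#' @export
recoveryRate <- function(sim, tolPpm = 5) {
  tr <- sim$truth
  pk <- sim$peaks[match(tr$peak_id, sim$peaks$peak_id), , drop = FALSE]
  mean(abs(ppmError(pk$mz, tr$theoretical_mz)) <= tolPpm)
}
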