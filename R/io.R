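## Readers/writers shared across the pipeline, atomic file output,
## structured logging, run configuration, and the command-line front end.
## CSV dialect is fixed: UTF-8, comma separator, "." decimal, header row.

.MATRIX_CODES <- c("PS", "PM", "PA", "U", "F", "L", "LM")

## temp-file-then-rename so readers never see a torn file
.atomicWrite <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

## FNV-1a 32-bit hash of a character scalar, hex string
.fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648) + 0)  # low 31 bits as hex
}

.logLevel <- new.env(parent = emptyenv())
.logLevel$threshold <- 2L  # info

#' Control structured logging
#'
#' Log lines go to standard error as `LEVEL timestamp message`.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return Previous level, invisibly.
#' @export
setLogLevel <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  prev <- c("debug", "info", "warn", "error")[.logLevel$threshold]
  .logLevel$threshold <- match(level, c("debug", "info", "warn", "error"))
  invisible(prev)
}

.log <- function(level, fmt, ...) {
  lv <- match(level, c("debug", "info", "warn", "error"))
  if (lv >= .logLevel$threshold) {
    message(sprintf("%s %s %s", toupper(level),
                    format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
  }
}

#' Run configuration
#'
#' Bundles the tunables of an annotation run and validates them before
#' any stage executes. The configuration (with a content hash) is
#' serialized into the provenance header of every output file.
#'
#' @param parent Parent ion formula string (the charged species, e.g.
#'   `"C26H31O14"` for negative mode).
#' @param polarity `"negative"` or `"positive"`.
#' @param tolPpm Peak-matching tolerance in ppm.
#' @param maxSteps Reaction step budget.
#' @param rtWindow Retention-time merge window in minutes.
#' @param mzConvention Electron-mass convention, see [ionMz()].
#' @param seed Integer seed for all stochastic stages.
#' @return A validated list of class `RunConfig` with a `hash` element.
#' @export
runConfig <- function(parent = "C26H31O14",
                      polarity = c("negative", "positive"),
                      tolPpm = 5, maxSteps = 4L, rtWindow = 0.05,
                      mzConvention = c("reported", "physical"),
                      seed = 1L) {
  polarity <- match.arg(polarity)
  mzConvention <- match.arg(mzConvention)
  stopifnot(tolPpm > 0, maxSteps >= 0, rtWindow >= 0,
            is.finite(seed))
  parseFormula(parent)  # validates
  cfg <- list(parent = parent, polarity = polarity, tolPpm = tolPpm,
              maxSteps = as.integer(maxSteps), rtWindow = rtWindow,
              mzConvention = mzConvention, seed = as.integer(seed))
  cfg$hash <- .fnv1a(paste(names(cfg), unlist(cfg), collapse = ";"))
  class(cfg) <- "RunConfig"
  cfg
}

.provenanceHeader <- function(config = NULL) {
  if (is.null(config)) {
    return(character(0))
  }
  c(sprintf("# config_hash: %s", config$hash),
    sprintf("# seed: %d", config$seed),
    sprintf("# %s: %s",
            setdiff(names(config), c("hash", "seed")),
            unlist(config[setdiff(names(config), c("hash", "seed"))])))
}

.writeCsv <- function(df, path, config = NULL) {
  .atomicWrite(path, function(tmp) {
    con <- file(tmp, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.provenanceHeader(config), con)
    utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  })
}

#' Read / write an observed-peak table
#'
#' Schema: `peak_id`, `rt_min`, `mz`, `polarity` (`+`/`-`), `matrix`
#' (one of PS, PM, PA, U, F, L, LM), `area`. Leading `#` lines
#' (provenance headers) are skipped; diagnostics name the offending data
#' row.
#'
#' @param path CSV file path.
#' @return `readPeakTable()`: validated data.frame of peaks.
#' @export
readPeakTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("peak_id", "rt_min", "mz", "polarity", "matrix", "area")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("peak table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("rt_min", "mz", "area")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("unparseable %s in row %d of %s", col, bad[1], path))
    }
    tab[[col]] <- v
  }
  bad <- which(!tab$matrix %in% .MATRIX_CODES)
  if (length(bad)) {
    stop(sprintf("unknown matrix code %s in row %d of %s",
                 sQuote(tab$matrix[bad[1]]), bad[1], path))
  }
  if (any(tab$mz <= 0)) stop("m/z must be positive in ", path)
  if (any(tab$area < 0)) stop("peak area must be non-negative in ", path)
  tab
}

#' @rdname readPeakTable
#' @param peaks Peak data.frame with the schema above.
#' @param config Optional [runConfig()] written as a provenance header.
#' @export
writePeakTable <- function(peaks, path, config = NULL) {
  .writeCsv(peaks[, c("peak_id", "rt_min", "mz", "polarity", "matrix",
                      "area")], path, config)
  invisible(path)
}

#' Read / write MS/MS fragment lists as long-format CSV
#'
#' Schema: `peak_id`, `fragment_mz`, `relative_abundance` (percent of
#' base peak).
#'
#' @param path CSV file path.
#' @return `readMs2Table()`: data.frame of fragments.
#' @export
readMs2Table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("peak_id", "fragment_mz", "relative_abundance")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("MS2 table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname readMs2Table
#' @param ms2 Fragment data.frame with the schema above.
#' @param config Optional [runConfig()] provenance header.
#' @export
writeMs2Table <- function(ms2, path, config = NULL) {
  .writeCsv(ms2[, c("peak_id", "fragment_mz", "relative_abundance")],
            path, config)
  invisible(path)
}

#' Read / write MS/MS spectra in Mascot generic format (MGF)
#'
#' A deliberately small MGF subset: `BEGIN IONS` / `END IONS` blocks
#' with `TITLE=` (used as the peak id), optional `PEPMASS=` and
#' `CHARGE=`, and `m/z intensity` peak lines.
#'
#' @param path MGF file path.
#' @return `readMgf()`: data.frame with columns `peak_id`,
#'   `fragment_mz`, `relative_abundance` (and attribute `precursors`, a
#'   named numeric vector of PEPMASS values).
#' @export
readMgf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  prec <- numeric(0)
  title <- NULL
  buf <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (ln == "BEGIN IONS") {
      title <- NA_character_
      buf <- list()
    } else if (ln == "END IONS") {
      if (length(buf)) {
        m <- do.call(rbind, buf)
        out[[length(out) + 1L]] <- data.frame(
          peak_id = title, fragment_mz = m[, 1],
          relative_abundance = m[, 2], stringsAsFactors = FALSE)
      }
      title <- NULL
    } else if (startsWith(ln, "TITLE=")) {
      title <- substring(ln, 7L)
    } else if (startsWith(ln, "PEPMASS=")) {
      prec[title] <- as.numeric(strsplit(substring(ln, 9L), "[ \t]")[[1]][1])
    } else if (startsWith(ln, "CHARGE=")) {
      next
    } else if (!is.null(title)) {
      v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      if (anyNA(v[1:2])) stop("unparseable MGF peak line: ", sQuote(ln))
      buf[[length(buf) + 1L]] <- v[1:2]
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(peak_id = character(0), fragment_mz = numeric(0),
               relative_abundance = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "precursors") <- prec
  res
}

#' @rdname readMgf
#' @param ms2 Long-format fragment data.frame (`peak_id`, `fragment_mz`,
#'   `relative_abundance`).
#' @param precursors Optional named numeric vector of precursor m/z per
#'   peak id, written as `PEPMASS`.
#' @export
writeMgf <- function(ms2, path, precursors = NULL) {
  .atomicWrite(path, function(tmp) {
    con <- file(tmp, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (id in unique(ms2$peak_id)) {
      sub <- ms2[ms2$peak_id == id, , drop = FALSE]
      writeLines("BEGIN IONS", con)
      writeLines(paste0("TITLE=", id), con)
      if (!is.null(precursors) && id %in% names(precursors)) {
        writeLines(sprintf("PEPMASS=%.6f", precursors[[id]]), con)
      }
      writeLines(sprintf("%.6f %.4f", sub$fragment_mz,
                         sub$relative_abundance), con)
      writeLines(c("END IONS", ""), con)
    }
  })
  invisible(path)
}

## ---- command-line front end ------------------------------------------

#' Command-line entry point
#'
#' Thin dispatcher used by the installed `exec/biotransms` script.
#' Subcommands: `fixtures` (write the packaged reference tables),
#' `simulate` (write synthetic peak/MS2 tables), `annotate` (run the
#' annotation pipeline over peak-table CSVs), `fragments` (assign
#' neutral losses for one ladder), `pathway` and `network` (graph
#' construction and export).
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status: 0 on success, 2 on argument errors, 1 on
#'   data errors.
#' @export
runCli <- function(argv = character(0)) {
  usage <- paste(
    "usage: biotransms <subcommand> [options]",
    "  fixtures  --out DIR",
    "  simulate  --out DIR [--seed N] [--ppm-sd X] [--decoys N]",
    "  annotate  --peaks FILE[,FILE...] [--ms2 FILE] --out FILE",
    "            [--parent F] [--ppm X] [--max-steps N] [--log-level L]",
    "  fragments --precursor X --fragments X1,X2,...",
    "  pathway   --annotations FILE --out PREFIX",
    "  network   --out PREFIX [--seed N]",
    sep = "\n")
  if (length(argv) == 0L) {
    message(usage)
    return(2L)
  }
  opts <- .parseArgv(argv[-1])
  if (is.null(opts)) {
    message(usage)
    return(2L)
  }
  if (!is.null(opts[["log-level"]])) {
    setLogLevel(opts[["log-level"]])
  }
  cmd <- argv[1]
  handler <- switch(cmd,
    fixtures = .cliFixtures, simulate = .cliSimulate,
    annotate = .cliAnnotate, fragments = .cliFragments,
    pathway = .cliPathway, network = .cliNetwork,
    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(2L)
  }
  tryCatch({
    handler(opts)
    0L
  }, error = function(e) {
    .log("error", "%s", conditionMessage(e))
    1L
  })
}

.parseArgv <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      return(NULL)
    }
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.cliReq <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required option --", key)
  opts[[key]]
}

.cliFixtures <- function(opts) {
  dir <- .cliReq(opts, "out")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- loadFixtures()
  .writeCsv(fx$metabolites, file.path(dir, "metabolite_table.csv"))
  .writeCsv(fx$targetCounts, file.path(dir, "target_counts.csv"))
  .log("info", "wrote fixtures to %s", dir)
}

.cliSimulate <- function(opts) {
  dir <- .cliReq(opts, "out")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- simulationConfig(
    seed = as.integer(opts[["seed"]] %||% 1L),
    ppmSd = as.numeric(opts[["ppm-sd"]] %||% 1),
    decoyCount = as.integer(opts[["decoys"]] %||% 100L))
  sim <- simulatePeakTables(config = cfg)
  writePeakTable(sim$peaks, file.path(dir, "peaks.csv"))
  writeMs2Table(sim$ms2, file.path(dir, "ms2.csv"))
  .writeCsv(sim$truth, file.path(dir, "truth.csv"))
  .log("info", "wrote %d peaks (%d decoys) to %s", nrow(sim$peaks),
       sum(sim$peaks$decoy), dir)
}

.cliAnnotate <- function(opts) {
  files <- strsplit(.cliReq(opts, "peaks"), ",")[[1]]
  out <- .cliReq(opts, "out")
  peaks <- do.call(rbind, lapply(files, readPeakTable))
  ms2 <- if (!is.null(opts[["ms2"]])) {
    f <- opts[["ms2"]]
    if (grepl("\\.mgf$", f, ignore.case = TRUE)) readMgf(f) else readMs2Table(f)
  }
  cfg <- runConfig(parent = opts[["parent"]] %||% "C26H31O14",
                   tolPpm = as.numeric(opts[["ppm"]] %||% 5),
                   maxSteps = as.integer(opts[["max-steps"]] %||% 4L))
  rec <- annotateDataset(peaks, parent = cfg$parent, tolPpm = cfg$tolPpm,
                         maxSteps = cfg$maxSteps, ms2 = ms2,
                         rtWindow = cfg$rtWindow)
  exportAnnotationTable(rec, out, config = cfg)
  .log("info", "annotated %d metabolites -> %s", nrow(rec), out)
}

.cliFragments <- function(opts) {
  prec <- as.numeric(.cliReq(opts, "precursor"))
  frags <- as.numeric(strsplit(.cliReq(opts, "fragments"), ",")[[1]])
  res <- assignNeutralLosses(prec, frags)
  utils::write.csv(res, stdout(), row.names = FALSE)
}

.cliPathway <- function(opts) {
  rec <- readAnnotationTable(.cliReq(opts, "annotations"))
  pg <- buildPathwayGraph(rec)
  prefix <- .cliReq(opts, "out")
  writePathwayGraph(pg, paste0(prefix, ".graphml"), format = "graphml")
  writePathwayGraph(pg, paste0(prefix, ".sif"), format = "sif")
  writePathwayGraph(pg, paste0(prefix, ".dot"), format = "dot")
  .log("info", "pathway graph: %d nodes, %d edges", numNodes(pg), numEdges(pg))
}

.cliNetwork <- function(opts) {
  t2 <- mulberrosideTargetCounts()
  asg <- simulateTargetAssignment(
    stats::setNames(t2$target_number, t2$node_id),
    total = 167L, seed = as.integer(opts[["seed"]] %||% 1L))
  bip <- buildBipartite(asg)
  prefix <- .cliReq(opts, "out")
  writeNetwork(bip, paste0(prefix, ".tsv"), format = "edgelist")
  writeNetwork(bip, paste0(prefix, ".graphml"), format = "graphml")
  .log("info", "bipartite network: %d nodes, %d edges",
       numNodes(bip), numEdges(bip))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
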