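## Directed metabolic pathway graph reconstruction and route
## classification: direct modification of the parent, metabolism via the
## monoglucoside, metabolism via the aglycone, or anomeric cleavage.

#' Build the directed metabolic pathway graph
#'
#' Every annotated metabolite is connected to the parent (root) through
#' the intermediates implied by its reaction multiset. Steps are applied
#' in a canonical order -- hydrolysis first (deglycosylation precedes
#' conjugation in vivo), then the remaining reactions in lexical order --
#' so records sharing a prefix share intermediate nodes. One hydrolysis
#' leads through the monoglucoside hub, two through the aglycone hub.
#' Intermediate nodes are keyed by composition; terminal nodes by
#' metabolite id, so isomers remain distinct (except that metabolites
#' whose composition IS a hub merge into the hub node, e.g. the two
#' monoglucoside isomers, which cannot be told apart by composition).
#' The two cleavage products attach to the root by their named cleavage
#' edges.
#'
#' @param records Annotation records ([annotateDataset()]) or the
#'   packaged fixture ([mulberrosideMetabolites()]): needs columns
#'   `ion_formula`, `reactions`, a metabolite id column
#'   (`metabolite_id` or `peak_id`), and optionally `cleavage`.
#' @param parent Parent [ionSpecies()] or ion formula string.
#' @param library Reaction library used to resolve each record's
#'   multiset (including the hydrolysis multiplicity, which printed
#'   labels leave implicit).
#' @param maxSteps Step budget when resolving multisets.
#' @return A [PathwayGraph-class] object.
#' @examples
#' pg <- buildPathwayGraph(mulberrosideMetabolites())
#' pg
#' @export
buildPathwayGraph <- function(records, parent = mulberrosideIon(),
                              library = defaultReactionLibrary(),
                              maxSteps = 4L) {
  if (!is(parent, "IonSpecies")) parent <- ionSpecies(parent)
  idcol <- if ("metabolite_id" %in% names(records)) "metabolite_id" else "peak_id"
  rootF <- formatFormula(composition(parent))
  rootId <- "parent"

  nodes <- list()
  edges <- list()
  addNode <- function(id, formula, role, label = id) {
    if (is.null(nodes[[id]])) {
      nodes[[id]] <<- list(formula = formula, role = role, label = label)
    } else if (role == "metabolite" && nodes[[id]]$role == "hub") {
      ## record merging into a hub: extend the label
      nodes[[id]]$label <<- paste(nodes[[id]]$label, label, sep = "/")
    }
    id
  }
  addEdge <- function(from, to, reaction) {
    key <- paste(from, to, reaction, sep = "\r")
    edges[[key]] <<- list(from = from, to = to, reaction = reaction)
  }
  addNode(rootId, rootF, "root")

  for (i in seq_len(nrow(records))) {
    mid <- records[[idcol]][i]
    target <- records$ion_formula[i]
    if (isTRUE(records$cleavage[i]) ||
        "cleavage" %in% names(parseReactionList(records$reactions[i]))) {
      cid <- addNode(mid, target, "cleavage", mid)
      addEdge(rootId, cid, "cleavage")
      next
    }
    ms <- .resolveMultiset(parent, target, records$reactions[i],
                           library, maxSteps)
    if (is.null(ms)) {
      stop(sprintf(
        "record %s (%s): reaction list %s does not map the parent to %s",
        mid, target, sQuote(records$reactions[i]), target))
    }
    if (length(ms) == 0L) {
      ## the prototype or an isomer of it: merges into the root
      nodes[[rootId]]$label <- paste(nodes[[rootId]]$label, mid, sep = "/")
      next
    }
    ## canonical step order: hydrolysis first, then lexical
    steps <- character(0)
    if ("hydrolysis" %in% names(ms)) {
      steps <- rep("hydrolysis", ms[["hydrolysis"]])
    }
    rest <- ms[setdiff(names(ms), "hydrolysis")]
    rest <- rest[order(names(rest))]
    steps <- c(steps, rep(names(rest), rest))

    comp <- composition(parent)
    prev <- rootId
    for (k in seq_along(steps)) {
      st <- steps[k]
      d <- library$delta[[match(st, library$name)]]
      comp <- composeFormula(comp, d)
      f <- formatFormula(comp)
      last <- k == length(steps)
      id <- if (last) {
        if (f %in% c(.MONOGLUCOSIDE, .AGLYCONE)) {
          addNode(f, f, "hub", .hubLabel(f))
          addNode(f, f, "metabolite", mid)
          f
        } else {
          addNode(mid, f, "metabolite", mid)
        }
      } else if (f %in% c(.MONOGLUCOSIDE, .AGLYCONE)) {
        addNode(f, f, "hub", .hubLabel(f))
      } else {
        addNode(f, f, "intermediate", f)
      }
      addEdge(prev, id, st)
      prev <- id
    }
  }

  ids <- names(nodes)
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
    formula = vapply(nodes, `[[`, character(1), "formula"),
    role = vapply(nodes, `[[`, character(1), "role"),
    label = vapply(nodes, `[[`, character(1), "label"))
  if (length(edges)) {
    ft <- do.call(rbind, lapply(edges, function(e) c(e$from, e$to)))
    g <- igraph::add_edges(g, t(matrix(match(ft, ids), ncol = 2L)),
                           reaction = vapply(edges, `[[`, character(1),
                                             "reaction"))
  }
  new("PathwayGraph", graph = g, root = rootId)
}

.MONOGLUCOSIDE <- "C20H21O9"
.AGLYCONE <- "C14H11O4"

.hubLabel <- function(f) {
  if (f == .MONOGLUCOSIDE) "monoglucoside" else "aglycone"
}

## Resolve a record's reaction multiset: find the enumerated multiset
## matching the printed reaction names (hydrolysis multiplicity free),
## falling back to any multiset explaining the composition. NULL if the
## target is unreachable; empty multiset if target == parent.
.resolveMultiset <- function(parent, target, reactions, library, maxSteps) {
  printed <- parseReactionList(reactions)
  cands <- explainTransformation(parent, target, library, maxSteps)
  if (!length(cands)) {
    return(NULL)
  }
  matchesPrinted <- function(m) {
    a <- m[setdiff(names(m), "hydrolysis")]
    b <- printed[setdiff(names(printed), "hydrolysis")]
    identical(a[order(names(a))], b[order(names(b))]) &&
      (("hydrolysis" %in% names(m)) == ("hydrolysis" %in% names(printed)))
  }
  hit <- Filter(matchesPrinted, cands)
  if (length(hit)) hit[[1]] else cands[[1]]
}

#' Classify a metabolite into a metabolic route
#'
#' Route follows the hydrolysis multiplicity of the reaction multiset:
#' no hydrolysis = direct modification of the parent; one = metabolism
#' via the monoglucoside; two = metabolism via the aglycone; cleavage
#' products are a special class.
#'
#' @param multiset Reaction multiset (named integer vector), a
#'   semicolon reaction string, or a records data.frame (then a vector
#'   of routes is returned, resolving hydrolysis multiplicity through
#'   `parent`/`library`).
#' @param parent,library,maxSteps Used only for data.frame input.
#' @return Factor with levels `direct`, `monoglucoside`, `aglycone`,
#'   `cleavage`.
#' @examples
#' classifyRoute(c(hydrolysis = 2L, sulfation = 1L))  # aglycone
#' @export
classifyRoute <- function(multiset, parent = mulberrosideIon(),
                          library = defaultReactionLibrary(),
                          maxSteps = 4L) {
  lv <- c("direct", "monoglucoside", "aglycone", "cleavage")
  one <- function(m, isCleavage = FALSE) {
    if (isCleavage || "cleavage" %in% names(m)) {
      return("cleavage")
    }
    h <- if ("hydrolysis" %in% names(m)) m[["hydrolysis"]] else 0L
    c("direct", "monoglucoside", "aglycone")[h + 1L]
  }
  if (is.data.frame(multiset)) {
    records <- multiset
    out <- character(nrow(records))
    for (i in seq_len(nrow(records))) {
      if (isTRUE(records$cleavage[i]) ||
          "cleavage" %in% names(parseReactionList(records$reactions[i]))) {
        out[i] <- "cleavage"
        next
      }
      ms <- .resolveMultiset(parent, records$ion_formula[i],
                             records$reactions[i], library, maxSteps)
      if (is.null(ms)) stop("unreachable record at row ", i)
      out[i] <- one(ms)
    }
    return(factor(out, levels = lv))
  }
  if (is.character(multiset)) multiset <- parseReactionList(multiset)
  factor(one(multiset), levels = lv)
}

#' Export a pathway graph
#'
#' @param x A [PathwayGraph-class].
#' @param path Output file.
#' @param format `"graphml"`, `"sif"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
writePathwayGraph <- function(x, path, format = c("graphml", "sif", "dot")) {
  format <- match.arg(format)
  g <- asIgraph(x)
  if (format == "graphml") {
    .atomicWrite(path, function(tmp) {
      igraph::write_graph(g, tmp, format = "graphml")
    })
  } else if (format == "sif") {
    el <- igraph::as_edgelist(g)
    .atomicWrite(path, function(tmp) {
      writeLines(sprintf("%s\t%s\t%s", el[, 1],
                         igraph::E(g)$reaction, el[, 2]), tmp)
    })
  } else {
    el <- igraph::as_edgelist(g)
    .atomicWrite(path, function(tmp) {
      writeLines(c("digraph pathway {",
                   sprintf('  "%s" -> "%s" [label="%s"];', el[, 1], el[, 2],
                           igraph::E(g)$reaction),
                   "}"), tmp)
    })
  }
  invisible(path)
}
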