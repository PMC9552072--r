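## S4 classes for the central data objects.

#' @import methods
NULL

#' Elemental-formula constraints
#'
#' Holds per-element count ranges and an RDB range. Construct with
#' [formulaConstraints()].
#'
#' @slot elements Numeric matrix with rownames = element symbols and
#'   columns `min`, `max`.
#' @slot rdb Length-2 numeric RDB range.
#' @aliases FormulaConstraints
#' @exportClass FormulaConstraints
setClass("FormulaConstraints",
  representation(elements = "matrix", rdb = "numeric"),
  validity = function(object) {
    msg <- character(0)
    el <- object@elements
    if (is.null(rownames(el)) || ncol(el) != 2L) {
      msg <- c(msg, "elements must be a named (min, max) matrix")
    } else if (any(el[, 1] > el[, 2])) {
      msg <- c(msg, "element min exceeds max")
    }
    if (length(object@rdb) != 2L || object@rdb[1] > object@rdb[2]) {
      msg <- c(msg, "rdb must be c(min, max) with min <= max")
    }
    if (length(msg)) msg else TRUE
  }
)

#' A singly charged ion species
#'
#' Couples an ion formula (the formula of the charged species as printed
#' in annotation tables, e.g. `C26H31O14` for a deprotonated molecule)
#' with its polarity and the electron-mass convention used to compute its
#' theoretical m/z. Construct with [ionSpecies()].
#'
#' @slot composition Named integer vector of element counts.
#' @slot polarity `"negative"` or `"positive"`.
#' @slot charge Integer, always 1.
#' @slot mzConvention `"reported"` or `"physical"` (see [ionMz()]).
#' @aliases IonSpecies
#' @exportClass IonSpecies
setClass("IonSpecies",
  representation(composition = "integer", polarity = "character",
                 charge = "integer", mzConvention = "character"),
  prototype(charge = 1L, polarity = "negative", mzConvention = "reported"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@composition < 0L)) msg <- c(msg, "negative element count")
    if (!object@polarity %in% c("negative", "positive")) {
      msg <- c(msg, "polarity must be 'negative' or 'positive'")
    }
    if (!identical(object@charge, 1L)) {
      msg <- c(msg, "only singly charged ions are supported")
    }
    if (!object@mzConvention %in% c("reported", "physical")) {
      msg <- c(msg, "mzConvention must be 'reported' or 'physical'")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct an IonSpecies
#'
#' @param formula Ion formula string or named integer composition.
#' @param polarity `"negative"` (default) or `"positive"`.
#' @param mzConvention `"reported"` (default) or `"physical"`; see [ionMz()].
#' @return An [IonSpecies-class] object.
#' @examples
#' ion <- ionSpecies("C26H31O14")
#' ionMz(ion)
#' @export
ionSpecies <- function(formula, polarity = c("negative", "positive"),
                       mzConvention = c("reported", "physical")) {
  new("IonSpecies",
      composition = .asComposition(formula),
      polarity = match.arg(polarity),
      charge = 1L,
      mzConvention = match.arg(mzConvention))
}

#' @describeIn ionSpecies Element counts of the ion formula.
#' @param object,x An `IonSpecies`.
#' @export
composition <- function(object) {
  stopifnot(is(object, "IonSpecies"))
  object@composition
}

#' @describeIn ionSpecies Ion polarity.
#' @export
polarity <- function(object) {
  stopifnot(is(object, "IonSpecies"))
  object@polarity
}

#' @describeIn ionSpecies Electron-mass convention.
#' @export
mzConvention <- function(object) {
  stopifnot(is(object, "IonSpecies"))
  object@mzConvention
}

setMethod("show", "IonSpecies", function(object) {
  cat(sprintf("IonSpecies %s [%s, %s convention] m/z %.4f\n",
              formatFormula(object@composition),
              object@polarity, object@mzConvention, ionMz(object)))
})

setMethod("show", "FormulaConstraints", function(object) {
  el <- object@elements
  cat("FormulaConstraints:",
      paste(sprintf("%s[%g-%g]", rownames(el), el[, 1], el[, 2]),
            collapse = " "),
      sprintf("RDB[%g-%g]\n", object@rdb[1], object@rdb[2]))
})

#' Directed metabolic pathway graph
#'
#' A rooted directed acyclic graph whose nodes carry elemental
#' compositions and whose edges are labelled with a single
#' biotransformation step mapping the source composition to the target
#' composition. Construct with [buildPathwayGraph()].
#'
#' @slot graph An `igraph` directed graph. Vertex attributes: `formula`,
#'   `role` (root / hub / intermediate / metabolite / cleavage), `label`.
#'   Edge attribute: `reaction`.
#' @slot root Name of the root (parent drug) vertex.
#' @aliases PathwayGraph
#' @exportClass PathwayGraph
setClass("PathwayGraph",
  representation(graph = "ANY", root = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!igraph::is_igraph(object@graph)) {
      msg <- c(msg, "graph must be an igraph object")
    } else {
      if (!igraph::is_dag(object@graph)) msg <- c(msg, "graph must be acyclic")
      if (!object@root %in% igraph::V(object@graph)$name) {
        msg <- c(msg, "root vertex not present in graph")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Metabolite--target bipartite network
#'
#' Undirected two-layer graph with unweighted, deduplicated edges between
#' metabolite and target nodes. Construct with [buildBipartite()].
#'
#' @slot graph An undirected `igraph` graph; vertex attribute `layer` is
#'   `"metabolite"` or `"target"`.
#' @slot metabolites,targets Character vectors of node names per layer.
#' @aliases BipartiteNetwork
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
  representation(graph = "ANY", metabolites = "character",
                 targets = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!igraph::is_igraph(object@graph)) {
      msg <- c(msg, "graph must be an igraph object")
    } else {
      ## superclass validity runs on a coerced copy during subclass
      ## validation, so compare per-layer rather than total node count
      vn <- igraph::V(object@graph)$name
      lay <- igraph::V(object@graph)$layer
      if (!setequal(vn[lay == "metabolite"], object@metabolites) ||
          !setequal(vn[lay == "target"], object@targets)) {
        msg <- c(msg, "graph layers must match the metabolite/target sets")
      }
      if (!all(lay %in% c("metabolite", "target", "pathway"))) {
        msg <- c(msg, "unknown node layer")
      }
      if (igraph::any_multiple(object@graph)) {
        msg <- c(msg, "duplicate edges are not allowed")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Metabolite--target--pathway tripartite network
#'
#' A [BipartiteNetwork-class] core extended with pathway nodes and
#' (target, pathway) membership edges. Construct with [buildTripartite()].
#'
#' @slot pathways Character vector of pathway node names.
#' @aliases TripartiteNetwork
#' @exportClass TripartiteNetwork
setClass("TripartiteNetwork",
  contains = "BipartiteNetwork",
  representation(pathways = "character"),
  validity = function(object) {
    msg <- character(0)
    lay <- igraph::V(object@graph)$layer
    if (!setequal(igraph::V(object@graph)$name[lay == "pathway"],
                  object@pathways)) {
      msg <- c(msg, "graph pathway layer must match the pathway set")
    }
    n <- length(object@metabolites) + length(object@targets) +
      length(object@pathways)
    if (igraph::vcount(object@graph) != n) {
      msg <- c(msg, "node count must equal metabolites + targets + pathways")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Number of nodes / edges in a network object
#'
#' @param x A `PathwayGraph`, `BipartiteNetwork` or `TripartiteNetwork`.
#' @return Integer count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Extract the underlying igraph
#'
#' @param x A `PathwayGraph`, `BipartiteNetwork` or `TripartiteNetwork`.
#' @return The `igraph` object backing `x`.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname numNodes
setMethod("numNodes", "PathwayGraph", function(x) igraph::vcount(x@graph))
#' @rdname numNodes
setMethod("numEdges", "PathwayGraph", function(x) igraph::ecount(x@graph))
#' @rdname numNodes
setMethod("numNodes", "BipartiteNetwork", function(x) igraph::vcount(x@graph))
#' @rdname numNodes
setMethod("numEdges", "BipartiteNetwork", function(x) igraph::ecount(x@graph))

#' @rdname asIgraph
setMethod("asIgraph", "PathwayGraph", function(x) x@graph)
#' @rdname asIgraph
setMethod("asIgraph", "BipartiteNetwork", function(x) x@graph)

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("PathwayGraph rooted at %s: %d nodes, %d edges\n",
              object@root, numNodes(object), numEdges(object)))
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat(sprintf(
    "BipartiteNetwork: %d metabolites + %d targets = %d nodes, %d edges\n",
    length(object@metabolites), length(object@targets),
    numNodes(object), numEdges(object)))
})

setMethod("show", "TripartiteNetwork", function(object) {
  cat(sprintf(paste0(
    "TripartiteNetwork: %d metabolites + %d targets + %d pathways",
    " = %d nodes, %d edges\n"),
    length(object@metabolites), length(object@targets),
    length(object@pathways), numNodes(object), numEdges(object)))
})
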