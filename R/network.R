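## Metabolite-target bipartite and metabolite-target-pathway tripartite
## network construction with exact node/edge/degree accounting.

#' Build a metabolite--target bipartite network
#'
#' @param assignments data.frame with columns `metabolite` and `target`
#'   (e.g. from [simulateTargetAssignment()]); duplicate pairs are
#'   collapsed.
#' @return A [BipartiteNetwork-class]: undirected, unweighted, with
#'   `|metabolites| + |targets|` nodes and one edge per distinct pair.
#' @examples
#' bip <- buildBipartite(data.frame(metabolite = "N1", target = "T001"))
#' numNodes(bip); numEdges(bip)
#' @export
buildBipartite <- function(assignments) {
  stopifnot(all(c("metabolite", "target") %in% names(assignments)))
  assignments <- unique(assignments[, c("metabolite", "target")])
  mets <- sort(unique(assignments$metabolite))
  tgts <- sort(unique(assignments$target))
  if (length(intersect(mets, tgts))) {
    stop("metabolite and target node names must not overlap")
  }
  ids <- c(mets, tgts)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
    layer = c(rep("metabolite", length(mets)), rep("target", length(tgts))),
    type = c(rep(FALSE, length(mets)), rep(TRUE, length(tgts))))
  g <- igraph::add_edges(g, rbind(match(assignments$metabolite, ids),
                                  match(assignments$target, ids)))
  new("BipartiteNetwork", graph = g, metabolites = mets, targets = tgts)
}

#' Extend a bipartite network with pathway membership
#'
#' Adds pathway nodes and undirected (target, pathway) membership edges
#' to a metabolite--target network; node and edge counts are additive.
#'
#' @param bipartite A [BipartiteNetwork-class].
#' @param memberships data.frame with columns `target` and `pathway`;
#'   every target must exist in the bipartite network.
#' @return A [TripartiteNetwork-class].
#' @export
buildTripartite <- function(bipartite, memberships) {
  stopifnot(is(bipartite, "BipartiteNetwork"),
            all(c("target", "pathway") %in% names(memberships)))
  memberships <- unique(memberships[, c("target", "pathway")])
  unknown <- setdiff(memberships$target, bipartite@targets)
  if (length(unknown)) {
    stop("membership references unknown target(s): ",
         paste(sQuote(utils::head(unknown, 3L)), collapse = ", "))
  }
  paths <- sort(unique(memberships$pathway))
  g <- bipartite@graph
  if (length(paths)) {
    g <- igraph::add_vertices(g, length(paths), name = paths,
                              layer = rep("pathway", length(paths)),
                              type = rep(NA, length(paths)))
    ids <- igraph::V(g)$name
    g <- igraph::add_edges(g, rbind(match(memberships$target, ids),
                                    match(memberships$pathway, ids)))
  }
  new("TripartiteNetwork", graph = g, metabolites = bipartite@metabolites,
      targets = bipartite@targets, pathways = paths)
}

#' Per-node degree table
#'
#' @param network A [BipartiteNetwork-class] or [TripartiteNetwork-class].
#' @return data.frame (`node`, `layer`, `degree`) sorted by decreasing
#'   degree, ties broken by node id -- a deterministic ranking.
#' @examples
#' t2 <- mulberrosideTargetCounts()
#' bip <- buildBipartite(simulateTargetAssignment(
#'   setNames(t2$target_number, t2$node_id), 167, seed = 1))
#' head(degreeTable(bip), 3)
#' @export
degreeTable <- function(network) {
  stopifnot(is(network, "BipartiteNetwork"))
  g <- network@graph
  out <- data.frame(node = igraph::V(g)$name,
                    layer = igraph::V(g)$layer,
                    degree = as.integer(igraph::degree(g)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network
#'
#' `"edgelist"` writes a TSV with columns `source`, `target`, `layer`
#' (the layer pair, e.g. `metabolite-target`); `"graphml"` uses igraph's
#' writer; `"sif"` writes Cytoscape simple-interaction lines.
#'
#' @param network A [BipartiteNetwork-class] or [TripartiteNetwork-class].
#' @param path Output file.
#' @param format `"edgelist"`, `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path,
                         format = c("edgelist", "graphml", "sif")) {
  format <- match.arg(format)
  g <- network@graph
  el <- igraph::as_edgelist(g)
  lay <- stats::setNames(igraph::V(g)$layer, igraph::V(g)$name)
  pair <- paste(lay[el[, 1]], lay[el[, 2]], sep = "-")
  if (format == "edgelist") {
    .atomicWrite(path, function(tmp) {
      writeLines(c("source\ttarget\tlayer",
                   sprintf("%s\t%s\t%s", el[, 1], el[, 2], pair)), tmp)
    })
  } else if (format == "graphml") {
    .atomicWrite(path, function(tmp) {
      igraph::write_graph(g, tmp, format = "graphml")
    })
  } else {
    .atomicWrite(path, function(tmp) {
      writeLines(sprintf("%s\t%s\t%s", el[, 1], pair, el[, 2]), tmp)
    })
  }
  invisible(path)
}

#' Rebuild a network from an exported edge list
#'
#' @param path TSV written by [writeNetwork()] (`format = "edgelist"`).
#' @return A [BipartiteNetwork-class] or [TripartiteNetwork-class],
#'   depending on whether pathway edges are present.
#' @export
readNetworkEdgelist <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mt <- tab[tab$layer %in% c("metabolite-target", "target-metabolite"), ]
  bip <- buildBipartite(data.frame(metabolite = mt$source,
                                   target = mt$target,
                                   stringsAsFactors = FALSE))
  pw <- tab[tab$layer %in% c("target-pathway", "pathway-target"), ]
  if (nrow(pw)) {
    buildTripartite(bip, data.frame(target = pw$source,
                                    pathway = pw$target,
                                    stringsAsFactors = FALSE))
  } else {
    bip
  }
}
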