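test_that("pathway graph is a rooted DAG with exact edge-label mass conservation", {
  t1 <- mulberrosideMetabolites()
  pg <- buildPathwayGraph(t1)
  g <- asIgraph(pg)
  expect_true(igraph::is_dag(g))
  expect_equal(pg@root, "parent")

  lib <- defaultReactionLibrary()
  el <- igraph::as_edgelist(g)
  vf <- setNames(igraph::V(g)$formula, igraph::V(g)$name)
  for (i in seq_len(igraph::ecount(g))) {
    rx <- igraph::E(g)$reaction[i]
    if (rx == "cleavage") next
    d <- lib$delta[[match(rx, lib$name)]]
    expect_equal(formatFormula(composeFormula(vf[[el[i, 1]]], d)),
                 vf[[el[i, 2]]],
                 info = paste(el[i, ], collapse = " -> "))
  }
})

test_that("the aglycone hub sits two hydrolysis edges below the root", {
  pg <- buildPathwayGraph(mulberrosideMetabolites())
  g <- asIgraph(pg)
  path <- igraph::shortest_paths(g, from = "parent", to = "C14H11O4",
                                 output = "epath")$epath[[1]]
  expect_length(path, 2L)
  expect_equal(unname(igraph::E(g)$reaction[path]), rep("hydrolysis", 2))
  # monoglucoside hub is the intermediate
  vpath <- igraph::shortest_paths(g, "parent", "C14H11O4")$vpath[[1]]
  expect_equal(igraph::V(g)$name[vpath][2], "C20H21O9")
  expect_match(igraph::V(g)$label[vpath][2], "monoglucoside")
})

test_that("every non-cleavage record is chained to the root through its multiset", {
  t1 <- mulberrosideMetabolites()
  pg <- buildPathwayGraph(t1)
  g <- asIgraph(pg)
  parent <- mulberrosideIon()
  lib <- defaultReactionLibrary()
  vf <- setNames(igraph::V(g)$formula, igraph::V(g)$name)
  hasEdge <- function(from, to, rx) {
    eid <- suppressWarnings(igraph::get_edge_ids(g, c(from, to)))
    eid != 0 && igraph::E(g)$reaction[eid] == rx
  }
  for (i in seq_len(nrow(t1))) {
    if (t1$cleavage[i]) next
    ms <- BiotransMS:::.resolveMultiset(parent, t1$ion_formula[i],
                                        t1$reactions[i], lib, 4L)
    if (length(ms) == 0L) {
      # the prototype and its isomer merge into the root node
      expect_match(igraph::V(g)$label[vf == "C26H31O14" &
                                        igraph::V(g)$role == "root"],
                   t1$peak_id[i], fixed = TRUE)
      next
    }
    # canonical chain: hydrolysis first, then lexical order
    steps <- c(rep("hydrolysis",
                   if ("hydrolysis" %in% names(ms)) ms[["hydrolysis"]] else 0L))
    rest <- ms[setdiff(names(ms), "hydrolysis")]
    rest <- rest[order(names(rest))]
    steps <- c(steps, rep(names(rest), rest))
    comp <- composition(parent)
    prev <- "parent"
    for (k in seq_along(steps)) {
      comp <- composeFormula(comp, lib$delta[[match(steps[k], lib$name)]])
      f <- formatFormula(comp)
      node <- if (k == length(steps)) {
        if (f %in% c("C20H21O9", "C14H11O4")) f else t1$peak_id[i]
      } else f
      expect_true(hasEdge(prev, node, steps[k]),
                  info = sprintf("%s step %d (%s)", t1$peak_id[i], k,
                                 steps[k]))
      prev <- node
    }
    # the walked path length is the total number of applied reactions
    expect_equal(length(steps), sum(ms), info = t1$peak_id[i])
  }
})

test_that("route classification partitions records by hydrolysis multiplicity", {
  expect_equal(as.character(classifyRoute(c(sulfation = 1L))), "direct")
  expect_equal(as.character(classifyRoute("hydrolysis;glucuronidation")),
               "monoglucoside")
  expect_equal(as.character(classifyRoute(c(hydrolysis = 2L,
                                            methylation = 1L))),
               "aglycone")
  expect_equal(as.character(classifyRoute(c(cleavage = 1L))), "cleavage")

  t1 <- mulberrosideMetabolites()
  rt <- classifyRoute(t1)
  expect_false(anyNA(rt))           # a partition: every record classified
  expect_equal(length(rt), nrow(t1))
  byId <- setNames(as.character(rt), t1$peak_id)
  expect_equal(byId[["M4"]], "direct")
  expect_equal(byId[["M3"]], "monoglucoside")
  expect_equal(byId[["M10"]], "aglycone")
  expect_equal(byId[["M1"]], "cleavage")
  # stable under record reordering
  rt2 <- classifyRoute(t1[rev(seq_len(nrow(t1))), ])
  expect_equal(as.vector(table(rt2)), as.vector(table(rt)))
})

test_that("pathway graphs export to GraphML, SIF and DOT", {
  pg <- buildPathwayGraph(mulberrosideMetabolites())
  gml <- withr::local_tempfile(fileext = ".graphml")
  writePathwayGraph(pg, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), numNodes(pg))
  expect_equal(igraph::ecount(back), numEdges(pg))

  sif <- withr::local_tempfile(fileext = ".sif")
  writePathwayGraph(pg, sif, "sif")
  expect_equal(length(readLines(sif)), numEdges(pg))

  dot <- withr::local_tempfile(fileext = ".dot")
  writePathwayGraph(pg, dot, "dot")
  lines <- readLines(dot)
  expect_match(lines[1], "digraph")
  expect_equal(length(lines), numEdges(pg) + 2L)
})
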