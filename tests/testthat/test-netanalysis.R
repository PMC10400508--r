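graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]), directed = FALSE
  )
}

test_that("edge list reader builds a simple undirected graph", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), path)
  g <- read_edge_list(path)
  expect_equal(igraph::ecount(g), 2) # A-B deduplicated, loop dropped
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "C\tpp\tD"), sif)
  gs <- read_edge_list(sif)
  expect_equal(igraph::ecount(gs), 2)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(igraph::vcount(read_edge_list(empty)), 0)
})

test_that("first-order subnetwork keeps seeds, neighbours and their edges", {
  tri <- graph_from_pairs("A", "B", "B", "C", "A", "C")
  fo <- first_order_subnetwork(tri, "A")
  expect_setequal(igraph::V(fo$graph)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(fo$graph), 3)

  path4 <- graph_from_pairs("A", "B", "B", "C", "C", "D")
  fo2 <- first_order_subnetwork(path4, "A")
  expect_setequal(igraph::V(fo2$graph)$name, c("A", "B"))
  expect_equal(igraph::ecount(fo2$graph), 1)

  fo3 <- first_order_subnetwork(path4, "Z")
  expect_equal(igraph::vcount(fo3$graph), 0)
  expect_equal(fo3$absent_seeds, "Z")
})

test_that("minimum network retains connecting paths and prunes non-seed leaves", {
  # unique connecting path: all intermediate nodes become connectors
  chain <- graph_from_pairs("v1", "v2", "v2", "v3", "v3", "v4", "v4", "v5")
  fo <- first_order_subnetwork(chain, c("v1", "v5"))
  # first-order around v1,v5 is not the whole chain; run on the full graph
  mn <- minimum_interaction_network(chain, seeds = c("v1", "v5"))
  expect_setequal(igraph::V(mn$graph)$name, paste0("v", 1:5))
  expect_setequal(mn$connectors, c("v2", "v3", "v4"))

  # adjacent seeds: the edge alone, no connectors
  mn2 <- minimum_interaction_network(graph_from_pairs("A", "B", "B", "C"),
    seeds = c("A", "B"))
  expect_setequal(igraph::V(mn2$graph)$name, c("A", "B"))
  expect_equal(mn2$connectors, character(0))

  # seeds in different components are connected per component
  two <- graph_from_pairs("A", "X", "X", "B", "C", "Y", "Y", "D")
  mn3 <- minimum_interaction_network(two, seeds = c("A", "B", "C", "D"))
  comp <- igraph::components(mn3$graph)
  expect_equal(comp$no, 2)
  expect_setequal(mn3$connectors, c("X", "Y"))

  # seed absent from the graph is an orphan
  mn4 <- minimum_interaction_network(two, seeds = c("A", "B", "ZZ"))
  expect_equal(mn4$orphan_seeds, "ZZ")
})

test_that("Steiner heuristic contains terminals, has no non-seed leaf, and is near-optimal", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(6:14, 1)
    g <- random_connected_graph(n, extra_edges = sample(2:8, 1))
    terms <- sample(igraph::V(g)$name, sample(2:4, 1))
    mn <- minimum_interaction_network(g, seeds = terms)
    nodes <- igraph::V(mn$graph)$name
    expect_true(all(terms %in% nodes))
    deg <- igraph::degree(mn$graph)
    non_seed_leaves <- setdiff(names(deg)[deg <= 1], terms)
    expect_equal(non_seed_leaves, character(0))
    opt <- brute_steiner_nodes(g, terms)
    expect_lte(length(nodes), 2 * opt)
  }
})

test_that("betweenness matches closed forms and the naive oracle", {
  # path A-B-C: B mediates the single pair
  pth <- graph_from_pairs("A", "B", "B", "C")
  sc <- betweenness_scores(pth)
  expect_equal(sc$betweenness[sc$symbol == "B"], 1)
  expect_equal(sum(sc$betweenness[sc$symbol != "B"]), 0)

  # star: center mediates C(4,2) = 6 pairs
  star <- graph_from_pairs("c", "l1", "c", "l2", "c", "l3", "c", "l4")
  scs <- betweenness_scores(star)
  expect_equal(scs$betweenness[scs$symbol == "c"], 6)

  set.seed(99)
  for (i in 1:20) {
    g <- random_connected_graph(sample(5:30, 1), extra_edges = sample(0:15, 1))
    got <- betweenness_scores(g)
    oracle <- naive_betweenness(g)
    expect_equal(
      stats::setNames(got$betweenness, got$symbol), oracle[got$symbol],
      tolerance = 1e-9
    )
  }
})

test_that("hub ranking orders by betweenness, then degree, then symbol", {
  # two branch nodes with equal betweenness but different degree
  g <- graph_from_pairs(
    "HUB", "A", "HUB", "B", "B", "B1", "B", "B2", "B", "B3",
    "A", "A1"
  )
  hubs <- rank_hubs(g, k = 3)
  expect_equal(hubs$rank, 1:3)
  expect_true(hubs$is_top_hub[1])
  expect_false(any(hubs$is_top_hub[-1]))
  # B mediates more pairs than A; both beat leaves
  expect_equal(hubs$symbol[1], "B")

  # pure tie: equal betweenness and degree resolved lexicographically
  sq <- graph_from_pairs("A", "B", "B", "C", "C", "D", "D", "A")
  hsq <- rank_hubs(sq, k = 4)
  expect_equal(hsq$symbol, c("A", "B", "C", "D"))

  expect_error(rank_hubs(igraph::make_empty_graph(0, directed = FALSE)), "empty")
})

test_that("network export round-trips GraphML and writes SIF lines", {
  tri <- graph_from_pairs("A", "B", "B", "C", "A", "C")
  mn <- minimum_interaction_network(tri, seeds = c("A", "B"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(mn, gml, format = "graphml", hubs = rank_hubs(mn, k = 1))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(mn$graph)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(mn$graph))
  expect_true("is_hub" %in% igraph::vertex_attr_names(back))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(tri, sif, format = "sif")
  expect_equal(length(readLines(sif)), 3)
  expect_error(export_network(tri, sif, format = "dot"), "should be one of")
})
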