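#' Read an undirected protein-protein interaction edge list
#'
#' Accepts a two-column TSV (`from<TAB>to`, optional header) or a SIF file
#' (`from<TAB>relation<TAB>to`). The result is a simple undirected graph:
#' duplicate edges (in either orientation) are merged and self-loops are
#' dropped, with a note of how many.
#'
#' @param path Path to the edge list.
#' @param dialect `"auto"` (default; SIF by `.sif` extension or 3 columns),
#'   `"tsv"` or `"sif"`.
#'
#' @return An `igraph` undirected simple graph with vertex `name` attributes.
#' @export
read_edge_list <- function(path, dialect = c("auto", "tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("edge list not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "sif" || all(nf == 3)) "sif" else "tsv"
  }
  want <- if (dialect == "sif") 3L else 2L
  bad <- which(nf < want)
  if (length(bad) > 0) {
    abort(paste0("edge list parse error: expected ", want, " fields at line ", bad[1]))
  }
  from <- vapply(fields, `[[`, character(1), 1)
  to <- vapply(fields, `[[`, character(1), if (dialect == "sif") 3 else 2)
  # tolerate a header row in TSV dialect
  if (dialect == "tsv" && tolower(from[1]) %in% c("from", "source", "node1", "proteina")) {
    from <- from[-1]
    to <- to[-1]
  }
  edges_to_graph(tibble(from = from, to = to))
}

## build a simple undirected graph from an edge tibble, logging dropped loops
edges_to_graph <- function(edges) {
  self <- edges$from == edges$to
  if (any(self)) {
    rp_inform("read_edge_list: dropped ", sum(self), " self-loop(s)")
    edges <- edges[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' First-order subnetwork around seed proteins
#'
#' Extracts the subgraph containing the seed proteins present in the
#' interactome, all their direct interactors, and every interactome edge
#' between nodes of that set.
#'
#' @param network An `igraph` interactome, as from [read_edge_list()].
#' @param seeds Character vector of seed gene symbols (symbols absent from
#'   the interactome are reported, not an error).
#'
#' @return A list with `graph` (the first-order `igraph`), `seeds` (seeds
#'   found in the network) and `absent_seeds`.
#' @export
first_order_subnetwork <- function(network, seeds) {
  seeds <- unique(seeds)
  present <- intersect(seeds, igraph::V(network)$name)
  absent <- setdiff(seeds, present)
  if (length(present) == 0) {
    return(list(
      graph = igraph::make_empty_graph(0, directed = FALSE),
      seeds = character(0), absent_seeds = absent
    ))
  }
  nbr <- unique(unlist(lapply(igraph::adjacent_vertices(network, present), names)))
  keep <- union(present, nbr)
  list(
    graph = igraph::induced_subgraph(network, keep),
    seeds = present,
    absent_seeds = absent
  )
}

#' Minimum interaction network over seed proteins
#'
#' Reduces a first-order subnetwork to a minimum interaction network: the
#' seed (differentially expressed) proteins plus only the connector nodes
#' needed to maximally connect them. Within each connected component holding
#' at least two seeds, an approximate minimum node-count Steiner tree over
#' the seed terminals is built with unit edge weights by the
#' Kou-Markowsky-Berman scheme: metric closure of the terminals, minimum
#' spanning tree of the closure, expansion of closure edges into shortest
#' paths, a spanning tree of the expanded subgraph, then iterative pruning
#' of non-seed leaves. Components with a single reachable seed collapse to
#' that seed alone.
#'
#' @param first_order Result of [first_order_subnetwork()] (or an `igraph`
#'   plus a `seeds` argument).
#' @param seeds Seed symbols; defaults to those recorded in `first_order`.
#'
#' @return An object of class `minimum_network`: list with `graph`
#'   (`igraph`), `seeds` (seeds retained in the network), `connectors`
#'   (non-seed retained nodes) and `orphan_seeds` (seeds absent from the
#'   first-order network or isolated in it).
#' @export
minimum_interaction_network <- function(first_order, seeds = NULL) {
  if (igraph::is_igraph(first_order)) {
    g <- first_order
    if (is.null(seeds)) abort("minimum_interaction_network: seeds required with a bare igraph")
  } else {
    g <- first_order$graph
    seeds <- seeds %||% first_order$seeds
  }
  seeds <- unique(seeds)
  present <- intersect(seeds, igraph::V(g)$name)
  orphan <- setdiff(seeds, present)

  if (length(present) == 0) {
    return(new_minimum_network(
      igraph::make_empty_graph(0, directed = FALSE),
      character(0), character(0), orphan
    ))
  }

  comp <- igraph::components(g)
  membership <- comp$membership[present]
  keep_nodes <- character(0)
  keep_edges <- matrix(character(0), ncol = 2)

  for (cid in sort(unique(membership))) {
    terms <- present[membership == cid]
    if (length(terms) == 1) {
      # single reachable seed: collapses to the seed alone; isolated seeds
      # (degree 0) are reported as orphans instead
      if (igraph::degree(g, terms) == 0) {
        orphan <- c(orphan, terms)
      } else {
        keep_nodes <- c(keep_nodes, terms)
      }
      next
    }
    sub <- igraph::induced_subgraph(g, names(comp$membership)[comp$membership == cid])
    tree <- steiner_tree_kmb(sub, terms)
    keep_nodes <- c(keep_nodes, igraph::V(tree)$name)
    if (igraph::ecount(tree) > 0) {
      keep_edges <- rbind(keep_edges, igraph::as_edgelist(tree))
    }
  }

  mg <- igraph::graph_from_data_frame(
    as.data.frame(keep_edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = unique(keep_nodes)
  )
  new_minimum_network(
    mg,
    seeds = intersect(present, igraph::V(mg)$name),
    connectors = setdiff(igraph::V(mg)$name, present),
    orphan_seeds = unique(orphan)
  )
}

new_minimum_network <- function(graph, seeds, connectors, orphan_seeds) {
  structure(
    list(
      graph = graph, seeds = seeds, connectors = connectors,
      orphan_seeds = orphan_seeds
    ),
    class = "minimum_network"
  )
}

#' @export
print.minimum_network <- function(x, ...) {
  cat("<minimum_network> ", length(x$seeds), " seeds, ",
    length(x$connectors), " connectors, ",
    igraph::ecount(x$graph), " edges",
    if (length(x$orphan_seeds) > 0) {
      paste0(" (", length(x$orphan_seeds), " orphan seeds)")
    } else {
      ""
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname minimum_interaction_network
#' @param x A `minimum_network` object.
#' @param ... Unused.
#' @method tidy minimum_network
#' @export
tidy.minimum_network <- function(x, ...) {
  nodes <- igraph::V(x$graph)$name
  tibble(
    symbol = nodes,
    role = ifelse(nodes %in% x$seeds, "seed", "connector"),
    degree = as.integer(igraph::degree(x$graph))
  )
}

#' @rdname minimum_interaction_network
#' @method glance minimum_network
#' @export
glance.minimum_network <- function(x, ...) {
  tibble(
    n_seeds = length(x$seeds),
    n_connectors = length(x$connectors),
    n_edges = igraph::ecount(x$graph),
    n_orphan_seeds = length(x$orphan_seeds)
  )
}

## KMB 2-approximate Steiner tree over `terminals` in connected graph `g`,
## unit edge weights; returns an igraph tree containing all terminals
steiner_tree_kmb <- function(g, terminals) {
  vnames <- igraph::V(g)$name
  terminals <- intersect(terminals, vnames)
  if (length(terminals) == 1) {
    return(igraph::induced_subgraph(g, terminals))
  }
  # 1. metric closure of the terminals
  d <- igraph::distances(g, v = terminals, to = terminals)
  closure_edges <- which(upper.tri(d), arr.ind = TRUE)
  cg <- igraph::graph_from_data_frame(
    data.frame(
      from = terminals[closure_edges[, 1]],
      to = terminals[closure_edges[, 2]],
      weight = d[closure_edges]
    ),
    directed = FALSE
  )
  # 2. MST of the closure
  cmst <- igraph::mst(cg, weights = igraph::E(cg)$weight)
  # 3. expand each closure edge into a concrete shortest path
  el <- igraph::as_edgelist(cmst)
  nodes <- character(0)
  for (i in seq_len(nrow(el))) {
    sp <- igraph::shortest_paths(g, from = el[i, 1], to = el[i, 2], output = "vpath")
    nodes <- union(nodes, names(sp$vpath[[1]]))
  }
  sub <- igraph::induced_subgraph(g, nodes)
  # 4. spanning tree of the expanded subgraph
  tree <- igraph::mst(sub)
  # 5. prune non-terminal leaves to a fixpoint
  repeat {
    leaves <- igraph::V(tree)$name[igraph::degree(tree) <= 1]
    drop <- setdiff(leaves, terminals)
    if (length(drop) == 0) break
    tree <- igraph::delete_vertices(tree, drop)
  }
  tree
}

#' Betweenness centrality of every node
#'
#' Unnormalized shortest-path betweenness (Brandes accumulation): for each
#' unordered pair of other nodes, a node is credited the fraction of
#' equal-length shortest paths between the pair that pass through it.
#'
#' @param network An `igraph` graph or a `minimum_network`.
#' @return A tibble with `symbol`, `betweenness`, `degree`, sorted as the
#'   graph stores its vertices. Empty graph gives an empty tibble.
#' @export
betweenness_scores <- function(network) {
  g <- if (inherits(network, "minimum_network")) network$graph else network
  if (igraph::vcount(g) == 0) {
    return(tibble(symbol = character(), betweenness = numeric(), degree = integer()))
  }
  tibble(
    symbol = igraph::V(g)$name,
    betweenness = as.numeric(igraph::betweenness(g, directed = FALSE, normalized = FALSE)),
    degree = as.integer(igraph::degree(g))
  )
}

#' Rank hub proteins by betweenness centrality
#'
#' The top `k` nodes ranked by betweenness descending define the hub
#' proteins; ties are broken by node degree descending, remaining ties
#' lexicographically by symbol so the ranking is a total order. The rank-1
#' entry is flagged the top hub.
#'
#' @param network An `igraph` graph or a `minimum_network` (in which case
#'   seed status is annotated).
#' @param k Number of hubs to return (default 5). If the network has fewer
#'   nodes, all are returned.
#'
#' @return A tibble of class `hub_ranking`: `symbol`, `betweenness`,
#'   `degree`, `rank`, `is_seed`, `is_top_hub`.
#' @export
rank_hubs <- function(network, k = 5) {
  seeds <- if (inherits(network, "minimum_network")) network$seeds else character(0)
  sc <- betweenness_scores(network)
  if (nrow(sc) == 0) abort("rank_hubs: empty network")
  ord <- lex_order(-sc$betweenness, -sc$degree, sc$symbol)
  sc <- sc[ord, , drop = FALSE]
  sc <- head(sc, k)
  sc$rank <- seq_len(nrow(sc))
  sc$is_seed <- sc$symbol %in% seeds
  sc$is_top_hub <- sc$rank == 1L
  class(sc) <- c("hub_ranking", class(sc))
  sc
}

#' Export a network to GraphML or SIF
#'
#' Writes the graph with node attributes `is_seed`, `is_connector`,
#' `is_hub`, `betweenness` and `degree` (GraphML), or plain
#' `node<TAB>pp<TAB>node` interaction lines (SIF). GraphML files round-trip
#' through [igraph::read_graph()] with node and edge sets intact.
#'
#' @param network An `igraph` graph or a `minimum_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @param hubs Optional [rank_hubs()] result used to flag hub nodes.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif"), hubs = NULL) {
  format <- match.arg(format)
  g <- if (inherits(network, "minimum_network")) network$graph else network
  seeds <- if (inherits(network, "minimum_network")) network$seeds else character(0)

  if (format == "sif") {
    el <- igraph::as_edgelist(g)
    readr::write_lines(paste(el[, 1], "pp", el[, 2], sep = "\t"), path)
    return(invisible(path))
  }

  sc <- betweenness_scores(g)
  idx <- match(igraph::V(g)$name, sc$symbol)
  igraph::V(g)$is_seed <- as.integer(igraph::V(g)$name %in% seeds)
  igraph::V(g)$is_connector <- as.integer(!(igraph::V(g)$name %in% seeds))
  igraph::V(g)$is_hub <- as.integer(igraph::V(g)$name %in% (hubs$symbol %||% character(0)))
  igraph::V(g)$betweenness <- sc$betweenness[idx]
  igraph::V(g)$degree <- sc$degree[idx]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
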