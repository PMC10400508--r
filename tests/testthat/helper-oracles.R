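# Independent brute-force oracles used to check the package's computations.
# Each is coded from the definition, not from the implementation it checks.

options(retproteome.quiet = TRUE)

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) equally likely draws: universe = 1..N, annotated = 1..K.
enum_hypergeom <- function(x, n, K, N) {
  if (n == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= x)
}

# Naive O(m^2) BH step-up: q_i = min over j with p_j >= p_i of p_j * m / rank_j.
naive_bh <- function(p) {
  m <- length(p)
  # rank of p_j for the step-up denominator uses the max rank among ties
  r_max <- rank(p, ties.method = "max")
  vals <- p * m / r_max
  vapply(seq_len(m), function(i) min(c(vals[p >= p[i]], 1)), numeric(1))
}

# Naive betweenness from the definition: credit each middle node the fraction
# of shortest s-t paths through it, each unordered pair counted once.
# Shortest-path counts by BFS-layer dynamic programming on the adjacency matrix.
naive_betweenness <- function(g) {
  n <- igraph::vcount(g)
  names_g <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- igraph::distances(g)
  sigma <- function(s) {
    # sigma[s, v] = number of shortest paths s -> v
    cnt <- numeric(n)
    cnt[s] <- 1
    ds <- D[s, ]
    for (d in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (v in which(ds == d)) {
        pred <- which(A[, v] > 0 & ds == d - 1)
        cnt[v] <- sum(cnt[pred])
      }
    }
    cnt
  }
  sig <- t(vapply(seq_len(n), sigma, numeric(n)))
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + sig[s, v] * sig[t, v] / sig[s, t]
        }
      }
    }
  }
  stats::setNames(bc, names_g)
}

# Exact minimum Steiner node count: smallest |terminals| + |extra connectors|
# over all connector subsets whose induced subgraph connects the terminals.
brute_steiner_nodes <- function(g, terminals) {
  vn <- igraph::V(g)$name
  others <- setdiff(vn, terminals)
  connects <- function(nodes) {
    sub <- igraph::induced_subgraph(g, nodes)
    comp <- igraph::components(sub)
    idx <- match(terminals, igraph::V(sub)$name)
    length(unique(comp$membership[idx])) == 1
  }
  for (k in 0:length(others)) {
    if (k == 0) {
      if (connects(terminals)) return(length(terminals))
      next
    }
    combos <- utils::combn(others, k, simplify = FALSE)
    for (extra in combos) {
      if (connects(c(terminals, extra))) return(length(terminals) + k)
    }
  }
  Inf
}

# Random connected simple graph on n nodes (named V1..Vn): spanning tree plus
# extra random edges.
random_connected_graph <- function(n, extra_edges = n) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  if (extra_edges > 0) {
    more <- cbind(
      sample.int(n, extra_edges, replace = TRUE),
      sample.int(n, extra_edges, replace = TRUE)
    )
    edges <- rbind(edges, more[more[, 1] != more[, 2], , drop = FALSE])
  }
  df <- data.frame(from = paste0("V", edges[, 1]), to = paste0("V", edges[, 2]))
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
    vertices = paste0("V", seq_len(n)))
  igraph::simplify(g)
}

# Small valid protein table for reader/filter tests.
tiny_protein_table <- function() {
  tbl <- tibble::tibble(
    accession = c("GI000001", "GI000002", "GI000003"),
    gene_symbol = c("ACTA1", "KRT10", "PKM"),
    n_peptides = c(5L, 4L, 1L),
    coverage_pct = c(30, 20, 10),
    is_reverse_hit = FALSE
  )
  for (ct in ret_contrasts()) {
    tbl[[paste0("ratio_", ct)]] <- c(1.5, 1.0, 0.6)
    tbl[[paste0("p_", ct)]] <- c(0.01, 0.5, 0.2)
  }
  tbl
}

# Long call table built directly from direction triples, for reversal tests.
calls_from_directions <- function(symbols, baseline, young, old) {
  ratio_for <- function(dir) ifelse(dir == "UP", 1.5, ifelse(dir == "DOWN", 0.6, 1.0))
  dirs <- list(
    old_vs_young_baseline = baseline,
    young_post_vs_pre = young,
    old_post_vs_pre = old
  )
  purrr::map_dfr(names(dirs), function(ct) {
    tibble::tibble(
      accession = symbols,
      gene_symbol = symbols,
      contrast = ct,
      ratio = ratio_for(dirs[[ct]]),
      p_value = 0.01,
      direction = dirs[[ct]],
      tier = ifelse(dirs[[ct]] == "UNCHANGED", "NONE", "SIGNIFICANT"),
      differential = dirs[[ct]] != "UNCHANGED"
    )
  })
}
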