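test_that("configuration errors name the offending field", {
  expect_error(synthetic_config(frac_up = 0.7, frac_down = 0.5), "frac_up")
  expect_error(synthetic_config(up_ratio_range = c(1.1, 2)), "up_ratio_range")
  expect_error(synthetic_config(down_ratio_range = c(0.5, 0.9)), "down_ratio_range")
  expect_error(synthetic_config(n_replicates = 1), "n_replicates")
  expect_error(
    synthetic_config(n_network_nodes = 6, planted_connector_count = 2),
    "n_network_nodes"
  )
  expect_error(
    synthetic_config(planted_term_size = 15, planted_term_up_members = 10),
    "planted_term_up_members"
  )
})

test_that("planted counts are forced by the configured fractions", {
  cfg <- synthetic_config(
    n_proteins = 200, frac_up = 0.1, frac_down = 0.1, seed = 7
  )
  prot <- generate_protein_table(cfg)
  expect_equal(nrow(prot$proteins), 200)
  counts <- prot$truth$de_labels |> dplyr::count(contrast, direction)
  expect_true(all(counts$n == 20))

  # label consistency: planted ratios always cross the cut-offs
  calls <- tidy(screen_contrasts(prot$proteins))
  joined <- dplyr::inner_join(
    calls, prot$truth$de_labels,
    by = c("gene_symbol", "contrast"), suffix = c("", "_truth")
  )
  expect_true(all(joined$ratio[joined$direction_truth == "UP"] > 1.2))
  expect_true(all(joined$ratio[joined$direction_truth == "DOWN"] < 0.8))
  # planted P-values sit at or below the configured bound
  expect_true(all(joined$p_value <= cfg$sig_p_max))
})

test_that("same config and seed give byte-identical bundles", {
  cfg <- synthetic_config(
    n_proteins = 60, n_network_nodes = 80,
    planted_term_size = 8, planted_term_up_members = 7, seed = 123
  )
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  write_fixture_bundle(cfg, d1)
  write_fixture_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = paste("bundle file", f)
    )
  }
  # a different seed changes the tables
  cfg2 <- synthetic_config(
    n_proteins = 60, n_network_nodes = 80,
    planted_term_size = 8, planted_term_up_members = 7, seed = 124
  )
  d3 <- file.path(withr::local_tempdir(), "b3")
  write_fixture_bundle(cfg2, d3)
  expect_false(identical(
    readLines(file.path(d1, "proteins.tsv")),
    readLines(file.path(d3, "proteins.tsv"))
  ))
})

test_that("fixture bundle round-trips through disk", {
  cfg <- synthetic_config(
    n_proteins = 50, n_network_nodes = 60,
    planted_term_size = 8, planted_term_up_members = 7, seed = 42
  )
  dir <- file.path(withr::local_tempdir(), "bundle")
  bundle <- write_fixture_bundle(cfg, dir)
  expect_setequal(
    list.files(dir),
    c("proteins.tsv", "annotations.gmt", "ppi_edges.tsv", "phospho.tsv",
      "truth.json", "config.json")
  )
  back <- read_fixture_bundle(dir)
  expect_equal(back$proteins$accession, bundle$proteins$accession)
  expect_equal(back$proteins$ratio_old_post_vs_pre,
    bundle$proteins$ratio_old_post_vs_pre, tolerance = 1e-9)
  expect_equal(back$terms$term_id, bundle$terms$term_id)
  expect_equal(back$terms$members, bundle$terms$members)
  expect_equal(igraph::ecount(back$network), igraph::ecount(bundle$network))
  expect_equal(as.data.frame(back$truth$de_labels),
    as.data.frame(bundle$truth$de_labels))
  expect_equal(back$truth$hub_ids, bundle$truth$hub_ids)
  expect_equal(back$config$seed, cfg$seed)

  # every labelled entity exists in the generated tables
  expect_true(all(back$truth$de_labels$gene_symbol %in% back$proteins$gene_symbol))
  expect_true(all(back$truth$hub_ids %in% igraph::V(back$network)$name))
  expect_true(all(back$truth$enriched_term_ids %in% back$terms$term_id))
  expect_true(all(back$truth$phospho_effects$peptide_id %in% back$peptides$peptide_id))
})

test_that("interactome communities are bridged only through planted connectors", {
  cfg <- synthetic_config(n_network_nodes = 104, planted_connector_count = 1, seed = 9)
  net <- generate_ppi_network(cfg)
  g <- net$network
  expect_equal(net$truth$hub_ids, "LINK01")
  expect_equal(igraph::components(g)$no, 1)
  # bridge property: removing the connectors disconnects the graph
  cut <- igraph::delete_vertices(g, net$truth$hub_ids)
  expect_gte(igraph::components(cut)$no, 2)
  # the single connector has strictly maximal betweenness
  sc <- betweenness_scores(g)
  expect_equal(sc$symbol[which.max(sc$betweenness)], "LINK01")

  # no connectors: single community, empty truth hub list
  cfg0 <- synthetic_config(n_network_nodes = 50, planted_connector_count = 0, seed = 9)
  net0 <- generate_ppi_network(cfg0)
  expect_equal(net0$truth$hub_ids, character(0))
  expect_equal(igraph::components(net0$network)$no, 1)
})

test_that("annotation generator plants term membership as configured", {
  cfg <- synthetic_config(term_size_range = c(5, 5), n_terms = 10, seed = 4)
  prot <- generate_protein_table(cfg)
  anno <- generate_annotation_sets(cfg, prot$proteins, prot$truth)
  expect_equal(nrow(anno$terms), 10)
  expect_true(all(lengths(anno$terms$members[anno$terms$term_id != "PLANTED_SET_1"]) == 5))
  planted <- anno$terms$members[[which(anno$terms$term_id == "PLANTED_SET_1")]]
  expect_length(planted, 15)
  up <- prot$truth$de_labels$gene_symbol[
    prot$truth$de_labels$contrast == cfg$planted_term_contrast &
      prot$truth$de_labels$direction == "UP"
  ]
  expect_equal(sum(planted %in% up), cfg$planted_term_up_members)

  # no planted ids: uniform terms only
  cfg2 <- synthetic_config(planted_term_ids = character(0), n_terms = 5, seed = 4)
  anno2 <- generate_annotation_sets(cfg2, prot$proteins, prot$truth)
  expect_equal(nrow(anno2$terms), 5)
  expect_equal(anno2$truth$enriched_term_ids, character(0))

  # planted term larger than the planted-UP pool is a configuration error
  cfg3 <- synthetic_config(
    n_proteins = 30, frac_up = 0.1, frac_down = 0.1,
    planted_term_up_members = 12, planted_term_size = 15, seed = 4
  )
  prot3 <- generate_protein_table(cfg3)
  expect_error(generate_annotation_sets(cfg3, prot3$proteins, prot3$truth), "planted-UP")
})

test_that("degenerate null configuration yields unit ratios and no calls", {
  cfg <- synthetic_config(
    n_proteins = 30, frac_up = 0, frac_down = 0, null_log_sd = 0, seed = 1
  )
  prot <- generate_protein_table(cfg)
  for (ct in ret_contrasts()) {
    expect_true(all(prot$proteins[[paste0("ratio_", ct)]] == 1))
  }
  expect_equal(screen_contrasts(prot$proteins)$n_differential, 0)
})
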