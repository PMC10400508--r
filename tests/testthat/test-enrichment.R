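test_that("GMT parsing handles members, duplicates, directives and bad lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "# category=KEGG",
    "T1\tdesc one\tGENEA\tGENEB",
    "T2\tdesc two\tGENEA\tGENEA\tgenec"
  ), path)
  terms <- read_gmt(path)
  expect_equal(nrow(terms), 2)
  expect_equal(terms$category, c("KEGG", "KEGG"))
  expect_equal(terms$members[[1]], c("GENEA", "GENEB"))
  expect_equal(terms$members[[2]], c("GENEA", "GENEC")) # dedup + uppercase

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tG1", "T2\tonly-two-fields"), bad)
  expect_error(read_gmt(bad), "line 2")

  # category inferred from file name
  kegg <- file.path(withr::local_tempdir(), "sets_kegg.gmt")
  writeLines("T1\td\tG1\tG2", kegg)
  expect_equal(read_gmt(kegg)$category, "KEGG")

  # round-trip through write_gmt
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(terms, out)
  back <- read_gmt(out)
  expect_equal(back$term_id, terms$term_id)
  expect_equal(back$members, terms$members)
})

test_that("hypergeometric tail matches closed forms", {
  # all 3 drawn from the 4 annotated among 10: C(4,3)/C(10,3) = 4/120
  expect_equal(hypergeom_pvalue(3, 3, 4, 10), 4 / 120, tolerance = 1e-12)
  # zero overlap: upper tail from zero is 1
  expect_equal(hypergeom_pvalue(0, 5, 3, 10), 1)
  expect_error(hypergeom_pvalue(4, 3, 4, 10), "inconsistent")
  expect_error(hypergeom_pvalue(1, 3, 11, 10), "inconsistent")
})

test_that("hypergeometric tail equals exhaustive enumeration for N <= 12", {
  for (N in c(5, 8, 12)) {
    for (n in 0:N) {
      for (K in 0:N) {
        for (x in 0:min(n, K)) {
          expect_equal(
            hypergeom_pvalue(x, n, K, N),
            enum_hypergeom(x, n, K, N),
            tolerance = 1e-12,
            label = sprintf("x=%d n=%d K=%d N=%d", x, n, K, N)
          )
        }
      }
    }
  }
})

test_that("BH adjustment matches the naive step-up oracle and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone: sorting by p sorts q non-decreasingly
    expect_true(!is.unsorted(q[order(p)]))
    # aligned output: permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("over-representation recovers a planted term and handles degenerate lists", {
  cfg <- synthetic_config(seed = 3)
  prot <- generate_protein_table(cfg)
  anno <- generate_annotation_sets(cfg, prot$proteins, prot$truth)
  up <- prot$truth$de_labels |>
    dplyr::filter(contrast == cfg$planted_term_contrast, direction == "UP") |>
    dplyr::pull(gene_symbol)

  res <- enrich_list(up, anno$terms)
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$term_id[1], "PLANTED_SET_1")
  expect_lt(res$q[1], 0.01)
  expect_true(res$significant[1])
  expect_true(all(res$q >= res$p))
  expect_true(all(res$x >= 1))

  # disjoint query: empty result
  expect_equal(nrow(suppressWarnings(enrich_list("NOTAGENE", anno$terms))), 0)

  # query = universe: every term saturates with p = 1
  uni <- unique(unlist(anno$terms$members))
  sat <- enrich_list(uni, anno$terms)
  expect_true(all(sat$x == sat$K))
  expect_true(all(sat$p == 1))

  # tightening the FDR threshold never gains significant terms
  n_tight <- sum(enrich_list(up, anno$terms, fdr_threshold = 0.001)$significant)
  expect_lte(n_tight, sum(res$significant))

  expect_error(enrich_list("A", anno$terms[0, ]), "empty universe")

  # symbols outside the universe are dropped with a warning
  expect_warning(
    withr::with_options(list(retproteome.quiet = FALSE), {
      enrich_list(c(up, "ZZZZ9"), anno$terms)
    }),
    "outside the universe"
  )
})
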