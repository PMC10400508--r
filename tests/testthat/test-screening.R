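test_that("protein table reader validates schema and values", {
  tbl <- tiny_protein_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  rd <- read_protein_table(path)
  expect_equal(nrow(rd), 3)
  expect_equal(rd$accession, tbl$accession)

  # missing P column for one contrast is a schema error naming it
  bad <- tbl[, setdiff(names(tbl), "p_old_post_vs_pre")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path2)
  expect_error(read_protein_table(path2), "p_old_post_vs_pre")

  # a zero ratio is a validation error citing the row
  bad2 <- tbl
  bad2$ratio_young_post_vs_pre[2] <- 0
  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad2, path3)
  expect_error(read_protein_table(path3), "row.*2")

  # header matching is case-insensitive
  up <- tbl
  names(up) <- toupper(names(up))
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(up, path4)
  expect_equal(nrow(read_protein_table(path4)), 3)

  expect_error(read_protein_table("table.xlsx"), "not found|XLSX")
})

test_that("exclusion filters drop contaminants, reverse hits and low-evidence proteins", {
  tbl <- tiny_protein_table() # KRT10 contaminant, PKM has 1 peptide
  tbl <- dplyr::bind_rows(tbl, dplyr::mutate(tbl[1, ],
    accession = "GI000009", gene_symbol = "MYH7", is_reverse_hit = TRUE
  ))
  res <- apply_exclusion_filters(tbl)
  expect_equal(res$retained$gene_symbol, "ACTA1")
  expect_equal(
    res$exclusions$reason[match(c("KRT10", "PKM", "MYH7"), res$exclusions$gene_symbol)],
    c("contaminant", "min_peptides", "reverse_hit")
  )
  expect_equal(sum(res$report$n_excluded), 3)
  expect_equal(nrow(res$retained) + nrow(res$exclusions), nrow(tbl))

  # idempotent
  res2 <- apply_exclusion_filters(res$retained)
  expect_identical(res2$retained, res$retained)
})

test_that("regulation calls follow strict fold-change cut-offs and P tiers", {
  th <- screening_thresholds()
  cases <- tibble::tribble(
    ~ratio, ~p, ~direction, ~tier,
    1.35, 0.02, "UP", "SIGNIFICANT",
    0.80, 0.01, "UNCHANGED", "NONE", # boundary is strict
    1.20, 0.01, "UNCHANGED", "NONE",
    0.75, 0.08, "DOWN", "TREND",
    1.50, 0.05, "UP", "TREND", # sig_p boundary falls into trend band
    1.50, 0.10, "UP", "TREND", # trend boundary inclusive
    1.50, 0.11, "UP", "FC_ONLY",
    0.60, 0.50, "DOWN", "FC_ONLY"
  )
  got <- call_regulation(cases$ratio, cases$p, th)
  expect_equal(got$direction, cases$direction)
  expect_equal(got$tier, cases$tier)

  expect_error(call_regulation(-1, 0.5), "positive")
  expect_error(call_regulation(1.5, 1.5), "\\[0, 1\\]")
  expect_error(screening_thresholds(up_cutoff = 0.9), "down_cutoff < 1 < up_cutoff")
})

test_that("screening conserves counts and is monotone in the up cut-off", {
  cfg <- synthetic_config(n_proteins = 120, seed = 11)
  prot <- generate_protein_table(cfg)
  screen <- screen_contrasts(prot$proteins)
  # conservation: per contrast, UP + DOWN + UNCHANGED = total
  expect_true(all(
    screen$summary$n_up + screen$summary$n_down + screen$summary$n_unchanged ==
      nrow(prot$proteins)
  ))
  # raising the up cut-off never increases the UP count
  for (up in c(1.3, 1.6, 2.0)) {
    s2 <- screen_contrasts(prot$proteins, screening_thresholds(up_cutoff = up))
    expect_true(all(s2$summary$n_up <= screen$summary$n_up))
    screen_prev <- s2
  }
})

test_that("noise-free synthetic table recovers planted truth exactly", {
  cfg <- synthetic_config(n_proteins = 150, null_log_sd = 0, seed = 5)
  prot <- generate_protein_table(cfg)
  screen <- screen_contrasts(prot$proteins)
  truth_counts <- prot$truth$de_labels |>
    dplyr::count(contrast, direction) |>
    tidyr::pivot_wider(names_from = direction, values_from = n)
  for (i in seq_len(nrow(screen$summary))) {
    ct <- screen$summary$contrast[i]
    tc <- truth_counts[truth_counts$contrast == ct, ]
    expect_equal(screen$summary$n_up[i], tc$UP)
    expect_equal(screen$summary$n_down[i], tc$DOWN)
    # the called symbols are exactly the planted ones
    expect_setequal(
      differential_symbols(screen, ct, "UP"),
      prot$truth$de_labels$gene_symbol[
        prot$truth$de_labels$contrast == ct & prot$truth$de_labels$direction == "UP"
      ]
    )
  }
  # all ratios exactly 1 with nothing planted: zero differential calls
  cfg0 <- synthetic_config(
    n_proteins = 50, frac_up = 0, frac_down = 0,
    null_log_sd = 0, seed = 2
  )
  prot0 <- generate_protein_table(cfg0)
  s0 <- screen_contrasts(prot0$proteins)
  expect_equal(s0$n_differential, 0)
  expect_true(all(s0$summary$n_unchanged == 50))
})

test_that("require_significance gates differential status on the P tier", {
  tbl <- tiny_protein_table()[1, ] # ratio 1.5 everywhere
  tbl$p_old_vs_young_baseline <- 0.5 # FC_ONLY
  th <- screening_thresholds(require_significance = TRUE)
  screen <- screen_contrasts(tbl, th)
  calls <- tidy(screen)
  b <- calls[calls$contrast == "old_vs_young_baseline", ]
  expect_equal(b$direction, "UP")
  expect_false(b$differential)
  expect_equal(
    screen$summary$n_up[screen$summary$contrast == "old_vs_young_baseline"], 0
  )
})
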