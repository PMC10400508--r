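#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic pooled 4-plex iTRAQ study with known planted ground
#' truth: a quantified-protein table with planted up/down effects per
#' contrast, a gene-set collection with planted enriched terms, a two-community
#' interactome joined only through planted connector (bridge) nodes, and a
#' phosphopeptide table with planted effects and decoy rows. Defaults mirror
#' a pooled sarcoplasmic muscle study: 164 analysis-ready proteins with
#' per-contrast planted up/down fractions 29/164, 21/164, 26/164 and 31/164,
#' 16/164, 19/164 (old-vs-young baseline, young RET, old RET respectively)
#' and 40 phosphopeptides of which a quarter are decoys.
#'
#' @param n_proteins Number of protein rows. Default 164.
#' @param frac_up,frac_down Planted up/down fractions per contrast (length 1
#'   or 3, ordered as [ret_contrasts()]). `frac_up + frac_down <= 1`
#'   elementwise.
#' @param responsive_frac Fraction of proteins eligible for planted effects.
#'   Effects for every contrast are drawn from this shared responsive pool,
#'   so differential sets overlap across contrasts the way repeated
#'   measurements of the same biology do. Default 73/164. Must satisfy
#'   `frac_up + frac_down <= responsive_frac` per contrast.
#' @param up_ratio_range Linear-ratio interval for planted UP effects;
#'   must lie entirely above 1.2. Default `c(1.3, 2.5)`.
#' @param down_ratio_range Interval for planted DOWN effects; entirely
#'   inside (0, 0.8). Default `c(0.4, 0.75)`.
#' @param null_log_sd Standard deviation of null log-ratios (lognormal about
#'   1). Default 0.08.
#' @param sig_p_max Upper bound for planted-effect P-values. Default 0.05.
#' @param trend_frac Fraction of planted effects given a trend-band P-value
#'   in (0.05, 0.1\]. Default 0.
#' @param n_terms Number of gene sets in the annotation collection. Default 50.
#' @param term_size_range Integer interval for random term sizes. Default
#'   `c(5, 25)`.
#' @param planted_term_ids Identifiers of terms guaranteed enriched.
#' @param planted_term_size Size of each planted term. Default 15.
#' @param planted_term_up_members Number of planted-UP members per planted
#'   term (>= 80% of the term). Default 13.
#' @param planted_term_contrast Contrast whose planted-UP proteins populate
#'   planted terms. Default `"old_vs_young_baseline"`.
#' @param n_network_nodes Interactome size. Default 200. Must be at least
#'   `2 * planted_connector_count + 4`.
#' @param attach_degree Preferential-attachment edges per new node. Default 2.
#' @param bridge_degree Edges from each planted connector into each community.
#'   Default 8: connectors are deliberately well-connected bridges, as a
#'   bottleneck protein joining two modules must be, so that they dominate
#'   the cross-community shortest paths they are planted to carry.
#' @param planted_connector_count Number of planted bridge nodes joining the
#'   two communities. Default 2.
#' @param n_phosphopeptides Phosphopeptide rows. Default 40.
#' @param n_replicates Replicate measurements per condition (>= 2). Default 3.
#' @param decoy_frac Fraction of phosphopeptide rows that are decoys
#'   (non-phospho, mis-allocated or confidence < 10). Default 0.25.
#' @param phospho_frac_up,phospho_frac_down Planted phospho effect fractions
#'   per contrast among non-decoy peptides. Default 0.1 each.
#' @param replicate_log_sd Replicate noise SD in log space. Default 0.1.
#' @param n_contaminants,n_low_evidence,n_reverse Extra rows appended to the
#'   protein table that the exclusion filter must remove. Default 0.
#' @param seed Integer RNG seed.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 164,
                             frac_up = c(29, 21, 26) / 164,
                             frac_down = c(31, 16, 19) / 164,
                             responsive_frac = 73 / 164,
                             up_ratio_range = c(1.3, 2.5),
                             down_ratio_range = c(0.4, 0.75),
                             null_log_sd = 0.08,
                             sig_p_max = 0.05,
                             trend_frac = 0,
                             n_terms = 50,
                             term_size_range = c(5, 25),
                             planted_term_ids = "PLANTED_SET_1",
                             planted_term_size = 15,
                             planted_term_up_members = 13,
                             planted_term_contrast = "old_vs_young_baseline",
                             n_network_nodes = 200,
                             attach_degree = 2,
                             bridge_degree = 8,
                             planted_connector_count = 2,
                             n_phosphopeptides = 40,
                             n_replicates = 3,
                             decoy_frac = 0.25,
                             phospho_frac_up = 0.1,
                             phospho_frac_down = 0.1,
                             replicate_log_sd = 0.1,
                             n_contaminants = 0,
                             n_low_evidence = 0,
                             n_reverse = 0,
                             seed = 1L) {
  cfg_error <- function(field, msg) {
    abort(paste0("synthetic_config: invalid `", field, "`: ", msg))
  }
  rep3 <- function(x, field) {
    if (!length(x) %in% c(1, 3)) cfg_error(field, "length must be 1 or 3")
    if (any(x < 0 | x > 1)) cfg_error(field, "fractions must lie in [0, 1]")
    rep_len(x, 3)
  }
  frac_up <- rep3(frac_up, "frac_up")
  frac_down <- rep3(frac_down, "frac_down")
  if (any(frac_up + frac_down > 1)) cfg_error("frac_up", "frac_up + frac_down must be <= 1")
  if (responsive_frac < 0 || responsive_frac > 1) {
    cfg_error("responsive_frac", "must lie in [0, 1]")
  }
  if (any(frac_up + frac_down > responsive_frac + 1e-12)) {
    cfg_error("responsive_frac", "responsive pool too small for the planted fractions")
  }
  if (n_proteins < 1) cfg_error("n_proteins", "must be >= 1")
  if (length(up_ratio_range) != 2 || any(up_ratio_range <= 1.2) ||
    up_ratio_range[1] > up_ratio_range[2]) {
    cfg_error("up_ratio_range", "must be an interval entirely above 1.2")
  }
  if (length(down_ratio_range) != 2 || any(down_ratio_range >= 0.8) ||
    any(down_ratio_range <= 0) || down_ratio_range[1] > down_ratio_range[2]) {
    cfg_error("down_ratio_range", "must be an interval inside (0, 0.8)")
  }
  if (null_log_sd < 0) cfg_error("null_log_sd", "must be >= 0")
  if (sig_p_max <= 0 || sig_p_max > 1) cfg_error("sig_p_max", "must be in (0, 1]")
  if (trend_frac < 0 || trend_frac > 1) cfg_error("trend_frac", "must be in [0, 1]")
  if (length(term_size_range) != 2 || term_size_range[1] > term_size_range[2] ||
    term_size_range[1] < 1) {
    cfg_error("term_size_range", "must be a positive integer interval")
  }
  if (planted_term_up_members > planted_term_size) {
    cfg_error("planted_term_up_members", "cannot exceed planted_term_size")
  }
  if (length(planted_term_ids) > 0 &&
    planted_term_up_members / planted_term_size < 0.8) {
    cfg_error("planted_term_up_members", "planted terms must be >= 80% planted-UP members")
  }
  planted_term_contrast <- match.arg(planted_term_contrast, ret_contrasts())
  if (planted_connector_count < 0) cfg_error("planted_connector_count", "must be >= 0")
  if (n_network_nodes < 2 * planted_connector_count + 4) {
    cfg_error("n_network_nodes", "must be >= 2 * planted_connector_count + 4")
  }
  if (attach_degree < 1) cfg_error("attach_degree", "must be >= 1")
  if (bridge_degree < 1) cfg_error("bridge_degree", "must be >= 1")
  if (n_replicates < 2) cfg_error("n_replicates", "t-tests need >= 2 replicates")
  if (decoy_frac < 0 || decoy_frac >= 1) cfg_error("decoy_frac", "must be in [0, 1)")
  if (phospho_frac_up + phospho_frac_down > 1) {
    cfg_error("phospho_frac_up", "phospho effect fractions must sum to <= 1")
  }
  if (replicate_log_sd < 0) cfg_error("replicate_log_sd", "must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) cfg_error("seed", "must be an integer")

  structure(
    list(
      n_proteins = as.integer(n_proteins),
      frac_up = frac_up, frac_down = frac_down,
      responsive_frac = responsive_frac,
      up_ratio_range = up_ratio_range, down_ratio_range = down_ratio_range,
      null_log_sd = null_log_sd, sig_p_max = sig_p_max, trend_frac = trend_frac,
      n_terms = as.integer(n_terms), term_size_range = as.integer(term_size_range),
      planted_term_ids = planted_term_ids,
      planted_term_size = as.integer(planted_term_size),
      planted_term_up_members = as.integer(planted_term_up_members),
      planted_term_contrast = planted_term_contrast,
      n_network_nodes = as.integer(n_network_nodes),
      attach_degree = as.integer(attach_degree),
      bridge_degree = as.integer(bridge_degree),
      planted_connector_count = as.integer(planted_connector_count),
      n_phosphopeptides = as.integer(n_phosphopeptides),
      n_replicates = as.integer(n_replicates),
      decoy_frac = decoy_frac,
      phospho_frac_up = phospho_frac_up, phospho_frac_down = phospho_frac_down,
      replicate_log_sd = replicate_log_sd,
      n_contaminants = as.integer(n_contaminants),
      n_low_evidence = as.integer(n_low_evidence),
      n_reverse = as.integer(n_reverse),
      seed = seed
    ),
    class = "synthetic_config"
  )
}

syn_symbol <- function(i) sprintf("SYN%04d", i)

## deterministic per-stage RNG scope: same config => same draws per generator
with_stage_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

#' Generate a synthetic quantified-protein table with planted truth
#'
#' Produces `n_proteins` rows with three ratio and three P-value columns.
#' Per contrast, `round(frac_up * n)` proteins get a ratio drawn from
#' `up_ratio_range` with P <= `sig_p_max` (a `trend_frac` share gets a
#' trend-band P instead), `round(frac_down * n)` the DOWN analogue; the rest
#' are nulls with ratio `exp(Normal(0, null_log_sd))` and P ~ Uniform(0.1, 1).
#' Optional contaminant / low-evidence / reverse-hit rows exercise the
#' exclusion filter and are never planted.
#'
#' @param config A [synthetic_config()].
#' @return A list with `proteins` (tibble in [read_protein_table()] layout)
#'   and `truth` (list; `de_labels` maps gene symbol x contrast to direction).
#' @export
generate_protein_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_stage_seed(config$seed, 1L, {
    n <- config$n_proteins
    symbols <- syn_symbol(seq_len(n))
    tbl <- tibble(
      accession = sprintf("GI%06d", seq_len(n)),
      gene_symbol = symbols,
      n_peptides = 2L + stats::rpois(n, 4),
      coverage_pct = round(runif(n, 5, 70), 1),
      is_reverse_hit = FALSE
    )
    labels <- list()
    pool_size <- round(config$responsive_frac * n)
    pool <- sample.int(n, pool_size)
    for (k in seq_along(ret_contrasts())) {
      ct <- ret_contrasts()[k]
      n_up <- round(config$frac_up[k] * n)
      n_down <- round(config$frac_down[k] * n)
      idx <- pool[sample.int(pool_size, n_up + n_down)]
      up_idx <- idx[seq_len(n_up)]
      down_idx <- idx[n_up + seq_len(n_down)]

      ratio <- exp(rnorm(n, 0, config$null_log_sd))
      p <- runif(n, 0.1, 1)
      ratio[up_idx] <- runif(n_up, config$up_ratio_range[1], config$up_ratio_range[2])
      ratio[down_idx] <- runif(n_down, config$down_ratio_range[1], config$down_ratio_range[2])
      planted <- c(up_idx, down_idx)
      p[planted] <- runif(length(planted), 0, config$sig_p_max)
      if (config$trend_frac > 0 && length(planted) > 0) {
        n_trend <- round(config$trend_frac * length(planted))
        trend_idx <- planted[seq_len(n_trend)]
        p[trend_idx] <- runif(n_trend, 0.05, 0.1)
      }
      tbl[[paste0("ratio_", ct)]] <- ratio
      tbl[[paste0("p_", ct)]] <- p
      labels[[ct]] <- tibble(
        gene_symbol = c(symbols[up_idx], symbols[down_idx]),
        contrast = ct,
        direction = rep(c("UP", "DOWN"), c(n_up, n_down))
      )
    }
    tbl <- append_excluded_rows(tbl, config)
    list(
      proteins = tbl,
      truth = list(de_labels = dplyr::bind_rows(labels))
    )
  })
}

append_excluded_rows <- function(tbl, config) {
  extra_n <- config$n_contaminants + config$n_low_evidence + config$n_reverse
  if (extra_n == 0) return(tbl)
  mk <- function(m, sym_prefix, n_pep, reverse) {
    if (m == 0) return(NULL)
    row <- tibble(
      accession = sprintf("GX%06d", seq_len(m) + nrow(tbl)),
      gene_symbol = sprintf("%s%d", sym_prefix, seq_len(m)),
      n_peptides = n_pep,
      coverage_pct = round(runif(m, 5, 70), 1),
      is_reverse_hit = reverse
    )
    for (ct in ret_contrasts()) {
      row[[paste0("ratio_", ct)]] <- exp(rnorm(m, 0, config$null_log_sd))
      row[[paste0("p_", ct)]] <- runif(m, 0.1, 1)
    }
    row
  }
  dplyr::bind_rows(
    tbl,
    mk(config$n_contaminants, "KRT", 5L, FALSE),
    mk(config$n_low_evidence, "LOWEV", 1L, FALSE),
    mk(config$n_reverse, "REVHIT", 5L, TRUE)
  )
}

#' Generate a two-community interactome with planted bridge connectors
#'
#' Builds two preferential-attachment communities whose node labels are
#' synthetic gene symbols shared with the protein table, joined only through
#' `planted_connector_count` bridge nodes: every path between the
#' communities passes a connector, so the connectors carry all
#' inter-community shortest paths and are the planted high-betweenness hubs.
#' With zero connectors a single community is generated and the truth hub
#' list is empty.
#'
#' @param config A [synthetic_config()].
#' @return A list with `network` (`igraph`), `edges` (tibble) and `truth`
#'   (list with `hub_ids`, the planted connector labels).
#' @export
generate_ppi_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_stage_seed(config$seed, 2L, {
    n <- config$n_network_nodes
    ncon <- config$planted_connector_count
    m <- config$attach_degree
    connectors <- if (ncon > 0) sprintf("LINK%02d", seq_len(ncon)) else character(0)
    comm_symbols <- sample(syn_symbol(seq_len(n - ncon)))

    pa_edges <- function(labels) {
      g <- igraph::sample_pa(length(labels), m = m, directed = FALSE)
      el <- igraph::as_edgelist(g)
      tibble(from = labels[el[, 1]], to = labels[el[, 2]])
    }

    if (ncon == 0) {
      edges <- pa_edges(comm_symbols)
    } else {
      half <- floor(length(comm_symbols) / 2)
      comm_a <- comm_symbols[seq_len(half)]
      comm_b <- comm_symbols[(half + 1):length(comm_symbols)]
      bridge <- purrr::map_dfr(connectors, function(cn) {
        k <- min(config$bridge_degree, length(comm_a), length(comm_b))
        tibble(
          from = cn,
          to = c(sample(comm_a, k), sample(comm_b, k))
        )
      })
      edges <- dplyr::bind_rows(pa_edges(comm_a), pa_edges(comm_b), bridge)
    }
    g <- edges_to_graph(edges)
    el <- igraph::as_edgelist(g)
    list(
      network = g,
      edges = tibble(from = el[, 1], to = el[, 2]),
      truth = list(hub_ids = connectors)
    )
  })
}

#' Generate a gene-set collection with planted enriched terms
#'
#' Planted terms draw `planted_term_up_members` of their
#' `planted_term_size` members from the planted-UP proteins of the
#' designated contrast (at least 80% of the term) and the remainder from the
#' other symbols; all other terms sample members uniformly from the protein
#' table's symbol universe.
#'
#' @param config A [synthetic_config()].
#' @param proteins Protein tibble from [generate_protein_table()].
#' @param truth Matching truth list (needs `de_labels`).
#' @return A list with `terms` (tibble as from [read_gmt()]) and `truth`
#'   (list with `enriched_term_ids`).
#' @export
generate_annotation_sets <- function(config, proteins, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  with_stage_seed(config$seed, 3L, {
    symbols <- proteins$gene_symbol
    up_pool <- truth$de_labels$gene_symbol[
      truth$de_labels$contrast == config$planted_term_contrast &
        truth$de_labels$direction == "UP"
    ]
    planted <- config$planted_term_ids
    if (length(planted) > 0 && config$planted_term_up_members > length(up_pool)) {
      abort(paste0(
        "synthetic_config: planted term needs ", config$planted_term_up_members,
        " planted-UP members but only ", length(up_pool), " are available"
      ))
    }
    planted_terms <- purrr::map_dfr(planted, function(id) {
      up_members <- sample(up_pool, config$planted_term_up_members)
      rest <- sample(
        setdiff(symbols, up_members),
        config$planted_term_size - config$planted_term_up_members
      )
      tibble(
        term_id = id,
        name = paste0("planted enriched set ", id),
        category = "GO_BP",
        members = list(c(up_members, rest))
      )
    })
    n_rand <- config$n_terms - length(planted)
    rand_terms <- purrr::map_dfr(seq_len(max(n_rand, 0)), function(i) {
      sizes <- seq(config$term_size_range[1], config$term_size_range[2])
      size <- sizes[sample.int(length(sizes), 1)]
      tibble(
        term_id = sprintf("RAND_SET_%03d", i),
        name = sprintf("random background set %03d", i),
        category = "GO_BP",
        members = list(sample(symbols, min(size, length(symbols))))
      )
    })
    list(
      terms = dplyr::bind_rows(planted_terms, rand_terms),
      truth = list(enriched_term_ids = planted)
    )
  })
}

#' Generate a synthetic phosphopeptide table with planted effects and decoys
#'
#' Each peptide carries a confidence score, a parent protein, phospho /
#' mis-allocation flags, a fold-change per contrast and `n_replicates`
#' normalized measurements per pooled condition (log-normal replicate
#' noise). Planted effects shift the numerator condition's mean in log space
#' by a factor drawn from the configured ratio ranges, so the per-contrast
#' two-sample t-test detects them. A `decoy_frac` share of rows are decoys
#' the filter must remove, split between non-phospho, mis-allocated and very
#' low confidence (< 10) peptides.
#'
#' @param config A [synthetic_config()].
#' @param proteins Protein tibble supplying parent symbols (optional; a
#'   synthetic symbol pool is used when omitted).
#' @return A list with `peptides` (tibble in [read_phospho_table()] layout)
#'   and `truth` (list; `phospho_effects` maps peptide x contrast to
#'   direction).
#' @export
generate_phospho_table <- function(config, proteins = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_stage_seed(config$seed, 4L, {
    n <- config$n_phosphopeptides
    n_decoy <- round(config$decoy_frac * n)
    parents <- if (is.null(proteins)) {
      syn_symbol(seq_len(max(n, 1)))
    } else {
      proteins$gene_symbol
    }
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
            "Q", "R", "S", "T", "V", "W", "Y")
    tbl <- tibble(
      peptide_id = sprintf("PEP%04d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste0(
          paste(sample(aa, 10, replace = TRUE), collapse = ""),
          "[pS", sample.int(10, 1), "]"
        )
      }, character(1)),
      parent_symbol = sample(parents, n, replace = n > length(parents)),
      confidence = round(runif(n, 10, 100), 1),
      is_phospho = TRUE,
      is_misallocated = FALSE
    )
    if (n_decoy > 0) {
      decoy_idx <- utils::tail(seq_len(n), n_decoy)
      kind <- rep_len(c("non_phospho", "misallocated", "low_confidence"), n_decoy)
      tbl$is_phospho[decoy_idx[kind == "non_phospho"]] <- FALSE
      tbl$is_misallocated[decoy_idx[kind == "misallocated"]] <- TRUE
      tbl$confidence[decoy_idx[kind == "low_confidence"]] <-
        round(runif(sum(kind == "low_confidence"), 0, 9.9), 1)
    } else {
      decoy_idx <- integer(0)
    }
    retained_idx <- setdiff(seq_len(n), decoy_idx)

    # per-contrast planted effect directions among retained peptides
    effects <- list()
    shift <- matrix(0, nrow = n, ncol = 4,
                    dimnames = list(NULL, ret_conditions()))
    base <- rnorm(n, 0, 0.3)
    for (k in seq_along(ret_contrasts())) {
      ct <- ret_contrasts()[k]
      n_up <- round(config$phospho_frac_up * length(retained_idx))
      n_down <- round(config$phospho_frac_down * length(retained_idx))
      idx <- retained_idx[sample.int(length(retained_idx), n_up + n_down)]
      up_idx <- idx[seq_len(n_up)]
      down_idx <- idx[n_up + seq_len(n_down)]
      cc <- contrast_conditions(ct)
      eff <- rep(0, n)
      eff[up_idx] <- log(runif(n_up, config$up_ratio_range[1], config$up_ratio_range[2]))
      eff[down_idx] <- log(runif(n_down, config$down_ratio_range[1], config$down_ratio_range[2]))
      shift[, cc[["num"]]] <- shift[, cc[["num"]]] + eff
      effects[[ct]] <- tibble(
        peptide_id = tbl$peptide_id[c(up_idx, down_idx)],
        contrast = ct,
        direction = rep(c("UP", "DOWN"), c(n_up, n_down))
      )
    }
    # old_post inherits the baseline age shift on top of the old RET effect
    shift[, "old_post"] <- shift[, "old_post"] + shift[, "old_pre"]

    reps <- list()
    for (cond in ret_conditions()) {
      draws <- matrix(
        exp(base + shift[, cond] +
          rnorm(n * config$n_replicates, 0, config$replicate_log_sd)),
        nrow = n
      )
      for (j in seq_len(config$n_replicates)) {
        reps[[paste0(cond, "_rep", j)]] <- round(draws[, j], 5)
      }
    }
    reps <- tibble::as_tibble(reps)
    for (ct in ret_contrasts()) {
      cc <- contrast_conditions(ct)
      num <- as.matrix(reps[, grep(paste0("^", cc[["num"]], "_rep"), names(reps))])
      den <- as.matrix(reps[, grep(paste0("^", cc[["den"]], "_rep"), names(reps))])
      tbl[[paste0("ratio_", ct)]] <- round(exp(rowMeans(log(num)) - rowMeans(log(den))), 5)
    }
    list(
      peptides = dplyr::bind_cols(tbl, reps),
      truth = list(phospho_effects = dplyr::bind_rows(effects))
    )
  })
}

#' Generate and write a complete fixture bundle
#'
#' Runs all four generators under the config's seed and writes six files to
#' `dir`: `proteins.tsv`, `annotations.gmt`, `ppi_edges.tsv`, `phospho.tsv`,
#' `truth.json` and `config.json`. Re-reading the bundle with
#' [read_fixture_bundle()] reproduces the in-memory objects; identical
#' config (including seed) gives byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects, the combined
#'   `truth` and the file `paths`.
#' @export
write_fixture_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create fixture directory: ", dir))
  }
  prot <- generate_protein_table(config)
  net <- generate_ppi_network(config)
  anno <- generate_annotation_sets(config, prot$proteins, prot$truth)
  phos <- generate_phospho_table(config, prot$proteins)

  truth <- list(
    de_labels = prot$truth$de_labels,
    hub_ids = net$truth$hub_ids,
    enriched_term_ids = anno$truth$enriched_term_ids,
    phospho_effects = phos$truth$phospho_effects
  )

  paths <- list(
    proteins = file.path(dir, "proteins.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    edges = file.path(dir, "ppi_edges.tsv"),
    phospho = file.path(dir, "phospho.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json")
  )
  readr::write_tsv(prot$proteins, paths$proteins, progress = FALSE)
  write_gmt(anno$terms, paths$gmt)
  readr::write_tsv(net$edges, paths$edges, progress = FALSE)
  readr::write_tsv(phos$peptides, paths$phospho, progress = FALSE)
  jsonlite::write_json(truth, paths$truth,
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(unclass(config), paths$config,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    proteins = prot$proteins, terms = anno$terms, network = net$network,
    edges = net$edges, peptides = phos$peptides, truth = truth, paths = paths
  ))
}

#' Read a fixture bundle back from disk
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return A list with `proteins`, `terms`, `network`, `peptides`, `truth`
#'   and `config`.
#' @export
read_fixture_bundle <- function(dir) {
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- list(
    de_labels = tibble::as_tibble(truth_raw$de_labels),
    hub_ids = as.character(truth_raw$hub_ids %||% character(0)),
    enriched_term_ids = as.character(truth_raw$enriched_term_ids %||% character(0)),
    phospho_effects = tibble::as_tibble(truth_raw$phospho_effects)
  )
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(synthetic_config, cfg_raw[names(cfg_raw) %in% names(formals(synthetic_config))])
  list(
    proteins = read_protein_table(file.path(dir, "proteins.tsv")),
    terms = read_gmt(file.path(dir, "annotations.gmt")),
    network = read_edge_list(file.path(dir, "ppi_edges.tsv")),
    peptides = read_phospho_table(file.path(dir, "phospho.tsv")),
    truth = truth,
    config = config
  )
}
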