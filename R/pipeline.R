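#' Pipeline configuration
#'
#' Validates input paths and analysis settings for [run_pipeline()]. All
#' thresholds default to the screening conventions of the pooled 4-plex
#' design: fold-change cut-offs 1.2 / 0.8, P tiers 0.05 / 0.1, minimum 2
#' peptides, enrichment FDR < 1%, top 5 hubs.
#'
#' @param protein_table Path to the quantified-protein TSV/CSV.
#' @param gmt Character vector of GMT file paths (one per category
#'   collection).
#' @param edge_list Path to the interactome edge list (TSV or SIF).
#' @param phospho_table Optional path to the phosphopeptide TSV.
#' @param accession_map Optional accession-to-symbol TSV.
#' @param out_dir Output directory for stage files.
#' @param thresholds A [screening_thresholds()] object.
#' @param universe `"annotation"` (default; union of GMT members) or
#'   `"detected"` (the filtered protein table's symbols) as the enrichment
#'   background.
#' @param fdr_threshold Enrichment significance cut-off on q. Default 0.01.
#' @param k_hubs Hubs per network. Default 5.
#' @param reversal_mode `"strict"` or `"lenient"`, see [classify_reversal()].
#' @param seed Integer seed recorded in the provenance block and applied at
#'   the start of the run.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(protein_table, gmt, edge_list,
                            phospho_table = NULL, accession_map = NULL,
                            out_dir = "retproteome-out",
                            thresholds = screening_thresholds(),
                            universe = c("annotation", "detected"),
                            fdr_threshold = 0.01,
                            k_hubs = 5,
                            reversal_mode = c("strict", "lenient"),
                            seed = 1L) {
  universe <- match.arg(universe)
  reversal_mode <- match.arg(reversal_mode)
  stopifnot(inherits(thresholds, "screening_thresholds"))
  for (p in c(protein_table, gmt, edge_list, phospho_table, accession_map)) {
    if (!file.exists(p)) abort(paste0("pipeline_config: input file not found: ", p))
  }
  structure(
    list(
      protein_table = protein_table, gmt = gmt, edge_list = edge_list,
      phospho_table = phospho_table, accession_map = accession_map,
      out_dir = out_dir, thresholds = thresholds, universe = universe,
      fdr_threshold = fdr_threshold, k_hubs = k_hubs,
      reversal_mode = reversal_mode, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the order of the underlying analysis: screening of
#' the protein table into per-contrast regulation calls; per-contrast
#' over-representation analysis of the UP and DOWN lists; RET-response
#' concordance between ages and RET reversal of baseline age dysregulation;
#' per-category minimum interaction networks and hub rankings for the
#' reversal categories; and phosphopeptide filtering, normalization and
#' testing. All stage outputs are written as plain files (TSV / JSON /
#' GraphML) under `config$out_dir` so any stage can be re-run or audited in
#' isolation, plus a provenance block sufficient to reproduce the run. The
#' run is deterministic given the config and seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `ret_report`: list with the screen, enrichment
#'   tables, concordance/reversal tables, per-category networks and hub
#'   tables, phospho results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  rp_inform("stage screening: reading and filtering protein table")
  proteins <- read_protein_table(config$protein_table, accession_map = config$accession_map)
  filt <- apply_exclusion_filters(proteins, config$thresholds)
  screen <- screen_contrasts(filt$retained, config$thresholds)
  write_calls_tsv(screen, file.path(out, "calls.tsv"))
  jsonlite::write_json(
    list(
      n_input = nrow(proteins),
      n_retained = screen$n_proteins,
      n_differential = screen$n_differential,
      exclusions = filt$report,
      summary = screen$summary
    ),
    file.path(out, "screen_summary.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  rp_inform("stage enrichment: over-representation of per-contrast lists")
  terms <- dplyr::bind_rows(lapply(config$gmt, read_gmt))
  uni <- if (config$universe == "detected") filt$retained$gene_symbol else NULL
  enrichments <- list()
  for (ct in ret_contrasts()) {
    for (dir in c("UP", "DOWN")) {
      syms <- differential_symbols(screen, ct, dir)
      key <- paste0(ct, "_", tolower(dir))
      enrichments[[key]] <- if (length(syms) > 0) {
        enrich_list(syms, terms, universe = uni, fdr_threshold = config$fdr_threshold)
      } else {
        enrich_list(character(0), terms[0, ], universe = uni %||% "NONE")
      }
    }
  }
  enr_all <- dplyr::bind_rows(enrichments, .id = "protein_list")
  readr::write_tsv(enr_all, file.path(out, "enrichment.tsv"), progress = FALSE)

  rp_inform("stage comparison: concordance and reversal classification")
  concordance <- compare_ret_profiles(screen$calls)
  reversal <- classify_reversal(screen$calls, mode = config$reversal_mode)
  readr::write_tsv(concordance, file.path(out, "concordance.tsv"), progress = FALSE)
  readr::write_tsv(reversal, file.path(out, "reversal.tsv"), progress = FALSE)

  seed_lists <- c(
    category_symbol_lists(reversal),
    category_symbol_lists(concordance)
  )
  for (nm in names(seed_lists)) {
    readr::write_lines(seed_lists[[nm]], file.path(out, paste0("seeds_", nm, ".txt")))
  }

  rp_inform("stage network: minimum interaction networks and hub ranking")
  interactome <- read_edge_list(config$edge_list)
  networks <- list()
  hub_tables <- list()
  for (nm in names(seed_lists)) {
    fo <- first_order_subnetwork(interactome, seed_lists[[nm]])
    if (igraph::vcount(fo$graph) == 0) next
    mn <- minimum_interaction_network(fo)
    if (igraph::vcount(mn$graph) == 0) next
    hubs <- rank_hubs(mn, k = config$k_hubs)
    networks[[nm]] <- mn
    hub_tables[[nm]] <- hubs
    export_network(mn, file.path(out, paste0("network_", nm, ".graphml")),
      format = "graphml", hubs = hubs
    )
  }
  if (length(hub_tables) > 0) {
    hub_all <- dplyr::bind_rows(hub_tables, .id = "seed_list")
    readr::write_tsv(hub_all, file.path(out, "hubs.tsv"), progress = FALSE)
  } else {
    hub_all <- tibble()
  }

  phospho <- NULL
  if (!is.null(config$phospho_table)) {
    rp_inform("stage phospho: filtering, normalization and t-tests")
    peptides <- read_phospho_table(config$phospho_table)
    pf <- filter_phosphopeptides(peptides)
    phospho <- analyze_phospho(pf$retained, proteins = filt$retained,
      thresholds = config$thresholds)
    readr::write_tsv(phospho, file.path(out, "phospho_results.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(exclusions = pf$report, summary = glance(phospho)),
      file.path(out, "phospho_summary.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  cfg_json <- file.path(out, "pipeline_config.json")
  jsonlite::write_json(
    serializable_config(config), cfg_json,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  provenance <- list(
    package = "retproteome",
    version = as.character(utils::packageVersion("retproteome")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_json))
  )
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  structure(
    list(
      screen = screen, exclusions = filt$report, enrichments = enrichments,
      concordance = concordance, reversal = reversal,
      seed_lists = seed_lists, networks = networks, hubs = hub_tables,
      phospho = phospho, provenance = provenance, out_dir = out
    ),
    class = "ret_report"
  )
}

## provenance copy of the config; out_dir is where the run lands, not part of
## what was computed, so it is omitted to keep runs byte-comparable
serializable_config <- function(config) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x$out_dir <- NULL
  x
}

#' @export
print.ret_report <- function(x, ...) {
  cat("<ret_report> written to ", x$out_dir, "\n", sep = "")
  print(x$screen)
  cat(
    "networks built for ", length(x$networks), " seed list(s); phospho ",
    if (is.null(x$phospho)) "skipped" else "analysed", "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `ret_report`.
#' @param ... Unused.
#' @method glance ret_report
#' @export
glance.ret_report <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$screen),
    tibble(
      n_enriched_terms = sum(vapply(
        x$enrichments, function(e) sum(e$significant), numeric(1)
      )),
      n_networks = length(x$networks),
      n_phospho_altered = if (is.null(x$phospho)) {
        NA_integer_
      } else {
        glance(x$phospho)$n_altered_any_contrast
      }
    )
  )
}
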