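#' Screening thresholds for differential-regulation calls
#'
#' Bundles the fold-change cut-offs, significance tiers and exclusion rules
#' used to screen an iTRAQ quantified-protein table. Defaults follow common
#' practice for pooled isobaric-label designs: a protein is called
#' up-regulated when its linear fold-change exceeds 1.2 and down-regulated
#' below 0.8 (strict inequalities; boundary values are UNCHANGED), with
#' P < 0.05 marking statistical significance and 0.05 <= P <= 0.1 a trend.
#' Suspected contaminants (haemoglobin, keratin) and proteins identified by
#' fewer than 2 peptides are excluded before screening.
#'
#' @param up_cutoff Linear ratio above which a protein is called UP. Default 1.2.
#' @param down_cutoff Linear ratio below which a protein is called DOWN.
#'   Default 0.8. Must satisfy `down_cutoff < 1 < up_cutoff`.
#' @param sig_p P-value below which a call is tier SIGNIFICANT. Default 0.05.
#' @param trend_p P-value at or below which (and at or above `sig_p`) a call
#'   is tier TREND. Default 0.1. Must exceed `sig_p`.
#' @param min_peptides Minimum number of identifying peptides required to
#'   retain a protein. Default 2.
#' @param contaminant_prefixes Gene-symbol prefixes flagged as contaminants.
#'   Default `c("HB", "KRT")` (haemoglobins and keratins).
#' @param require_significance If `TRUE`, downstream "differential" status
#'   additionally requires tier SIGNIFICANT or TREND; by default the
#'   fold-change criterion alone defines differential regulation and the
#'   P-based tier only annotates.
#'
#' @return A list of class `screening_thresholds`.
#' @export
#' @examples
#' screening_thresholds()
screening_thresholds <- function(up_cutoff = 1.2,
                                 down_cutoff = 0.8,
                                 sig_p = 0.05,
                                 trend_p = 0.1,
                                 min_peptides = 2,
                                 contaminant_prefixes = c("HB", "KRT"),
                                 require_significance = FALSE) {
  if (!(down_cutoff < 1 && 1 < up_cutoff)) {
    abort("screening_thresholds: need down_cutoff < 1 < up_cutoff")
  }
  if (!(sig_p < trend_p)) {
    abort("screening_thresholds: need sig_p < trend_p")
  }
  if (min_peptides < 1) abort("screening_thresholds: min_peptides must be >= 1")
  structure(
    list(
      up_cutoff = up_cutoff, down_cutoff = down_cutoff,
      sig_p = sig_p, trend_p = trend_p,
      min_peptides = min_peptides,
      contaminant_prefixes = toupper(contaminant_prefixes),
      require_significance = isTRUE(require_significance)
    ),
    class = "screening_thresholds"
  )
}

## canonical column names of a protein table
protein_table_columns <- function() {
  c(
    "accession", "gene_symbol", "n_peptides", "coverage_pct", "is_reverse_hit",
    paste0("ratio_", ret_contrasts()), paste0("p_", ret_contrasts())
  )
}

#' Read a quantified-protein table
#'
#' Loads a TSV or CSV table of iTRAQ protein quantifications into the
#' canonical tibble layout: one row per protein with identifier columns
#' (`accession`, `gene_symbol`, `n_peptides`, `coverage_pct`,
#' `is_reverse_hit`) and, for each of the three contrasts
#' (see [ret_contrasts()]), a linear fold-change column `ratio_<contrast>`
#' and a P-value column `p_<contrast>`. Header matching is case-insensitive;
#' row order is preserved. An optional two-column accession-to-symbol map
#' fills in missing gene symbols.
#'
#' @param path Path to the table.
#' @param format One of `"auto"` (default, by file extension), `"tsv"` or
#'   `"csv"`.
#' @param accession_map Optional path to a two-column TSV
#'   (accession, gene_symbol) used to fill missing symbols.
#'
#' @return A tibble of validated protein records.
#' @export
read_protein_table <- function(path, format = c("auto", "tsv", "csv"),
                               accession_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("protein table not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (format == "auto") {
    if (ext %in% c("xlsx", "xls")) {
      abort("XLSX protein tables are not supported; export the sheet as TSV or CSV")
    }
    format <- if (ext == "csv") "csv" else "tsv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  names(raw) <- tolower(names(raw))

  need <- c(
    "accession", "gene_symbol", "n_peptides",
    paste0("ratio_", ret_contrasts()), paste0("p_", ret_contrasts())
  )
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "protein table is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!"coverage_pct" %in% names(raw)) raw$coverage_pct <- NA_real_
  if (!"is_reverse_hit" %in% names(raw)) raw$is_reverse_hit <- FALSE

  tbl <- tibble::as_tibble(raw[, protein_table_columns()])
  tbl$gene_symbol <- toupper(tbl$gene_symbol)
  tbl$is_reverse_hit <- as.logical(tbl$is_reverse_hit)

  if (!is.null(accession_map)) {
    map <- readr::read_tsv(accession_map, show_col_types = FALSE, progress = FALSE)
    names(map) <- tolower(names(map))
    idx <- match(tbl$accession, map$accession)
    fill <- !is.na(idx) & (is.na(tbl$gene_symbol) | tbl$gene_symbol == "")
    tbl$gene_symbol[fill] <- toupper(map$gene_symbol[idx[fill]])
  }

  validate_protein_table(tbl)
  tbl
}

validate_protein_table <- function(tbl) {
  for (ct in ret_contrasts()) {
    r <- tbl[[paste0("ratio_", ct)]]
    p <- tbl[[paste0("p_", ct)]]
    bad_r <- which(!is.finite(r) | r <= 0)
    if (length(bad_r) > 0) {
      abort(paste0(
        "non-positive or missing ratio for contrast ", ct,
        " at row(s): ", paste(head(bad_r, 5), collapse = ", ")
      ))
    }
    bad_p <- which(!is.finite(p) | p < 0 | p > 1)
    if (length(bad_p) > 0) {
      abort(paste0(
        "P-value outside [0, 1] for contrast ", ct,
        " at row(s): ", paste(head(bad_p, 5), collapse = ", ")
      ))
    }
  }
  bad_n <- which(!is.finite(tbl$n_peptides) | tbl$n_peptides < 1)
  if (length(bad_n) > 0) {
    abort(paste0("n_peptides < 1 at row(s): ", paste(head(bad_n, 5), collapse = ", ")))
  }
  invisible(tbl)
}

#' Exclude reverse hits, contaminants and low-evidence proteins
#'
#' Removes reverse-library hits, proteins whose gene symbol starts with a
#' contaminant prefix (haemoglobins and keratins by default), and proteins
#' identified by fewer than `min_peptides` peptides. Each record is counted
#' under one exclusion reason, checked in that order. The operation is
#' idempotent.
#'
#' @param proteins Protein tibble, as from [read_protein_table()].
#' @param thresholds A [screening_thresholds()] object.
#'
#' @return A list with `retained` (tibble of kept records, row order
#'   preserved), `exclusions` (tibble of dropped records with a `reason`
#'   column) and `report` (tibble of counts per reason).
#' @export
apply_exclusion_filters <- function(proteins, thresholds = screening_thresholds()) {
  stopifnot(inherits(thresholds, "screening_thresholds"))
  pref <- thresholds$contaminant_prefixes
  is_contam <- function(sym) {
    if (length(pref) == 0) return(rep(FALSE, length(sym)))
    Reduce(`|`, lapply(pref, function(p) startsWith(sym, p)))
  }
  reason <- rep(NA_character_, nrow(proteins))
  reason[is.na(reason) & proteins$is_reverse_hit] <- "reverse_hit"
  reason[is.na(reason) & is_contam(proteins$gene_symbol)] <- "contaminant"
  reason[is.na(reason) & proteins$n_peptides < thresholds$min_peptides] <- "min_peptides"

  excl <- proteins[!is.na(reason), , drop = FALSE]
  excl$reason <- reason[!is.na(reason)]
  report <- tibble(
    reason = c("reverse_hit", "contaminant", "min_peptides"),
    n_excluded = c(
      sum(reason == "reverse_hit", na.rm = TRUE),
      sum(reason == "contaminant", na.rm = TRUE),
      sum(reason == "min_peptides", na.rm = TRUE)
    )
  )
  list(
    retained = proteins[is.na(reason), , drop = FALSE],
    exclusions = tibble::as_tibble(excl),
    report = report
  )
}

#' Call direction and significance tier for one ratio/P pair
#'
#' Applies the fold-change-first screening rule: direction is UP when the
#' linear ratio strictly exceeds `up_cutoff`, DOWN when strictly below
#' `down_cutoff`, otherwise UNCHANGED. The P-value annotates a tier:
#' SIGNIFICANT (`p < sig_p`), TREND (`sig_p <= p <= trend_p`) or FC_ONLY;
#' UNCHANGED proteins always get tier NONE.
#'
#' @param ratio Numeric vector of positive linear fold-changes.
#' @param p_value Numeric vector of P-values in \[0, 1\].
#' @param thresholds A [screening_thresholds()] object.
#'
#' @return A tibble with character columns `direction` and `tier`, one row
#'   per input element.
#' @export
#' @examples
#' call_regulation(c(1.35, 0.80, 0.75), c(0.02, 0.01, 0.08))
call_regulation <- function(ratio, p_value, thresholds = screening_thresholds()) {
  stopifnot(inherits(thresholds, "screening_thresholds"))
  if (any(!is.finite(ratio) | ratio <= 0)) abort("call_regulation: ratios must be positive")
  if (any(!is.finite(p_value) | p_value < 0 | p_value > 1)) {
    abort("call_regulation: P-values must lie in [0, 1]")
  }
  direction <- ifelse(ratio > thresholds$up_cutoff, "UP",
    ifelse(ratio < thresholds$down_cutoff, "DOWN", "UNCHANGED")
  )
  tier <- ifelse(p_value < thresholds$sig_p, "SIGNIFICANT",
    ifelse(p_value <= thresholds$trend_p, "TREND", "FC_ONLY")
  )
  tier[direction == "UNCHANGED"] <- "NONE"
  tibble(direction = direction, tier = tier)
}

#' Screen all contrasts of a protein table into regulation calls
#'
#' Applies [call_regulation()] to every protein for each of the three
#' contrasts and tallies per-contrast UP/DOWN counts plus the number of
#' proteins differential in at least one contrast. A protein is
#' "differential" when its fold-change crosses a cut-off; with
#' `require_significance = TRUE` in the thresholds, the call must
#' additionally be tier SIGNIFICANT or TREND.
#'
#' @param proteins Filtered protein tibble (see [apply_exclusion_filters()]).
#' @param thresholds A [screening_thresholds()] object.
#'
#' @return An object of class `protein_screen`: list with `calls` (long
#'   tibble: accession, gene_symbol, contrast, ratio, p_value, direction,
#'   tier, differential), `summary` (per-contrast counts), `n_differential`,
#'   `n_proteins` and the thresholds used. Use [tidy()] for the call table
#'   and [glance()] for the one-row summary.
#' @export
screen_contrasts <- function(proteins, thresholds = screening_thresholds()) {
  stopifnot(inherits(thresholds, "screening_thresholds"))
  validate_protein_table(proteins)

  calls <- purrr::map_dfr(ret_contrasts(), function(ct) {
    r <- proteins[[paste0("ratio_", ct)]]
    p <- proteins[[paste0("p_", ct)]]
    cl <- call_regulation(r, p, thresholds)
    tibble(
      accession = proteins$accession,
      gene_symbol = proteins$gene_symbol,
      contrast = ct,
      ratio = r,
      p_value = p,
      direction = cl$direction,
      tier = cl$tier
    )
  })
  calls$differential <- calls$direction != "UNCHANGED" &
    (!thresholds$require_significance | calls$tier %in% c("SIGNIFICANT", "TREND"))

  summary <- calls |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(
      n_up = sum(.data$direction == "UP" & .data$differential),
      n_down = sum(.data$direction == "DOWN" & .data$differential),
      n_unchanged = dplyr::n() - .data$n_up - .data$n_down,
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$contrast, ret_contrasts()))

  n_diff <- calls |>
    dplyr::filter(.data$differential) |>
    dplyr::distinct(.data$accession) |>
    nrow()

  structure(
    list(
      calls = calls, summary = summary,
      n_differential = n_diff, n_proteins = nrow(proteins),
      thresholds = thresholds
    ),
    class = "protein_screen"
  )
}

#' @export
print.protein_screen <- function(x, ...) {
  cat("<protein_screen> ", x$n_proteins, " proteins, ",
    x$n_differential, " differential in >=1 contrast\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' @rdname screen_contrasts
#' @param x A `protein_screen` object.
#' @param ... Unused.
#' @method tidy protein_screen
#' @export
tidy.protein_screen <- function(x, ...) x$calls

#' @rdname screen_contrasts
#' @method glance protein_screen
#' @export
glance.protein_screen <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_wider(
      names_from = "contrast",
      values_from = c("n_up", "n_down", "n_unchanged")
    )
  dplyr::bind_cols(
    tibble(n_proteins = x$n_proteins, n_differential = x$n_differential),
    wide
  )
}

#' Extract differential gene symbols from a screen
#'
#' Returns the gene symbols called differential for a given contrast and
#' direction -- the seed lists that feed enrichment and network analysis.
#'
#' @param screen A `protein_screen` object.
#' @param contrast One of [ret_contrasts()].
#' @param direction `"UP"`, `"DOWN"` or `"ANY"`.
#'
#' @return Character vector of unique gene symbols, lexicographically sorted.
#' @export
differential_symbols <- function(screen, contrast, direction = c("ANY", "UP", "DOWN")) {
  stopifnot(inherits(screen, "protein_screen"))
  direction <- match.arg(direction)
  contrast <- match.arg(contrast, ret_contrasts())
  sel <- screen$calls$contrast == contrast & screen$calls$differential
  if (direction != "ANY") sel <- sel & screen$calls$direction == direction
  syms <- unique(screen$calls$gene_symbol[sel])
  syms[lex_order(syms)]
}

#' Write the per-protein call table as wide TSV
#'
#' One row per protein with a `direction_<contrast>` and `tier_<contrast>`
#' column pair for each of the three contrasts.
#'
#' @param screen A `protein_screen` object.
#' @param path Output TSV path.
#' @return The wide tibble, invisibly.
#' @export
write_calls_tsv <- function(screen, path) {
  stopifnot(inherits(screen, "protein_screen"))
  wide <- screen$calls |>
    dplyr::select(
      "accession", "gene_symbol", "contrast",
      "ratio", "p_value", "direction", "tier"
    ) |>
    tidyr::pivot_wider(
      names_from = "contrast",
      values_from = c("ratio", "p_value", "direction", "tier")
    )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(wide)
}
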