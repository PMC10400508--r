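#' Read a phosphopeptide table
#'
#' Loads a TSV with one row per phosphopeptide: `peptide_id`, `sequence`
#' (with site annotation), `parent_symbol`, `confidence` (0-100 score),
#' `is_phospho`, `is_misallocated`, a `ratio_<contrast>` column per contrast
#' and replicate measurement columns `<condition>_rep<i>` for the four
#' pooled conditions (`young_pre`, `young_post`, `old_pre`, `old_post`).
#'
#' @param path Path to the TSV.
#' @return A tibble of validated phosphopeptide records.
#' @export
read_phospho_table <- function(path) {
  if (!file.exists(path)) abort(paste0("phosphopeptide table not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  need <- c("peptide_id", "parent_symbol", "confidence", "is_phospho", "is_misallocated")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(
      "phosphopeptide table missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(tbl$confidence < 0 | tbl$confidence > 100)) {
    abort("phosphopeptide confidence scores must lie in [0, 100]")
  }
  tbl$is_phospho <- as.logical(tbl$is_phospho)
  tbl$is_misallocated <- as.logical(tbl$is_misallocated)
  tibble::as_tibble(tbl)
}

#' Filter phosphopeptides before analysis
#'
#' Removes non-phosphorylated peptides, mis-allocated peptides and very low
#' confidence peptides (confidence strictly below `min_confidence`; a score
#' exactly at the threshold is retained). Each record is counted under one
#' removal reason, checked in that order. Idempotent.
#'
#' @param peptides Phosphopeptide tibble (see [read_phospho_table()]).
#' @param min_confidence Confidence cut-off, default 10.
#'
#' @return A list with `retained`, `exclusions` (records + `reason`) and
#'   `report` (counts per reason).
#' @export
filter_phosphopeptides <- function(peptides, min_confidence = 10) {
  reason <- rep(NA_character_, nrow(peptides))
  reason[is.na(reason) & !peptides$is_phospho] <- "non_phospho"
  reason[is.na(reason) & peptides$is_misallocated] <- "misallocated"
  reason[is.na(reason) & peptides$confidence < min_confidence] <- "low_confidence"
  excl <- peptides[!is.na(reason), , drop = FALSE]
  excl$reason <- reason[!is.na(reason)]
  list(
    retained = peptides[is.na(reason), , drop = FALSE],
    exclusions = tibble::as_tibble(excl),
    report = tibble(
      reason = c("non_phospho", "misallocated", "low_confidence"),
      n_excluded = c(
        sum(reason == "non_phospho", na.rm = TRUE),
        sum(reason == "misallocated", na.rm = TRUE),
        sum(reason == "low_confidence", na.rm = TRUE)
      )
    )
  )
}

#' Normalize a phosphopeptide ratio to its parent protein
#'
#' Isolates the phosphorylation change from the protein-level change by
#' dividing the phosphopeptide fold-change by the parent protein's
#' fold-change for the same contrast (ratio of ratios on the linear scale).
#'
#' @param phospho_ratio Positive phosphopeptide fold-change(s).
#' @param protein_ratio Positive parent-protein fold-change(s).
#' @return `phospho_ratio / protein_ratio`.
#' @export
#' @examples
#' normalize_to_protein(2.4, 1.2)
normalize_to_protein <- function(phospho_ratio, protein_ratio) {
  if (any(!is.finite(phospho_ratio) | phospho_ratio <= 0)) {
    abort("normalize_to_protein: phospho_ratio must be positive")
  }
  if (any(!is.finite(protein_ratio) | protein_ratio <= 0)) {
    abort("normalize_to_protein: protein_ratio must be positive")
  }
  phospho_ratio / protein_ratio
}

#' Two-sample Student's t-test for phosphopeptide replicates
#'
#' Pooled-variance two-sample t-test (Welch's correction selectable) of
#' replicate-level normalized measurements, with significance accepted at
#' P <= 0.05 inclusive. Degenerate inputs are handled explicitly: groups
#' with identical values and equal means give t = 0, P = 1; zero pooled
#' variance with unequal means reports P = 0 with a warning.
#'
#' @param values_a,values_b Numeric replicate vectors, each of length >= 2.
#'   `values_a` is the numerator condition of the contrast, so a positive t
#'   corresponds to up-regulation.
#' @param var_equal Use the pooled-variance Student form (default `TRUE`);
#'   `FALSE` gives Welch's test.
#' @param sig_p Significance threshold (inclusive), default 0.05.
#'
#' @return One-row tibble: `t`, `df`, `p`, `significant`.
#' @export
#' @examples
#' phospho_ttest(c(1, 2, 3), c(4, 5, 6))
phospho_ttest <- function(values_a, values_b, var_equal = TRUE, sig_p = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("phospho_ttest: each group needs at least 2 replicate values")
  }
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b)) {
      t <- 0
      df <- length(values_a) + length(values_b) - 2
      p <- 1
    } else {
      rp_warn("phospho_ttest: zero variance in both groups with unequal means; P reported as 0")
      t <- sign(mean(values_a) - mean(values_b)) * Inf
      df <- length(values_a) + length(values_b) - 2
      p <- 0
    }
  } else {
    fit <- stats::t.test(values_a, values_b, var.equal = var_equal)
    t <- unname(fit$statistic)
    df <- unname(fit$parameter)
    p <- fit$p.value
  }
  tibble(t = t, df = df, p = p, significant = p <= sig_p)
}

#' Per-contrast phosphopeptide analysis
#'
#' For each retained phosphopeptide and each contrast, runs the two-sample
#' t-test between the replicate measurements of the contrast's numerator and
#' denominator conditions, normalizes the phosphopeptide fold-change to the
#' parent protein's fold-change when a protein table is supplied, and calls
#' direction at the screening fold-change cut-offs.
#'
#' @param peptides Filtered phosphopeptide tibble with replicate columns
#'   `<condition>_rep<i>`.
#' @param proteins Optional protein tibble used for parent-protein
#'   normalization (peptides whose parent is absent keep their raw ratio).
#' @param thresholds [screening_thresholds()] supplying the fold-change
#'   cut-offs; phospho significance is fixed at P <= 0.05 (inclusive).
#' @param var_equal Passed to [phospho_ttest()].
#'
#' @return A tibble of class `phospho_result`: one row per peptide per
#'   contrast with `raw_ratio`, `protein_ratio`, `norm_ratio`, `t`, `df`,
#'   `p`, `significant`, `direction`.
#' @export
analyze_phospho <- function(peptides, proteins = NULL,
                            thresholds = screening_thresholds(),
                            var_equal = TRUE) {
  res <- purrr::map_dfr(ret_contrasts(), function(ct) {
    cc <- contrast_conditions(ct)
    num_cols <- grep(paste0("^", cc[["num"]], "_rep\\d+$"), names(peptides), value = TRUE)
    den_cols <- grep(paste0("^", cc[["den"]], "_rep\\d+$"), names(peptides), value = TRUE)
    if (length(num_cols) < 2 || length(den_cols) < 2) {
      abort(paste0(
        "analyze_phospho: need >=2 replicate columns per condition for contrast ", ct
      ))
    }
    purrr::map_dfr(seq_len(nrow(peptides)), function(i) {
      a <- as.numeric(peptides[i, num_cols])
      b <- as.numeric(peptides[i, den_cols])
      tt <- phospho_ttest(a, b, var_equal = var_equal)
      raw <- peptides[[paste0("ratio_", ct)]][i] %||% exp(mean(log(a)) - mean(log(b)))
      prot_ratio <- NA_real_
      if (!is.null(proteins)) {
        j <- match(peptides$parent_symbol[i], proteins$gene_symbol)
        if (!is.na(j)) prot_ratio <- proteins[[paste0("ratio_", ct)]][j]
      }
      norm <- if (is.na(prot_ratio)) raw else normalize_to_protein(raw, prot_ratio)
      tibble(
        peptide_id = peptides$peptide_id[i],
        parent_symbol = peptides$parent_symbol[i],
        contrast = ct,
        raw_ratio = raw,
        protein_ratio = prot_ratio,
        norm_ratio = norm,
        t = tt$t, df = tt$df, p = tt$p,
        significant = tt$significant
      )
    })
  })
  dir <- call_regulation(res$norm_ratio, pmin(pmax(res$p, 0), 1), thresholds)
  res$direction <- dir$direction
  class(res) <- c("phospho_result", class(res))
  res
}

#' @method glance phospho_result
#' @export
glance.phospho_result <- function(x, ...) {
  altered <- x$significant & x$direction != "UNCHANGED"
  tibble(
    n_peptides = length(unique(x$peptide_id)),
    n_altered_any_contrast = length(unique(x$peptide_id[altered])),
    n_significant_calls = sum(altered)
  )
}
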