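#' Concordance of RET responses between young and old muscle
#'
#' Cross-classifies every protein that is differential in at least one of
#' the two within-age RET contrasts by its (young, old) direction pair:
#' concordant (`UP_BOTH`, `DOWN_BOTH`), age-unique (`UP_YOUNG_ONLY`,
#' `DOWN_YOUNG_ONLY`, `UP_OLD_ONLY`, `DOWN_OLD_ONLY`) or opposite
#' (`OPPOSITE_Y_UP_O_DOWN`, `OPPOSITE_Y_DOWN_O_UP`). Directions alone are
#' compared; significance tiers are ignored. Proteins unchanged in both
#' contrasts are excluded.
#'
#' @param calls Long call tibble from [screen_contrasts()] (via [tidy()]),
#'   containing the `young_post_vs_pre` and `old_post_vs_pre` contrasts.
#'
#' @return A tibble of class `concordance_table`: `gene_symbol`,
#'   `young_call`, `old_call`, `category`. Attribute `counts` holds the
#'   per-category tally (also via [glance()]).
#' @export
compare_ret_profiles <- function(calls) {
  wide <- calls_direction_wide(calls, c("young_post_vs_pre", "old_post_vs_pre"))
  y <- wide$young_post_vs_pre
  o <- wide$old_post_vs_pre
  keep <- y != "UNCHANGED" | o != "UNCHANGED"
  wide <- wide[keep, , drop = FALSE]
  y <- y[keep]
  o <- o[keep]
  category <- dplyr::case_when(
    y == "UP" & o == "UP" ~ "UP_BOTH",
    y == "DOWN" & o == "DOWN" ~ "DOWN_BOTH",
    y == "UP" & o == "UNCHANGED" ~ "UP_YOUNG_ONLY",
    y == "DOWN" & o == "UNCHANGED" ~ "DOWN_YOUNG_ONLY",
    y == "UNCHANGED" & o == "UP" ~ "UP_OLD_ONLY",
    y == "UNCHANGED" & o == "DOWN" ~ "DOWN_OLD_ONLY",
    y == "UP" & o == "DOWN" ~ "OPPOSITE_Y_UP_O_DOWN",
    y == "DOWN" & o == "UP" ~ "OPPOSITE_Y_DOWN_O_UP"
  )
  out <- tibble(
    gene_symbol = wide$gene_symbol,
    young_call = y, old_call = o, category = category
  )
  class(out) <- c("concordance_table", class(out))
  out
}

#' RET reversal of baseline age dysregulation
#'
#' For every protein dysregulated at baseline in old vs. young muscle,
#' classifies whether resistance exercise training in the old group moved it
#' in the opposite direction: `UP_REVERSED` / `UP_NOT_REVERSED` for proteins
#' elevated with age, `DOWN_REVERSED` / `DOWN_NOT_REVERSED` for proteins
#' suppressed with age. Under the default strict mode, "reversed" requires
#' the RET response itself to cross the opposite fold-change cut-off; under
#' `mode = "lenient"` any opposite-side RET ratio (relative to 1) counts.
#' The per-category symbol lists are the seed lists for network analysis.
#'
#' @param calls Long call tibble from [screen_contrasts()] (via [tidy()]),
#'   containing the `old_vs_young_baseline` and `old_post_vs_pre` contrasts.
#' @param mode `"strict"` (default) or `"lenient"`, see above.
#'
#' @return A tibble of class `reversal_table`: `gene_symbol`,
#'   `baseline_call`, `old_ret_call`, `category`.
#' @export
classify_reversal <- function(calls, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  wide <- calls_direction_wide(
    calls, c("old_vs_young_baseline", "old_post_vs_pre"),
    keep_ratio = TRUE
  )
  keep <- wide$old_vs_young_baseline != "UNCHANGED"
  wide <- wide[keep, , drop = FALSE]
  b <- wide$old_vs_young_baseline
  r <- wide$old_post_vs_pre
  if (mode == "lenient") {
    # any opposite-side movement of the RET ratio relative to 1 reverses
    r <- ifelse(wide$ratio_old_post_vs_pre > 1, "UP",
      ifelse(wide$ratio_old_post_vs_pre < 1, "DOWN", "UNCHANGED")
    )
  }
  category <- dplyr::case_when(
    b == "UP" & r == "DOWN" ~ "UP_REVERSED",
    b == "UP" ~ "UP_NOT_REVERSED",
    b == "DOWN" & r == "UP" ~ "DOWN_REVERSED",
    b == "DOWN" ~ "DOWN_NOT_REVERSED"
  )
  out <- tibble(
    gene_symbol = wide$gene_symbol,
    baseline_call = b,
    old_ret_call = wide$old_post_vs_pre,
    category = category
  )
  class(out) <- c("reversal_table", class(out))
  out
}

## pivot the long call table to one row per protein with a direction column
## per requested contrast (gated by the `differential` flag when present)
calls_direction_wide <- function(calls, contrasts, keep_ratio = FALSE) {
  need <- c("gene_symbol", "contrast", "direction")
  if (!all(need %in% names(calls))) {
    abort("expected a long call table with gene_symbol, contrast and direction columns")
  }
  sub <- calls[calls$contrast %in% contrasts, , drop = FALSE]
  missing_ct <- setdiff(contrasts, unique(sub$contrast))
  if (length(missing_ct) > 0) {
    abort(paste0("call table lacks contrast(s): ", paste(missing_ct, collapse = ", ")))
  }
  dir <- sub$direction
  if ("differential" %in% names(sub)) {
    dir[!sub$differential] <- "UNCHANGED"
  }
  sub$direction_eff <- dir
  cols <- c("direction_eff", if (keep_ratio && "ratio" %in% names(sub)) "ratio")
  wide <- sub |>
    dplyr::select(dplyr::all_of(c("gene_symbol", "contrast", cols))) |>
    tidyr::pivot_wider(
      names_from = "contrast", values_from = dplyr::all_of(cols)
    )
  # pivot_wider prefixes names only when >1 value column
  if (length(cols) > 1) {
    for (ct in contrasts) {
      names(wide)[names(wide) == paste0("direction_eff_", ct)] <- ct
    }
  } else {
    # single value column keeps bare contrast names already
  }
  wide
}

#' @method glance concordance_table
#' @export
glance.concordance_table <- function(x, ...) category_counts(x)

#' @method glance reversal_table
#' @export
glance.reversal_table <- function(x, ...) category_counts(x)

category_counts <- function(x) {
  x |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::arrange(.data$category)
}

#' Per-category symbol lists from a concordance or reversal table
#'
#' @param x A `concordance_table` or `reversal_table`.
#' @return Named list of lexicographically sorted symbol vectors, one per
#'   category present.
#' @export
category_symbol_lists <- function(x) {
  split(x$gene_symbol, x$category) |>
    lapply(function(s) unique(s)[lex_order(unique(s))])
}
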