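#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT dialect: field 1 = term id, field 2 =
#' description, fields 3+ = member gene symbols. Duplicate members within a
#' term are dropped, symbols are upper-cased. The collection category
#' (GO_BP, GO_CC, GO_MF, KEGG, REACTOME) is taken from, in order: the
#' `category` argument, a `# category=...` header directive, or a token in
#' the file name (e.g. `*_kegg.gmt`).
#'
#' @param path Path to a GMT file.
#' @param category Optional category label overriding inference.
#'
#' @return A tibble with columns `term_id`, `name`, `category` and a
#'   list-column `members`.
#' @export
read_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)

  directive <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]

  if (is.null(category)) {
    m <- regmatches(directive, regexpr("category\\s*=\\s*[A-Za-z_]+", directive))
    if (length(m) > 0) {
      category <- toupper(sub("category\\s*=\\s*", "", m[[1]]))
    } else {
      category <- infer_gmt_category(basename(path))
    }
  }
  category <- toupper(category)

  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    abort(paste0(
      "GMT parse error: fewer than 3 fields at line ",
      which(lines == body[short[1]])[1]
    ))
  }
  tibble(
    term_id = vapply(fields, `[[`, character(1), 1),
    name = vapply(fields, `[[`, character(1), 2),
    category = category,
    members = lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  )
}

infer_gmt_category <- function(fname) {
  f <- tolower(fname)
  if (grepl("bp", f)) return("GO_BP")
  if (grepl("cc", f)) return("GO_CC")
  if (grepl("mf", f)) return("GO_MF")
  if (grepl("kegg", f)) return("KEGG")
  if (grepl("reactome", f)) return("REACTOME")
  "GO_BP"
}

#' Write a gene-set collection as GMT
#'
#' @param terms Term tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term_id[i], terms$name[i], terms$members[[i]]), collapse = "\t")
  }, character(1))
  lines <- c(paste0("# category=", terms$category[1] %||% "GO_BP"), lines)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail enrichment P-value
#'
#' Probability of observing `x` or more annotated genes in a draw of `n`
#' from a universe of `N` genes of which `K` carry the annotation:
#' `P = sum_{k = x..min(n, K)} C(K, k) C(N - K, n - k) / C(N, n)`,
#' the one-sided over-representation test (equivalent to one-sided Fisher).
#' Computed via the log-space hypergeometric distribution function for
#' numerical stability. All arguments are vectorized.
#'
#' @param x Overlap count between the input list and the gene set.
#' @param n Input-list size.
#' @param K Gene-set size within the universe.
#' @param N Universe size.
#'
#' @return Numeric vector of upper-tail probabilities in (0, 1\].
#' @export
#' @examples
#' hypergeom_pvalue(3, 3, 4, 10) # C(4,3)/C(10,3) = 1/30
hypergeom_pvalue <- function(x, n, K, N) {
  bad <- x < 0 | x > pmin(n, K) | K > N | n > N | n < 0 | K < 0
  if (any(bad)) abort("hypergeom_pvalue: inconsistent counts (need 0 <= x <= min(n, K), K <= N, n <= N)")
  exp(phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Standard BH false-discovery-rate adjustment, aligned to the input order.
#'
#' @param p_values Numeric vector of P-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("bh_adjust: P-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a symbol list
#'
#' Tests an input gene-symbol list against every term of a GMT collection
#' with the one-sided hypergeometric test, adjusting within each category
#' collection (GO BP/CC/MF, KEGG, Reactome) separately by Benjamini-Hochberg.
#' Terms are significant at `q < fdr_threshold` (FDR < 1% by default).
#' Term membership and the test are evaluated within the universe: member
#' symbols outside the universe are ignored, and input symbols outside the
#' universe are dropped with a warning.
#'
#' @param symbols Character vector of query gene symbols.
#' @param terms Term tibble from [read_gmt()].
#' @param universe Background symbol universe. Default `NULL` uses the union
#'   of all term members in the collection; pass the detected-protein symbol
#'   set to use the experiment's background instead.
#' @param fdr_threshold Significance cut-off on q. Default 0.01.
#'
#' @return A tibble of class `enrichment_result`, one row per term with
#'   overlap `x >= 1`, sorted by P ascending: columns `term_id`, `name`,
#'   `category`, `x`, `n`, `K`, `N`, `p`, `q`, `significant`, `overlap`
#'   (semicolon-joined symbols).
#' @export
enrich_list <- function(symbols, terms, universe = NULL, fdr_threshold = 0.01) {
  symbols <- unique(toupper(symbols))
  if (is.null(universe)) {
    universe <- unique(toupper(unlist(terms$members)))
  } else {
    universe <- unique(toupper(universe))
  }
  if (length(universe) == 0) abort("enrich_list: empty universe")

  outside <- setdiff(symbols, universe)
  if (length(outside) > 0) {
    rp_warn(
      "enrich_list: dropping ", length(outside),
      " query symbol(s) outside the universe"
    )
    symbols <- intersect(symbols, universe)
  }

  N <- length(universe)
  n <- length(symbols)

  res <- purrr::map_dfr(seq_len(nrow(terms)), function(i) {
    members <- intersect(terms$members[[i]], universe)
    hit <- intersect(symbols, members)
    tibble(
      term_id = terms$term_id[i],
      name = terms$name[i],
      category = terms$category[i],
      x = length(hit),
      n = n,
      K = length(members),
      N = N,
      overlap = paste(hit[lex_order(hit)], collapse = ";")
    )
  })
  res <- res[res$x >= 1 & res$K >= 1, , drop = FALSE]
  if (nrow(res) == 0) {
    out <- tibble(
      term_id = character(), name = character(), category = character(),
      x = integer(), n = integer(), K = integer(), N = integer(),
      p = numeric(), q = numeric(), significant = logical(),
      overlap = character()
    )
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  res$p <- hypergeom_pvalue(res$x, res$n, res$K, res$N)
  res <- res |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup()
  res$significant <- res$q < fdr_threshold
  res <- res[lex_order(res$p, res$q, res$term_id), , drop = FALSE]
  res <- res[, c(
    "term_id", "name", "category", "x", "n", "K", "N",
    "p", "q", "significant", "overlap"
  )]
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_terms_tested = nrow(x),
    n_significant = sum(x$significant),
    min_q = if (nrow(x) > 0) min(x$q) else NA_real_,
    top_term = if (nrow(x) > 0) x$term_id[1] else NA_character_
  )
}
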