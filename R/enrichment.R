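# Term enrichment (GO/SynGO-style over-representation) against a
# user-supplied background, with Benjamini-Hochberg correction and the
# -log10 significance transform. Testing a membrane-anchored query against
# the full proteome would trivially enrich membrane terms; supplying the
# membrane-anchored list itself as the background removes that bias.

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: step-up
#' false-discovery-rate control, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order, each `>=` its input and
#'   `<= 1`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1]", class = "shedscan_domain_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Negative log10 of a p-value, with a capped zero sentinel
#'
#' The conventional display transform for adjusted p-values: significance at
#' the 0.05 level corresponds to `-log10(p) >= 1.3` (since
#' `-log10(0.05) = 1.301`). Zero p-values (possible after floating-point
#' underflow) are reported as the finite cap rather than infinity so that
#' output tables stay numeric.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param cap Value substituted for `-log10(0)` (default 300, just under the
#'   double-precision underflow limit).
#' @return `-log10(p)`, element-wise, with zeros mapped to `cap`.
#' @export
neg_log10 <- function(p, cap = 300) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]", class = "shedscan_domain_error")
  }
  out <- -log10(p)
  out[p == 0] <- cap
  out
}

#' Significance threshold on the -log10 scale
#'
#' `-log10(alpha)` for the adjusted-p cutoff; 1.301 at the conventional
#' `alpha = 0.05`, usually quoted as 1.3.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The threshold on the `-log10` scale.
#' @export
neg_log10_threshold <- function(alpha = 0.05) {
  -log10(alpha)
}

#' Term over-representation analysis with a custom background
#'
#' One-sided hypergeometric over-representation of annotation terms in a
#' query gene set relative to a user-supplied background universe. Term gene
#' sets are intersected with the background before testing; query genes with
#' no term annotation still count toward the query size `n` (they can only
#' dilute enrichment, mirroring how DAVID treats unannotated genes within a
#' supplied background). Terms with no query hits are skipped. BH correction
#' is applied across all tested terms of the run (one term namespace).
#'
#' @param query Character vector of query genes; must be a subset of
#'   `background`.
#' @param background Character vector, the background universe (e.g. all
#'   membrane-anchored proteins).
#' @param term_table Either a data frame with columns `term_id`, `term_name`
#'   (optional) and `gene`, or a named list of gene vectors.
#' @param alpha Significance level on adjusted p (default 0.05; the
#'   significance flag is `neg_log10_p_adj >= -log10(alpha)`).
#' @param ease Use the conservative EASE variant (DAVID's default), which
#'   penalises single-gene hits by removing one query hit from each term
#'   before taking the hypergeometric tail. Default `FALSE`: plain
#'   hypergeometric.
#' @return A tibble of class `enrichment_result`, one row per tested term,
#'   sorted by adjusted p: `term_id`, `term_name`, `K` (background genes with
#'   the term), `n` (query size), `k` (query hits), `expected`,
#'   `fold_enrichment`, `p`, `p_adj`, `neg_log10_p_adj`, `significant`.
#' @export
term_enrichment <- function(query, background, term_table, alpha = 0.05,
                            ease = FALSE) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    abort(sprintf("query gene(s) not in background: %s",
                  paste(head(stray, 10), collapse = ", ")),
          class = "shedscan_domain_error")
  }
  if (is.data.frame(term_table)) {
    if (!all(c("term_id", "gene") %in% names(term_table))) {
      abort("term table needs columns term_id and gene",
            class = "shedscan_format_error")
    }
    if (!"term_name" %in% names(term_table)) {
      term_table$term_name <- term_table$term_id
    }
    terms <- split(as.character(term_table$gene), term_table$term_id)
    term_names <- term_table$term_name[!duplicated(term_table$term_id)]
    names(term_names) <- term_table$term_id[!duplicated(term_table$term_id)]
  } else {
    terms <- lapply(term_table, as.character)
    term_names <- setNames(names(terms), names(terms))
  }
  B <- length(background)
  n <- length(query)

  rows <- purrr::imap_dfr(terms, function(genes, id) {
    genes <- intersect(unique(genes), background)
    K <- length(genes)
    k <- length(intersect(query, genes))
    if (k == 0) return(NULL)
    k_eff <- if (ease) max(k - 1L, 0L) else k
    p <- if (k_eff == 0) 1 else phyper(k_eff - 1, K, B - K, n,
                                       lower.tail = FALSE)
    expected <- n * K / B
    tibble::tibble(term_id = id,
                   term_name = unname(term_names[id]),
                   K = K, n = n, k = k,
                   expected = expected,
                   fold_enrichment = if (expected == 0) NA_real_
                                     else k / expected,
                   p = p)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(term_id = character(), term_name = character(),
                           K = integer(), n = integer(), k = integer(),
                           expected = double(), fold_enrichment = double(),
                           p = double(), p_adj = double(),
                           neg_log10_p_adj = double(),
                           significant = logical())
    return(structure(rows, class = c("enrichment_result", class(rows)),
                     alpha = alpha))
  }
  rows$p_adj <- bh_adjust(rows$p)
  rows$neg_log10_p_adj <- neg_log10(rows$p_adj)
  rows$significant <- rows$neg_log10_p_adj >= neg_log10_threshold(alpha)
  rows <- dplyr::arrange(rows, .data$p_adj, .data$p, .data$term_id)
  structure(rows, class = c("enrichment_result", class(rows)), alpha = alpha)
}
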