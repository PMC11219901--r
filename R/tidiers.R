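# broom-style tidiers for the fitted result objects.

#' Tidy a differential-abundance result
#' @param x A `diff_abund` tibble.
#' @param ... Unused.
#' @return The per-protein results as a plain tibble.
#' @export
tidy.diff_abund <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a differential-abundance fit
#' @param x A `diff_abund` tibble.
#' @param alpha Adjusted-p threshold for the significance count.
#' @param ... Unused.
#' @return A one-row tibble: `n_proteins`, `n_significant`, prior `d0` and
#'   `s0sq`, residual `df`.
#' @export
glance.diff_abund <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_significant = sum(x$p_adj < alpha),
    d0 = attr(x, "d0"),
    s0sq = attr(x, "s0sq"),
    df = x$df[1] %||% NA_integer_)
}

#' Tidy an overlap test
#' @param x An `overlap_test` tibble.
#' @param ... Unused.
#' @return The result row(s) as a plain tibble.
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an overlap test
#' @param x An `overlap_test`.
#' @param ... Unused.
#' @return A one-row tibble with the key statistics.
#' @export
glance.overlap_test <- function(x, ...) {
  tibble::as_tibble(x)[, intersect(
    c("N", "n1", "n2", "k", "expected", "fold_enrichment", "p_hyper",
      "mc_p", "mc_fold"), names(x))]
}

#' Tidy an enrichment result
#' @param x An `enrichment_result` tibble.
#' @param ... Unused.
#' @return The per-term results as a plain tibble.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an enrichment run
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A one-row tibble: terms tested, terms significant, query and
#'   background sizes.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_terms_tested = nrow(x),
    n_significant = sum(x$significant),
    query_size = if (nrow(x) > 0) x$n[1] else NA_integer_,
    alpha = attr(x, "alpha"))
}
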