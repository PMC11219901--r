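# Set-overlap statistics between sheddomes: Venn region counts, the
# upper-tail hypergeometric overlap test, and fold enrichment with both the
# analytic null (n1*n2/N) and a Monte-Carlo null drawn from the
# membrane-anchored universe.

check_overlap_args <- function(N, n1, n2, k) {
  ok <- length(N) == 1 && length(n1) == 1 && length(n2) == 1 &&
    length(k) == 1 && !anyNA(c(N, n1, n2, k)) &&
    all(c(N, n1, n2, k) == floor(c(N, n1, n2, k))) &&
    k >= 0 && k <= min(n1, n2) && n1 <= N && n2 <= N && N >= 0
  if (!ok) {
    abort("overlap test requires integers 0 <= k <= min(n1, n2) <= N and n1, n2 <= N",
          class = "shedscan_domain_error")
  }
}

#' Hypergeometric test for the overlap of two protein sets
#'
#' Tests whether the observed overlap `k` between two sets of sizes `n1` and
#' `n2`, drawn from a universe of `N` proteins (by default the
#' transmembrane/GPI-anchored list), is larger than expected under uniform
#' random sampling. The p-value is the upper tail
#' \deqn{p = \sum_{i=k}^{\min(n_1,n_2)} \binom{n_2}{i}\binom{N-n_2}{n_1-i} / \binom{N}{n_1},}
#' the expected overlap is \eqn{n_1 n_2 / N}, and fold enrichment is
#' `k / expected` (reported as `NA` when the expectation is zero, i.e. when
#' either set is empty).
#'
#' @param N Universe size.
#' @param n1,n2 Sizes of the two sets.
#' @param k Observed overlap.
#' @return A one-row tibble of class `overlap_test` with columns `N`, `n1`,
#'   `n2`, `k`, `expected`, `fold_enrichment`, `p_hyper`.
#' @examples
#' hypergeometric_overlap_test(N = 20, n1 = 5, n2 = 8, k = 4)
#' @export
hypergeometric_overlap_test <- function(N, n1, n2, k) {
  check_overlap_args(N, n1, n2, k)
  p <- if (k == 0) 1.0 else phyper(k - 1, n2, N - n2, n1, lower.tail = FALSE)
  expected <- if (N == 0) 0 else n1 * n2 / N
  fold <- if (expected == 0) NA_real_ else k / expected
  out <- tibble::tibble(N = as.integer(N), n1 = as.integer(n1),
                        n2 = as.integer(n2), k = as.integer(k),
                        expected = expected, fold_enrichment = fold,
                        p_hyper = p)
  structure(out, class = c("overlap_test", class(out)))
}

#' Monte-Carlo overlap test against a resampled null
#'
#' Empirical counterpart of [hypergeometric_overlap_test()]: draws `reps`
#' uniform samples of size `|set1|` from the universe without replacement and
#' compares their overlap with `set2` to the observed overlap. Mirrors the
#' device of re-drawing the first set at random from the transmembrane/GPI
#' protein list to calibrate fold enrichment.
#'
#' @param universe Character vector, the sampling universe.
#' @param set1,set2 Character vectors, both subsets of `universe`.
#' @param reps Number of Monte-Carlo draws (default `1e5`).
#' @param seed Integer seed; the result is fully reproducible from it.
#' @return A one-row tibble of class `overlap_test` with the analytic fields
#'   plus `mc_p` (permutation-test convention,
#'   `(1 + #\{overlap >= k\}) / (reps + 1)`), `mc_fold` (`k` over the mean
#'   simulated overlap), `mc_reps` and `seed`.
#' @export
monte_carlo_overlap <- function(universe, set1, set2, reps = 1e5,
                                seed = 1L) {
  universe <- unique(as.character(universe))
  set1 <- unique(as.character(set1))
  set2 <- unique(as.character(set2))
  if (!all(set1 %in% universe) || !all(set2 %in% universe)) {
    abort("set1 and set2 must be subsets of the universe",
          class = "shedscan_domain_error")
  }
  stopifnot(reps >= 1)
  N <- length(universe); n1 <- length(set1); n2 <- length(set2)
  k <- length(intersect(set1, set2))

  in2 <- universe %in% set2
  set.seed(seed)
  sims <- vapply(seq_len(reps),
                 function(i) sum(in2[sample.int(N, n1)]),
                 integer(1))
  mc_p <- (1 + sum(sims >= k)) / (reps + 1)
  mean_sim <- mean(sims)
  mc_fold <- if (mean_sim == 0) NA_real_ else k / mean_sim

  out <- hypergeometric_overlap_test(N, n1, n2, k)
  out$mc_p <- mc_p
  out$mc_fold <- mc_fold
  out$mc_reps <- as.integer(reps)
  out$seed <- as.integer(seed)
  out
}

#' Exclusive-region counts for two or three labelled sets
#'
#' Computes the counts behind a Venn diagram: every exclusive region plus the
#' per-set and union totals.
#'
#' @param sets A named list of 2 or 3 character vectors.
#' @return A tibble with columns `region` (e.g. `"A_only"`, `"A&B"`) and
#'   `count`, followed by `total_<name>` rows and `union`.
#' @examples
#' venn_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets) %||% LETTERS[seq_along(sets)]
  nm[nm == ""] <- LETTERS[seq_along(sets)][nm == ""]
  names(sets) <- nm
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), nrow = 0, ncol = length(sets),
                     dimnames = list(NULL, nm))
  }
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]  # drop the all-out region
  names(combos) <- nm
  region_rows <- purrr::pmap_dfr(combos, function(...) {
    inc <- c(...)
    sel <- rep(TRUE, length(universe))
    for (j in seq_along(inc)) {
      sel <- sel & (member[, j] == inc[j])
    }
    label <- if (sum(inc) == 1) paste0(nm[inc], "_only")
             else paste(nm[inc], collapse = "&")
    tibble::tibble(region = unname(label), count = unname(sum(sel)))
  })
  totals <- tibble::tibble(
    region = c(paste0("total_", nm), "union"),
    count = unname(c(vapply(sets, length, integer(1)), length(universe))))
  dplyr::bind_rows(region_rows, totals)
}
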