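# Two-group differential abundance of label-free intensities: contaminant
# and consistency filtering, log2 transform, left-censored (MNAR) imputation
# with a down-shifted Gaussian, and an empirical-Bayes moderated t-test with
# variance shrinkage toward a moment-estimated prior.

#' Preprocess a protein table for differential testing
#'
#' Drops contaminants, applies the replicate-consistency rule, and converts
#' the retained MaxLFQ intensities to log2. The consistency rule removes
#' proteins that were not quantified reproducibly within a condition: by
#' default a protein is kept only if it is quantified in *all* replicates of
#' at least one group (`consistency = "all"`); an integer `k` relaxes this to
#' at least `k` replicates of at least one group.
#'
#' @param table A `protein_table`.
#' @param groups Either a data frame with columns `sample` and `group`, or a
#'   named character vector `sample -> group`. Exactly two groups, each with
#'   at least two samples. The first factor level (alphabetical unless given
#'   as a factor) is the reference; fold changes are `group2 - group1`.
#' @param contaminants Character vector of contaminant accessions to drop
#'   (default none).
#' @param consistency `"all"` or an integer minimum per-group quantification
#'   count.
#' @return An object of class `intensity_matrix`: a list with `log2` (protein
#'   x sample matrix of log2 intensities, `NA` where missing), `groups`
#'   (factor per sample), `mask` (logical matrix of imputed cells, all
#'   `FALSE` before imputation), and `dropped` (counts of removed rows by
#'   reason).
#' @export
preprocess <- function(table, groups, contaminants = character(),
                       consistency = "all") {
  if (is.data.frame(groups)) {
    g <- setNames(groups$group, as.character(groups$sample))
  } else {
    g <- groups
  }
  samples <- names(g)
  miss <- setdiff(samples, sample_columns(table) %||% names(table))
  if (length(miss) > 0) {
    abort(sprintf("group sample(s) not in table: %s",
                  paste(miss, collapse = ", ")),
          class = "shedscan_config_error")
  }
  gf <- if (is.factor(g)) droplevels(g) else factor(as.character(g))
  if (nlevels(gf) != 2L) {
    abort("exactly two groups are required", class = "shedscan_config_error")
  }
  if (any(table(gf) < 2L)) {
    abort("each group needs at least two samples",
          class = "shedscan_config_error")
  }

  mat <- as.matrix(tibble::as_tibble(table)[, samples])
  rownames(mat) <- table$accession
  storage.mode(mat) <- "double"

  is_contam <- table$accession %in% contaminants
  if ("contaminant" %in% names(table)) {
    is_contam <- is_contam | (!is.na(table$contaminant) & table$contaminant)
  }
  n_contam <- sum(is_contam)
  mat <- mat[!is_contam, , drop = FALSE]

  per_group_n <- table(gf)
  need <- if (identical(consistency, "all")) {
    as.integer(per_group_n)
  } else {
    k <- as.integer(consistency)
    pmin(as.integer(per_group_n), k)
  }
  names(need) <- levels(gf)
  quant <- sapply(levels(gf), function(lv) {
    rowSums(!is.na(mat[, gf == lv, drop = FALSE]))
  })
  if (nrow(mat) == 1) quant <- matrix(quant, nrow = 1,
                                      dimnames = list(rownames(mat),
                                                      levels(gf)))
  consistent <- quant[, 1] >= need[1] | quant[, 2] >= need[2]
  n_inconsistent <- sum(!consistent)
  mat <- mat[consistent, , drop = FALSE]

  structure(list(
    log2 = log2(mat),
    groups = gf,
    mask = matrix(FALSE, nrow(mat), ncol(mat),
                  dimnames = dimnames(mat)),
    dropped = c(contaminant = n_contam, inconsistent = n_inconsistent)
  ), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples (%s); %d imputed cells\n",
              nrow(x$log2), ncol(x$log2),
              paste(sprintf("%s n=%d", levels(x$groups),
                            as.integer(table(x$groups))), collapse = " vs "),
              sum(x$mask)))
  invisible(x)
}

#' Impute left-censored missing values (MNAR)
#'
#' Missing label-free intensities are predominantly low-abundance
#' non-detections (missing not at random). Following the widely used
#' Perseus-style instantiation, each missing cell in sample `s` is drawn from
#' a Gaussian down-shifted from that sample's observed distribution:
#' \deqn{x \sim N(\mu_s - \mathrm{shift}\cdot\sigma_s,\ (\mathrm{width}\cdot\sigma_s)^2)}
#' with defaults `shift = 1.8` and `width = 0.3` standard deviations.
#'
#' @param x An `intensity_matrix` from [preprocess()].
#' @param shift Down-shift in per-sample standard-deviation units.
#' @param width Width of the imputation distribution in s.d. units.
#' @param seed Integer seed; the imputation is bit-reproducible from it.
#' @return The `intensity_matrix` with no remaining missing cells and `mask`
#'   marking every imputed cell.
#' @export
impute_mnar <- function(x, shift = 1.8, width = 0.3, seed = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  m <- x$log2
  if (!anyNA(m)) return(x)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 3L)) {
    abort(sprintf(
      "sample(s) with fewer than 3 observed values (cannot estimate mean/sd): %s",
      paste(colnames(m)[n_obs < 3L], collapse = ", ")),
      class = "shedscan_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  mask <- x$mask
  for (j in seq_len(ncol(m))) {
    obs <- m[, j][!is.na(m[, j])]
    mu <- mean(obs); sigma <- sd(obs)
    nas <- which(is.na(m[, j]))
    if (length(nas) > 0) {
      m[nas, j] <- rnorm(length(nas),
                         mean = mu - shift * sigma,
                         sd = width * sigma)
      mask[nas, j] <- TRUE
    }
  }
  x$log2 <- m
  x$mask <- mask
  x
}

# Inverse of trigamma by Newton iteration on 1/x (monotone, convex there);
# needed for the method-of-moments fit of the variance prior.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior `s0^2, d0` for per-protein
#' residual variances by the method of moments on `log(s_g^2)`: under the
#' hierarchical model, `e_g = log(s_g^2) - digamma(d/2) + log(d/2)` has mean
#' `log(s0^2) + digamma(d0/2) - log(d0/2)` and excess variance
#' `trigamma(d0/2)` beyond the sampling term `trigamma(d/2)`. When the
#' observed spread does not exceed the sampling spread the moment equation
#' has no finite root and `d0` is capped at `1e6` (near-complete shrinkage).
#'
#' @param s2 Per-protein residual variances (zeros are excluded from the
#'   fit).
#' @param df Residual degrees of freedom (scalar, `n1 + n2 - 2`).
#' @return A list with `d0` and `s0sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) == 0) {
    abort("all residual variances are zero: degenerate input",
          class = "shedscan_numerical_error")
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- if (length(e) > 1) var(e) else 0
  excess <- evar - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    if (!is.finite(d0) || d0 > 1e6) {
      inform("variance prior d0 capped at 1e6 (near-complete shrinkage)")
      d0 <- 1e6
    }
  } else {
    inform("variance prior d0 capped at 1e6 (near-complete shrinkage)")
    d0 <- 1e6
  }
  s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated two-sample t-test (empirical Bayes)
#'
#' Protein-wise two-group comparison with variance moderation: the pooled
#' per-protein variance `s_g^2` (d = n1 + n2 - 2 degrees of freedom) is
#' shrunk toward the prior `s0^2` (d0 prior degrees of freedom, both
#' estimated by [fit_variance_prior()] unless supplied):
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
#'       \tilde t_g = \frac{\bar x_{g2} - \bar x_{g1}}
#'                         {\tilde s_g \sqrt{1/n_1 + 1/n_2}},}
#' with two-sided p-values from the t distribution on `d0 + d` degrees of
#' freedom and BH adjustment across proteins. `d0 = 0` recovers the ordinary
#' pooled t-test; `d0 = Inf` fixes every variance at `s0^2`.
#'
#' @param x A complete (post-imputation) `intensity_matrix`.
#' @param prior Optional list with `d0` and `s0sq` to override the
#'   empirical-Bayes fit (useful for the no-shrinkage limit `d0 = 0`).
#' @return A tibble of class `diff_abund`, one row per protein: `accession`,
#'   `log2fc` (group2 minus group1 mean), `s2`, `df`, `s2_post`, `t`, `df_total`,
#'   `p`, `p_adj`, `direction`, `n_imputed`. The fitted prior and group
#'   labels are attached as attributes (`d0`, `s0sq`, `groups`).
#' @export
moderated_t_test <- function(x, prior = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  m <- x$log2
  if (anyNA(m)) {
    abort("matrix has missing values: run impute_mnar() first",
          class = "shedscan_domain_error")
  }
  gf <- x$groups
  lv <- levels(gf)
  i1 <- gf == lv[1]; i2 <- gf == lv[2]
  n1 <- sum(i1); n2 <- sum(i2)
  d <- n1 + n2 - 2L

  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  diff <- m2 - m1
  ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d

  if (is.null(prior)) {
    if (all(s2 == 0)) {
      if (any(diff != 0)) {
        abort("all residual variances are zero: degenerate input",
              class = "shedscan_numerical_error")
      }
      # identical groups everywhere: no evidence, no shrinkage needed
      prior <- list(d0 = 0, s0sq = 0)
    } else {
      prior <- fit_variance_prior(s2, d)
    }
  } else if (all(s2 == 0) && any(diff != 0)) {
    abort("all residual variances are zero: degenerate input",
          class = "shedscan_numerical_error")
  }
  d0 <- prior$d0; s0sq <- prior$s0sq

  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf),
                   diff / se)
  df_total <- min(d0 + d, .Machine$double.xmax)
  p <- 2 * pt(-abs(t_stat), df = df_total)
  p[t_stat == 0] <- 1

  out <- tibble::tibble(
    accession = rownames(m),
    log2fc = unname(diff),
    s2 = unname(s2),
    df = d,
    s2_post = unname(s2_post),
    t = unname(t_stat),
    df_total = df_total,
    p = unname(p),
    p_adj = bh_adjust(unname(p)),
    direction = dplyr::case_when(diff > 0 ~ "up", diff < 0 ~ "down",
                                 TRUE ~ "none"),
    n_imputed = as.integer(rowSums(x$mask)))
  structure(out, class = c("diff_abund", class(out)),
            d0 = d0, s0sq = s0sq,
            groups = stats::setNames(c(n1, n2), lv))
}

#' Annotate differential results for a volcano plot
#'
#' Adds the display transform and a significance class at the given fold
#' change and p thresholds, and summary counts. Thresholds are strict: a
#' protein at exactly `alpha` sits on the dashed line and is classified
#' `ns`. By default classification uses BH-adjusted p for the significant
#' list, while the conventional dashed plotting line corresponds to raw
#' `p = 0.05` (`-log10 = 1.3`).
#'
#' @param results A `diff_abund` tibble.
#' @param fc_threshold Minimum `|log2fc|` (default 0: any change).
#' @param alpha Significance threshold (default 0.05), applied strictly
#'   (`p < alpha`).
#' @param p_column `"p_adj"` (default) or `"p"`.
#' @return A tibble of class `volcano_table` with added `neg_log10_p`
#'   (transform of `p_column`) and `class` (`"up"`, `"down"`, `"ns"`);
#'   `attr(, "summary")` holds `n_tested`, `n_significant`,
#'   `percent_significant` (full precision) and the thresholds.
#' @export
volcano_table <- function(results, fc_threshold = 0, alpha = 0.05,
                          p_column = c("p_adj", "p")) {
  p_column <- match.arg(p_column)
  pv <- results[[p_column]]
  sig <- pv < alpha & abs(results$log2fc) > fc_threshold
  out <- dplyr::mutate(tibble::as_tibble(results),
    neg_log10_p = neg_log10(pv),
    class = dplyr::case_when(
      sig & .data$log2fc > 0 ~ "up",
      sig & .data$log2fc < 0 ~ "down",
      TRUE ~ "ns"))
  n_tested <- nrow(out)
  n_sig <- sum(sig)
  structure(out, class = c("volcano_table", class(out)),
            summary = list(
              n_tested = n_tested,
              n_significant = n_sig,
              n_up = sum(out$class == "up"),
              n_down = sum(out$class == "down"),
              percent_significant = if (n_tested == 0) 0
                                    else 100 * n_sig / n_tested,
              fc_threshold = fc_threshold,
              alpha = alpha,
              p_column = p_column))
}
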