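# Preprocessing, MNAR imputation and the empirical-Bayes moderated t-test.

two_group_labels <- function(samples = paste0("s", 1:8)) {
  tibble::tibble(sample = samples,
                 group = factor(rep(c("g1", "g2"), each = 4),
                                levels = c("g1", "g2")))
}

test_that("preprocess applies contaminant and consistency rules", {
  samples <- paste0("s", 1:8)
  mk <- function(v) as.numeric(v)
  df <- tibble::tibble(
    accession = c("FULL", "ONE_GROUP", "PATCHY", "CONTAM"),
    gene_symbol = NA_character_,
    s1 = mk(c(2^20, 2^20, 2^20, 2^20)),
    s2 = mk(c(2^20, 2^20, 2^20, 2^20)),
    s3 = mk(c(2^20, 2^20, NA, 2^20)),
    s4 = mk(c(2^20, 2^20, NA, 2^20)),
    s5 = mk(c(2^20, NA, 2^20, 2^20)),
    s6 = mk(c(2^20, NA, 2^20, 2^20)),
    s7 = mk(c(2^20, NA, NA, 2^20)),
    s8 = mk(c(2^20, NA, NA, 2^20)))
  tb <- as_protein_table(df, samples)
  im <- preprocess(tb, two_group_labels(), contaminants = "CONTAM")
  # quantified 4/4 in one group and 0/4 in the other is consistent
  expect_setequal(rownames(im$log2), c("FULL", "ONE_GROUP"))
  # 2/4 in each group fails the default all-replicates rule
  expect_false("PATCHY" %in% rownames(im$log2))
  expect_equal(unname(im$dropped["contaminant"]), 1L)
  expect_equal(unname(im$dropped["inconsistent"]), 1L)
  # relaxed rule >= 2 per group readmits the patchy protein
  im2 <- preprocess(tb, two_group_labels(), contaminants = "CONTAM",
                    consistency = 2)
  expect_true("PATCHY" %in% rownames(im2$log2))
  # log2 transform applied
  expect_equal(unname(im$log2["FULL", "s1"]), 20)

  bad <- two_group_labels()
  bad$group <- factor(rep(c("g1", "g2", "g3", "g1"), 2))
  expect_error(preprocess(tb, bad), class = "shedscan_config_error")
  expect_error(
    preprocess(tb, tibble::tibble(sample = paste0("s", 1:3),
                                  group = c("g1", "g1", "g2"))),
    class = "shedscan_config_error")
})

test_that("MNAR imputation draws from the down-shifted Gaussian", {
  withr::local_seed(1)
  # no missing cells: identity, empty mask
  m0 <- make_intensity_matrix(matrix(rnorm(40, 25, 2), 5))
  expect_identical(impute_mnar(m0, seed = 1)$log2, m0$log2)
  expect_equal(sum(impute_mnar(m0, seed = 1)$mask), 0)

  # width = 0 collapses to the point mu - 1.8 sigma exactly
  # (observed cells of the imputed column have mean 25, sd 2 exactly)
  obs <- as.numeric(scale(rnorm(190))) * 2 + 25
  m1 <- matrix(c(rep(NA_real_, 10), obs, rnorm(200, 25, 2)), ncol = 2)
  im1 <- make_intensity_matrix(m1, n1 = 1)
  out1 <- impute_mnar(im1, shift = 1.8, width = 0, seed = 3)
  expect_equal(unname(out1$log2[1:10, 1]), rep(21.4, 10), tolerance = 1e-9)
  expect_true(all(out1$mask[1:10, 1]))

  # law of large numbers on the stated distribution over 10,000 cells;
  # the observed cells of the imputed sample have mean 25, sd 2 exactly
  n <- 10200
  col_obs <- c(rep(NA_real_, 10000),
               as.numeric(scale(rnorm(200))) * 2 + 25)
  m2 <- cbind(col_obs, rnorm(n, 25, 2))
  m2[1:10000, 1] <- NA
  im2 <- make_intensity_matrix(m2, n1 = 1)
  out2 <- impute_mnar(im2, shift = 1.8, width = 0.3, seed = 4)
  imp <- out2$log2[1:10000, 1]
  expect_lt(abs(mean(imp) - 21.4), 0.05)
  expect_lt(abs(sd(imp) - 0.6), 0.05)

  # same seed is bit-reproducible
  outA <- impute_mnar(im2, seed = 9)
  outB <- impute_mnar(im2, seed = 9)
  expect_identical(outA$log2, outB$log2)

  # a sample with < 3 observed values cannot be imputed
  m3 <- matrix(c(NA, NA, 1, 2, 3, 4), ncol = 2)
  expect_error(impute_mnar(make_intensity_matrix(m3, n1 = 1)),
               class = "shedscan_domain_error")
})

test_that("moderated t reproduces the hand-computed shrinkage example", {
  # one protein: diff = 1, n1 = n2 = 3, s_g^2 = 0.25, prior d0 = 4,
  # s0^2 = 0.25 -> posterior variance 0.25, t = 1/(0.5 sqrt(2/3)), df = 8
  g1 <- c(-0.5, 0, 0.5); g2 <- g1 + 1    # mean diff 1, pooled s2 = 0.25
  m <- matrix(c(g1, g2), nrow = 1)
  im <- make_intensity_matrix(m, n1 = 3)
  r <- moderated_t_test(im, prior = list(d0 = 4, s0sq = 0.25))
  expect_equal(r$log2fc, 1)
  expect_equal(r$s2, 0.25)
  expect_equal(r$s2_post, 0.25)
  expect_equal(r$t, 1 / (0.5 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(r$t, 2.449, tolerance = 1e-3)
  expect_equal(r$df_total, 8)
  expect_equal(r$p, 2 * pt(-r$t, df = 8), tolerance = 1e-12)
})

test_that("d0 = 0 recovers the ordinary pooled two-sample t exactly", {
  withr::local_seed(5)
  m <- matrix(rnorm(20 * 8, 24, 1), 20)
  m[1:4, 5:8] <- m[1:4, 5:8] + 1.5
  im <- make_intensity_matrix(m)
  r <- moderated_t_test(im, prior = list(d0 = 0, s0sq = 1))
  for (i in c(1, 7, 20)) {
    tt <- t.test(m[i, 5:8], m[i, 1:4], var.equal = TRUE)
    expect_equal(r$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("shrinkage brackets every posterior variance; d0 -> Inf is the z-limit", {
  withr::local_seed(6)
  m <- matrix(rnorm(50 * 8, 24, 1), 50)
  im <- make_intensity_matrix(m)
  r <- moderated_t_test(im)
  d0 <- attr(r, "d0"); s0 <- attr(r, "s0sq")
  expect_true(all(r$s2_post >= pmin(r$s2, s0) - 1e-12))
  expect_true(all(r$s2_post <= pmax(r$s2, s0) + 1e-12))

  rInf <- moderated_t_test(im, prior = list(d0 = 1e8, s0sq = 0.8))
  z <- (rowMeans(m[, 5:8]) - rowMeans(m[, 1:4])) /
    sqrt(0.8 * (1 / 4 + 1 / 4))
  expect_equal(rInf$t, unname(z), tolerance = 1e-4)
})

test_that("identical groups give t = 0, p = 1; degenerate input errors", {
  withr::local_seed(10)
  m <- matrix(rep(rnorm(5, 24, 1), 8), nrow = 5)  # same value across samples
  im <- make_intensity_matrix(m)
  r <- moderated_t_test(im)
  expect_true(all(r$t == 0))
  expect_true(all(r$p == 1))

  m2 <- matrix(rep(c(20, 22), each = 4), nrow = 1)
  expect_error(moderated_t_test(make_intensity_matrix(m2)),
               class = "shedscan_numerical_error")

  m3 <- matrix(c(rnorm(8), NA), nrow = 1)[, 1:8, drop = FALSE]
  m3[1, 3] <- NA
  expect_error(moderated_t_test(make_intensity_matrix(m3)),
               class = "shedscan_domain_error")
})

test_that("moderated t agrees with the limma reference implementation", {
  withr::local_seed(8)
  # heteroscedastic truth so the prior degrees of freedom are finite
  n <- 150
  true_sd <- sqrt(0.3 * 5 / rchisq(n, df = 5))
  m <- matrix(rnorm(n * 8, 24, rep(true_sd, 8)), nrow = n)
  m[1:15, 5:8] <- m[1:15, 5:8] - 1
  im <- make_intensity_matrix(m)
  r <- moderated_t_test(im)

  design <- cbind(1, rep(c(0, 1), each = 4))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(r, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(r, "s0sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(r$t, fit$t[, 2], ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(r$p, fit$p.value[, 2], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("significant sets are stable across imputation seeds", {
  bench <- recovery_benchmark(seeds = 101:105)
  expect_gte(mean(bench$jaccard_reimpute), 0.8)
})

test_that("volcano table classifies at strict thresholds and summarises", {
  mk_res <- function(p_adj, fc) {
    structure(tibble::tibble(
      accession = sprintf("P%d", seq_along(p_adj)),
      log2fc = fc, s2 = 0.1, df = 6L, s2_post = 0.1, t = 1,
      df_total = 10, p = p_adj, p_adj = p_adj,
      direction = ifelse(fc > 0, "up", "down"), n_imputed = 0L),
      class = c("diff_abund", "tbl_df", "tbl", "data.frame"),
      d0 = 4, s0sq = 0.1)
  }
  # everything null
  v0 <- volcano_table(mk_res(rep(1, 5), rep(0.5, 5)))
  expect_equal(attr(v0, "summary")$n_significant, 0)
  expect_equal(attr(v0, "summary")$percent_significant, 0)

  # 7 of 169 significant reported as 4.1% at one decimal
  p <- c(rep(0.01, 7), rep(0.5, 162))
  v <- volcano_table(mk_res(p, rep(-1, 169)))
  s <- attr(v, "summary")
  expect_equal(s$n_tested, 169)
  expect_equal(s$n_significant, 7)
  expect_equal(format_percent(s$percent_significant, 1), "4.1%")
  expect_equal(sum(v$class == "down"), 7)

  # exactly at alpha sits on the line: ns under the strict inequality
  vb <- volcano_table(mk_res(c(0.05, 0.049), c(1, 1)))
  expect_equal(vb$class, c("ns", "up"))
})
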