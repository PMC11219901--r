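# Overlap statistics and term enrichment.

test_that("hypergeometric overlap test matches exhaustive tail sums", {
  # sum of the pmf terms i = 4, 5: (C(8,4)C(12,1) + C(8,5)C(12,0)) / C(20,5)
  r <- hypergeometric_overlap_test(N = 20, n1 = 5, n2 = 8, k = 4)
  expect_equal(r$p_hyper, 896 / 15504, tolerance = 1e-12)
  expect_equal(r$expected, 2)
  expect_equal(r$fold_enrichment, 2)

  # brute-force oracle: full enumeration of the pmf on small instances
  brute_tail <- function(N, n1, n2, k) {
    i <- k:min(n1, n2)
    sum(choose(n2, i) * choose(N - n2, n1 - i)) / choose(N, n1)
  }
  cases <- list(c(20, 5, 8, 2), c(15, 6, 6, 3), c(30, 10, 12, 7),
                c(10, 4, 4, 4))
  for (cs in cases) {
    expect_equal(
      hypergeometric_overlap_test(cs[1], cs[2], cs[3], cs[4])$p_hyper,
      brute_tail(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-12)
  }

  # k at the expectation has fold enrichment exactly 1
  r2 <- hypergeometric_overlap_test(20, 5, 8, 2)
  expect_equal(r2$fold_enrichment, 1)
  # zero overlap: upper tail from zero is the whole distribution
  expect_equal(hypergeometric_overlap_test(20, 5, 8, 0)$p_hyper, 1)
  # empty set: expectation zero, fold reported missing
  expect_true(is.na(hypergeometric_overlap_test(20, 0, 8, 0)$fold_enrichment))

  expect_error(hypergeometric_overlap_test(20, 5, 8, 6),
               class = "shedscan_domain_error")
  expect_error(hypergeometric_overlap_test(20, 25, 8, 2),
               class = "shedscan_domain_error")
})

test_that("Monte-Carlo overlap agrees with the analytic null and is seeded", {
  u <- sprintf("u%02d", 1:20)
  s1 <- u[1:5]; s2 <- u[4:11]  # k = 2
  r <- monte_carlo_overlap(u, s1, s2, reps = 20000, seed = 5)
  se <- sqrt(r$p_hyper * (1 - r$p_hyper) / r$mc_reps)
  expect_lt(abs(r$mc_p - r$p_hyper), 3 * se)
  # mean simulated overlap estimates n1*n2/N, so mc fold tracks the analytic
  expect_equal(r$mc_fold, r$fold_enrichment, tolerance = 0.1)
  # reproducible from the seed
  r2 <- monte_carlo_overlap(u, s1, s2, reps = 20000, seed = 5)
  expect_identical(r$mc_p, r2$mc_p)

  # degenerate cases
  expect_equal(monte_carlo_overlap(u, u, u, reps = 200, seed = 1)$mc_p, 1)
  expect_equal(
    monte_carlo_overlap(u[1:10], u[1:2], character(), reps = 200,
                        seed = 1)$mc_p, 1)
  expect_error(monte_carlo_overlap(u, c(s1, "zz"), s2),
               class = "shedscan_domain_error")
})

test_that("fold enrichment of a random query centres on 1", {
  withr::local_seed(11)
  u <- sprintf("u%03d", 1:100)
  s2 <- u[1:40]
  folds <- replicate(300, {
    s1 <- sample(u, 25)
    k <- length(intersect(s1, s2))
    k / (25 * 40 / 100)
  })
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 1), 3 * se)
})

test_that("BH adjustment is validated, hand-checked and permutation-stable", {
  expect_equal(bh_adjust(0.05), 0.05)
  # step-up by hand: all three minima equal 0.03
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "shedscan_domain_error")

  withr::local_seed(2)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("-log10 transform and the 1.3 significance threshold", {
  expect_equal(round(neg_log10(0.05), 3), 1.301)
  expect_gte(neg_log10(0.05), neg_log10_threshold(0.05))
  expect_equal(neg_log10(1), 0)
  expect_equal(neg_log10(0.001), 3)
  # zero maps to the documented finite cap, never infinity
  expect_equal(neg_log10(0), 300)
  expect_error(neg_log10(-0.1), class = "shedscan_domain_error")
})

test_that("term enrichment against a custom background", {
  bg <- sprintf("g%02d", 1:10)
  terms <- tibble::tibble(
    term_id = rep(c("T1", "T2"), c(4, 5)),
    term_name = rep(c("one", "two"), c(4, 5)),
    gene = c(bg[1:4], bg[3:7]))

  # query = background: nothing can be over-represented
  r_all <- term_enrichment(bg, bg, terms)
  expect_true(all(r_all$p == 1))

  # a term annotating exactly the query attains the minimum p = 1/C(B, n)
  q <- bg[1:3]
  t_exact <- tibble::tibble(term_id = "TX", term_name = "exact", gene = q)
  r_min <- term_enrichment(q, bg, t_exact)
  expect_equal(r_min$p, 1 / choose(10, 3), tolerance = 1e-12)

  # genes without term annotation inflate n but never k
  q2 <- c(bg[1:2], bg[9:10])  # two genes in T1, two in no term
  r2 <- term_enrichment(q2, bg, terms)
  t1 <- r2[r2$term_id == "T1", ]
  expect_equal(t1$n, 4L)
  expect_equal(t1$k, 2L)

  # zero-hit terms are skipped; query outside background errors
  r3 <- term_enrichment(bg[5:7], bg, terms)
  expect_false("T1" %in% r3$term_id[r3$k == 0])
  expect_error(term_enrichment(c(bg[1], "zz"), bg, terms), "zz",
               class = "shedscan_domain_error")

  # EASE variant drops one hit per term, so it is never more significant
  re <- term_enrichment(q2, bg, terms, ease = TRUE)
  t1e <- re[re$term_id == "T1", ]
  expect_equal(t1e$p, phyper(0, 4, 6, 4, lower.tail = FALSE))
  expect_gte(t1e$p, t1$p)
})

test_that("random queries from the background show no systematic enrichment", {
  withr::local_seed(9)
  bg <- sprintf("m%03d", 1:80)
  terms <- tibble::tibble(
    term_id = rep(sprintf("T%d", 1:8), each = 10),
    gene = unlist(lapply(1:8, function(i) sample(bg, 10))))
  n_sig <- 0L; n_tests <- 0L
  for (i in 1:200) {
    q <- sample(bg, 20)
    r <- term_enrichment(q, bg, terms)
    n_sig <- n_sig + sum(r$p_adj <= 0.05)
    n_tests <- n_tests + nrow(r)
  }
  rate <- n_sig / n_tests
  se <- sqrt(0.05 * 0.95 / n_tests)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("venn counts cover exclusive regions and totals", {
  v <- venn_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  get <- function(r) v$count[v$region == r]
  expect_equal(get("A_only"), 1)
  expect_equal(get("B_only"), 1)
  expect_equal(get("A&B"), 2)
  expect_equal(get("union"), 4)

  same <- venn_counts(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(same$count[same$region == "A_only"], 0)
  expect_equal(same$count[same$region == "A&B"], 5)

  # the published-size layout: |A| = 84, |B| = 64, overlap 40
  A <- sprintf("a%03d", 1:84)
  B <- c(A[1:40], sprintf("b%03d", 1:24))
  v2 <- venn_counts(list(h1 = A, h2 = B))
  expect_equal(v2$count[v2$region == "h1_only"], 44)
  expect_equal(v2$count[v2$region == "h2_only"], 24)
  expect_equal(v2$count[v2$region == "h1&h2"], 40)

  v3 <- venn_counts(list(A = c("1", "2"), B = c("2", "3"), C = c("3", "4")))
  expect_equal(v3$count[v3$region == "A&B"], 1)
  expect_equal(v3$count[v3$region == "A&B&C"], 0)
})
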