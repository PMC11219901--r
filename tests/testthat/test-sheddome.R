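# Membrane-anchor classification and sheddome extraction.

test_that("membrane anchoring requires a TM domain or a GPI anchor", {
  expect_false(classify_membrane_anchored(0L, FALSE))
  expect_true(classify_membrane_anchored(7L, FALSE))
  expect_true(classify_membrane_anchored(0L, TRUE))
  expect_equal(classify_membrane_anchored(tiny_annotations()),
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("extract_sheddome composes anchor, weight and occurrence filters", {
  withr::local_seed(1)
  tb <- tiny_protein_table()
  ann <- tiny_annotations()

  s0 <- extract_sheddome(tb, ann)
  expect_s3_class(s0, "sheddome_set")
  expect_setequal(s0$accession, c("P1", "P2", "P4"))
  expect_equal(provenance(s0)$output_size, 3)

  # weight boundary is inclusive at mw_min: "below" excluded, equal kept
  s40 <- extract_sheddome(tb, ann, mw_min = 40)
  expect_setequal(s40$accession, c("P2", "P4"))
  ann2 <- ann
  ann2$mol_weight[ann2$accession == "P2"] <- 39.9
  expect_setequal(extract_sheddome(tb, ann2, mw_min = 40)$accession, "P4")
  ann2$mol_weight[ann2$accession == "P2"] <- 40.0
  expect_setequal(extract_sheddome(tb, ann2, mw_min = 40)$accession,
                  c("P2", "P4"))

  # occurrence: detected in 1 of 4 fails min_occurrence = 2, 2 of 4 passes
  df <- tibble::as_tibble(tb)
  df[df$accession == "P1", c("s1", "s2", "s3")] <- NA_real_
  tb1 <- as_protein_table(df, sample_columns(tb))
  expect_false("P1" %in%
    extract_sheddome(tb1, ann, min_occurrence = 2)$accession)
  df[df$accession == "P1", "s2"] <- 2^22
  tb2 <- as_protein_table(df, sample_columns(tb))
  expect_true("P1" %in%
    extract_sheddome(tb2, ann, min_occurrence = 2)$accession)
})

test_that("unannotated accessions are excluded but counted", {
  tb <- tiny_protein_table()
  ann <- tiny_annotations()[1:3, ]
  s <- extract_sheddome(tb, ann)
  expect_setequal(s$accession, c("P1", "P2"))
  expect_equal(provenance(s)$n_unannotated, 2)
})

test_that("filters are order-independent and monotone", {
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- 30
    samples <- paste0("s", 1:4)
    ann <- as_annotation_table(tibble::tibble(
      accession = sprintf("R%02d", 1:n),
      gene_symbol = sprintf("G%d", 1:n),
      seq_length = sample(100:900, n, TRUE),
      mol_weight = runif(n, 10, 120),
      tm_count = rpois(n, 0.8),
      gpi_anchor = runif(n) < 0.2))
    vals <- matrix(2^runif(n * 4, 18, 28), nrow = n)
    vals[runif(length(vals)) < 0.4] <- NA
    df <- dplyr::bind_cols(
      tibble::tibble(accession = ann$accession, gene_symbol = ann$gene_symbol),
      tibble::as_tibble(`colnames<-`(vals, samples)))
    tb <- as_protein_table(df, samples)

    both <- extract_sheddome(tb, ann, mw_min = 40, min_occurrence = 2)
    # manual composition in the other order: occurrence first, then weight
    occ_first <- tb[tb$detection_count >= 2, ]
    occ_first <- as_protein_table(occ_first, samples)
    other <- extract_sheddome(occ_first, ann, mw_min = 40)
    expect_setequal(both$accession, other$accession)

    # no optional filters: exactly the anchored subset of the table
    plain <- extract_sheddome(tb, ann)
    anchored <- ann$accession[classify_membrane_anchored(ann)]
    expect_setequal(plain$accession, intersect(tb$accession, anchored))

    # monotone in both thresholds
    expect_true(all(
      extract_sheddome(tb, ann, mw_min = 60)$accession %in%
        extract_sheddome(tb, ann, mw_min = 40)$accession))
    expect_true(all(
      extract_sheddome(tb, ann, min_occurrence = 3)$accession %in%
        extract_sheddome(tb, ann, min_occurrence = 2)$accession))
  }
})

test_that("merge_fractions pools gel fractions into one table", {
  withr::local_seed(3)
  # five disjoint 10-protein fractions merge to 50 rows
  tabs <- lapply(1:5, function(f) {
    df <- tibble::tibble(
      accession = sprintf("F%d_%02d", f, 1:10),
      gene_symbol = sprintf("G%d_%02d", f, 1:10),
      s1 = 2^runif(10, 20, 26), s2 = 2^runif(10, 20, 26))
    as_protein_table(df, c("s1", "s2"))
  })
  merged <- merge_fractions(tabs)
  expect_equal(nrow(merged), 50)

  # shared protein appears once, with its fraction list, intensities pooled
  t2 <- as_protein_table(tibble::tibble(
    accession = c("PX", "PA"), gene_symbol = c("GX", "GA"),
    s1 = c(100, 50), s2 = c(NA, 60)), c("s1", "s2"))
  t3 <- as_protein_table(tibble::tibble(
    accession = c("PX", "PB"), gene_symbol = c("GX", "GB"),
    s1 = c(200, 70), s2 = c(300, 80)), c("s1", "s2"))
  m <- merge_fractions(list(t2, t3), labels = c("2", "3"))
  expect_equal(nrow(m), 3)
  px <- m[m$accession == "PX", ]
  expect_equal(px$fractions, "2,3")
  expect_equal(px$s1, 300)
  expect_equal(px$s2, 300)
  expect_equal(px$detection_count, 2L)

  # merging a single table is the identity on values and order
  m1 <- merge_fractions(list(t2))
  expect_equal(m1$accession, t2$accession)
  expect_equal(m1$s1, t2$s1)
  expect_equal(m1$detection_count, t2$detection_count)

  # conflicting gene symbols warn and keep the first
  t4 <- as_protein_table(tibble::tibble(
    accession = "PX", gene_symbol = "OTHER", s1 = 1, s2 = 1), c("s1", "s2"))
  expect_warning(m2 <- merge_fractions(list(t2, t4)), "PX")
  expect_equal(m2$gene_symbol[m2$accession == "PX"], "GX")
})
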