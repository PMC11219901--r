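# Sheddome extraction: the membrane-anchored subset of an identified
# proteome, optionally restricted by molecular weight and by detection
# occurrence, with gel-fraction merging.

#' Classify proteins as membrane-anchored
#'
#' A protein is membrane-anchored -- and therefore a candidate ectodomain
#' shedding substrate when found in a soluble fraction -- if it carries at
#' least one transmembrane domain or a GPI anchor.
#'
#' @param tm_count Integer vector of transmembrane-domain counts, or an
#'   `annotation_table` (in which case `gpi_anchor` is ignored).
#' @param gpi_anchor Logical vector of GPI-anchor flags.
#' @return Logical vector: `tm_count >= 1 | gpi_anchor`.
#' @examples
#' classify_membrane_anchored(c(0L, 7L, 0L), c(FALSE, FALSE, TRUE))
#' @export
classify_membrane_anchored <- function(tm_count, gpi_anchor = NULL) {
  if (is.data.frame(tm_count)) {
    gpi_anchor <- tm_count$gpi_anchor
    tm_count <- tm_count$tm_count
  }
  tm_count >= 1L | gpi_anchor
}

#' Extract the sheddome from a protein table
#'
#' Intersects an identified proteome with its membrane-anchored subset and
#' applies the optional molecular-weight and occurrence rules. The weight
#' cutoff is inclusive: proteins *below* `mw_min` are excluded, so a protein
#' at exactly `mw_min` kDa is retained. The occurrence rule keeps proteins
#' quantified in at least `min_occurrence` samples; by default occurrences
#' are counted over all sample columns, or over the subset named in
#' `occurrence_samples` (e.g. the replicates of one condition).
#'
#' Accessions absent from the annotation table are conservatively treated as
#' not membrane-anchored; their number is recorded in the provenance.
#'
#' @param table A `protein_table`.
#' @param annotations An `annotation_table`.
#' @param mw_min Minimum molecular weight in kDa, or `NULL` for no filter.
#' @param min_occurrence Minimum number of samples with a quantified value,
#'   or `NULL` for no filter.
#' @param occurrence_samples Optional character vector of sample columns over
#'   which to count occurrences.
#' @return A tibble of class `sheddome_set` with columns `accession`,
#'   `gene_symbol`, `tm_count`, `gpi_anchor`, `mol_weight`,
#'   `detection_count`; the filter provenance (input/output sizes, filters
#'   applied with parameters, unannotated count) is in
#'   `attr(, "provenance")`.
#' @export
extract_sheddome <- function(table, annotations, mw_min = NULL,
                             min_occurrence = NULL,
                             occurrence_samples = NULL) {
  stopifnot(is.data.frame(table), is.data.frame(annotations))
  ann <- tibble::as_tibble(annotations)[
    , c("accession", "gene_symbol", "tm_count", "gpi_anchor", "mol_weight")]
  names(ann)[2] <- "ann_gene_symbol"

  occ <- table$detection_count
  if (!is.null(occurrence_samples)) {
    miss <- setdiff(occurrence_samples, names(table))
    if (length(miss) > 0) {
      abort(sprintf("occurrence_samples not in table: %s",
                    paste(miss, collapse = ", ")),
            class = "shedscan_config_error")
    }
    occ <- as.integer(rowSums(!is.na(as.matrix(table[occurrence_samples]))))
  }

  x <- tibble::tibble(accession = table$accession,
                      gene_symbol = table$gene_symbol,
                      detection_count = occ)
  x <- dplyr::left_join(x, ann, by = "accession")
  n_unannotated <- sum(is.na(x$tm_count) & is.na(x$gpi_anchor))
  x$gene_symbol <- dplyr::coalesce(x$gene_symbol, x$ann_gene_symbol)
  x$ann_gene_symbol <- NULL

  anchored <- !is.na(x$tm_count) & !is.na(x$gpi_anchor) &
    classify_membrane_anchored(x$tm_count, x$gpi_anchor)
  keep <- anchored
  filters <- list(anchor = "tm_count >= 1 | gpi_anchor")
  if (!is.null(mw_min)) {
    keep <- keep & !is.na(x$mol_weight) & x$mol_weight >= mw_min
    filters$mw_min <- mw_min
  }
  if (!is.null(min_occurrence)) {
    keep <- keep & x$detection_count >= min_occurrence
    filters$min_occurrence <- min_occurrence
  }
  out <- x[keep, c("accession", "gene_symbol", "tm_count", "gpi_anchor",
                   "mol_weight", "detection_count")]
  structure(out,
            class = c("sheddome_set", class(out)),
            provenance = list(
              input_size = nrow(table),
              output_size = nrow(out),
              filters = filters,
              n_unannotated = n_unannotated,
              occurrence_samples = occurrence_samples))
}

#' Filter provenance of a sheddome set
#' @param x A `sheddome_set`.
#' @return The provenance record attached at extraction time.
#' @export
provenance <- function(x) {
  attr(x, "provenance")
}

#' Merge protein tables from gel fractions
#'
#' Pools the protein tables of electrophoretic fractions analysed in separate
#' LC-MS/MS runs into one table. A protein found in several fractions appears
#' once; for sample columns shared between fractions its intensities are
#' summed (total signal across gel slices, linear scale), and detection
#' counts are recomputed over the union of samples. The contributing
#' fractions per protein are recorded in a `fractions` column.
#'
#' @param tables A list of `protein_table` objects (or a single one).
#' @param labels Optional fraction labels; defaults to `"1"`, `"2"`, ...
#' @return A `protein_table` over the union of accessions and samples, with
#'   an extra `fractions` character column (comma-separated labels).
#' @details Conflicting gene symbols for one accession trigger a warning; the
#'   first occurrence wins.
#' @export
merge_fractions <- function(tables, labels = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  labels <- labels %||% as.character(seq_along(tables))
  stopifnot(length(labels) == length(tables))

  all_samples <- unique(unlist(lapply(tables, sample_columns)))
  long <- purrr::map2_dfr(tables, labels, function(tb, lab) {
    tidyr::pivot_longer(
      tibble::as_tibble(tb)[, c("accession", "gene_symbol",
                                sample_columns(tb))],
      cols = dplyr::all_of(sample_columns(tb)),
      names_to = "sample", values_to = "intensity") |>
      dplyr::mutate(fraction = lab)
  })

  sym <- dplyr::distinct(long, .data$accession, .data$gene_symbol) |>
    dplyr::filter(!is.na(.data$gene_symbol))
  conflicts <- sym$accession[duplicated(sym$accession)]
  if (length(conflicts) > 0) {
    warn(sprintf("conflicting gene_symbol for accession(s): %s; keeping first",
                 paste(unique(conflicts), collapse = ", ")))
  }
  sym <- sym[!duplicated(sym$accession), ]

  pooled <- long |>
    dplyr::group_by(.data$accession, .data$sample) |>
    dplyr::summarise(intensity = if (all(is.na(.data$intensity))) NA_real_
                     else sum(.data$intensity, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "intensity")

  frac <- long |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::distinct(.data$accession, .data$fraction) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(fractions = paste(sort(unique(.data$fraction)),
                                       collapse = ","),
                     .groups = "drop")

  first_seen <- unique(long$accession)
  pooled <- pooled[match(first_seen, pooled$accession), ]
  pooled <- dplyr::left_join(pooled, sym, by = "accession")
  pooled <- dplyr::left_join(pooled, frac, by = "accession")
  missing_samples <- setdiff(all_samples, names(pooled))
  for (s in missing_samples) pooled[[s]] <- NA_real_

  out <- as_protein_table(
    pooled[, c("accession", "gene_symbol", all_samples)],
    sample_columns = all_samples)
  out$fractions <- pooled$fractions
  out
}
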