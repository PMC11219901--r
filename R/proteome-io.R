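# Readers and writers for the tabular inputs: protein quantification tables
# (FragPipe / Proteome-Discoverer style), UniProt-derived annotation tables
# with a compact topology micro-format, peptide coordinate tables, identifier
# maps and contaminant lists. All readers validate into the shared data model;
# all outputs are plain TSV/CSV with a fixed column order.

# Delimiter from extension only (.csv -> comma, everything else -> tab).
delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_quiet <- function(path, ...) {
  readr::read_delim(
    path,
    delim = delim_for(path),
    show_col_types = FALSE,
    progress = FALSE,
    na = c("", "NA"),
    ...
  )
}

#' Read a protein-level quantification table
#'
#' Reads a FragPipe-style protein table (TSV or CSV, delimiter chosen by file
#' extension) into a validated protein table. Sample intensity columns are
#' MaxLFQ-like linear-scale intensities; empty cells and zeros are treated as
#' missing (non-quantification), following the label-free convention that a
#' zero intensity means the protein was not quantified in that run. A
#' `detection_count` column (number of samples with a quantified value) is
#' computed for every row.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param sample_columns Character vector naming the intensity columns.
#' @param accession_col Name of the accession column (default `"accession"`).
#' @param gene_col Name of the gene-symbol column, or `NULL` if absent.
#' @param qvalue_col Optional name of an identification q-value column.
#' @param contaminant_col Optional name of a logical/0-1 contaminant flag
#'   column.
#'
#' @return A tibble of class `protein_table` with columns `accession`,
#'   `gene_symbol`, one column per sample, `detection_count`, and optionally
#'   `qvalue` and `contaminant`. The sample column names are stored in
#'   `attr(, "sample_columns")`.
#'
#' @details Duplicate accessions are a hard error (protein-level parsimony,
#'   e.g. "Master" protein selection, is assumed done upstream); the error
#'   names the offending accessions rather than silently collapsing rows.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\tgene_symbol\ts1\ts2",
#'              "P1\tGENE1\t1e6\t0",
#'              "P2\tGENE2\t\t2e6"), tf)
#' read_protein_table(tf, sample_columns = c("s1", "s2"))
#' @export
read_protein_table <- function(path, sample_columns,
                               accession_col = "accession",
                               gene_col = "gene_symbol",
                               qvalue_col = NULL,
                               contaminant_col = NULL) {
  raw <- read_delim_quiet(path)
  if (!accession_col %in% names(raw)) {
    abort(sprintf("protein table '%s' has no accession column '%s'",
                  path, accession_col), class = "shedscan_format_error")
  }
  missing_samples <- setdiff(sample_columns, names(raw))
  if (length(missing_samples) > 0) {
    abort(sprintf("sample column(s) not found in '%s': %s",
                  path, paste(missing_samples, collapse = ", ")),
          class = "shedscan_format_error")
  }
  as_protein_table(raw, sample_columns,
                   accession_col = accession_col, gene_col = gene_col,
                   qvalue_col = qvalue_col, contaminant_col = contaminant_col)
}

#' Build a protein table from an in-memory data frame
#'
#' Applies the same validation and conventions as [read_protein_table()]:
#' zeros and `NA` in sample columns become missing, detection counts are
#' (re)computed, duplicate accessions are an error.
#'
#' @inheritParams read_protein_table
#' @param x A data frame with an accession column and the named sample
#'   columns.
#' @return A `protein_table` tibble.
#' @export
as_protein_table <- function(x, sample_columns,
                             accession_col = "accession",
                             gene_col = "gene_symbol",
                             qvalue_col = NULL,
                             contaminant_col = NULL) {
  stopifnot(is.data.frame(x))
  if (anyDuplicated(sample_columns)) {
    abort("sample column names must be unique", class = "shedscan_format_error")
  }
  acc <- as.character(x[[accession_col]])
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate accession(s) in protein table: %s",
                  paste(dup, collapse = ", ")),
          class = "shedscan_validation_error")
  }
  out <- tibble::tibble(accession = acc)
  out$gene_symbol <- if (!is.null(gene_col) && gene_col %in% names(x)) {
    as.character(x[[gene_col]])
  } else {
    NA_character_
  }
  for (s in sample_columns) {
    v <- suppressWarnings(as.numeric(x[[s]]))
    v[!is.na(v) & v == 0] <- NA_real_
    if (any(!is.na(v) & v < 0)) {
      abort(sprintf("negative intensity in sample column '%s'", s),
            class = "shedscan_validation_error")
    }
    out[[s]] <- v
  }
  if (!is.null(qvalue_col) && qvalue_col %in% names(x)) {
    out$qvalue <- suppressWarnings(as.numeric(x[[qvalue_col]]))
  }
  if (!is.null(contaminant_col) && contaminant_col %in% names(x)) {
    out$contaminant <- as.logical(as.integer(x[[contaminant_col]]))
  }
  mat <- as.matrix(out[sample_columns])
  out$detection_count <- as.integer(rowSums(!is.na(mat)))
  structure(out,
            class = c("protein_table", class(out)),
            sample_columns = sample_columns)
}

#' Sample columns of a protein table
#' @param x A `protein_table`.
#' @return Character vector of sample column names.
#' @export
sample_columns <- function(x) {
  attr(x, "sample_columns")
}

# ---- topology micro-format ------------------------------------------------

#' Parse a compact topology string
#'
#' Topology segments are encoded as `"E:1-60;T:61-83;C:84-120"` with kinds
#' `E` (extracellular), `T` (transmembrane) and `C` (cytoplasmic) and 1-based
#' inclusive residue coordinates, the UniProt convention.
#'
#' @param topo A single topology string, or `NA`/`""` for no annotation.
#' @param seq_length Protein length in residues, used for range validation.
#' @param accession Accession used in error messages.
#' @return A tibble with columns `kind` (`"extracellular"`,
#'   `"transmembrane"`, `"cytoplasmic"`), `start`, `end`, sorted by `start`;
#'   zero rows when `topo` is empty.
#' @export
parse_topology <- function(topo, seq_length, accession = "?") {
  empty <- tibble::tibble(kind = character(), start = integer(),
                          end = integer())
  if (is.null(topo) || length(topo) == 0 || is.na(topo) || topo == "") {
    return(empty)
  }
  kinds <- c(E = "extracellular", T = "transmembrane", C = "cytoplasmic")
  parts <- strsplit(topo, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([ETC]):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    abort(sprintf("malformed topology segment '%s' for %s",
                  parts[bad][1], accession),
          class = "shedscan_validation_error")
  }
  seg <- tibble::tibble(
    kind = unname(kinds[vapply(m, `[`, "", 2)]),
    start = as.integer(vapply(m, `[`, "", 3)),
    end = as.integer(vapply(m, `[`, "", 4))
  )
  seg <- dplyr::arrange(seg, .data$start)
  validate_segments(seg, seq_length, accession)
  seg
}

validate_segments <- function(seg, seq_length, accession = "?") {
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(seg$start < 1L) || any(seg$end > seq_length) ||
      any(seg$start > seg$end)) {
    abort(sprintf(
      "topology segment out of range for %s (need 1 <= start <= end <= %d)",
      accession, seq_length), class = "shedscan_validation_error")
  }
  if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
    abort(sprintf("overlapping topology segments for %s", accession),
          class = "shedscan_validation_error")
  }
  invisible(seg)
}

format_topology <- function(seg) {
  if (is.null(seg) || nrow(seg) == 0) return(NA_character_)
  code <- c(extracellular = "E", transmembrane = "T", cytoplasmic = "C")
  paste(sprintf("%s:%d-%d", code[seg$kind], seg$start, seg$end),
        collapse = ";")
}

#' Read a UniProt-derived annotation table
#'
#' Expects a TSV/CSV with columns `accession`, `gene_symbol`, `seq_length`
#' (residues), `mol_weight` (kDa), `tm_count` (number of transmembrane
#' domains), `gpi_anchor` (0/1 or logical), optionally `entrez_id` and a
#' `topology` column in the compact micro-format of [parse_topology()].
#'
#' @param path Path to the annotation file.
#' @return A tibble of class `annotation_table` with one row per accession
#'   and a `topology` list-column of segment tibbles (zero-row tibbles when
#'   no topology is annotated).
#'
#' @details Validation enforces the per-record invariants: unique accessions,
#'   positive length and mass, non-overlapping in-range segments, and --
#'   when segments are present -- agreement between `tm_count` and the number
#'   of transmembrane segments. A GPI-anchored protein may legitimately have
#'   `tm_count = 0`.
#' @export
read_annotation_table <- function(path) {
  raw <- read_delim_quiet(path)
  as_annotation_table(raw)
}

#' Validate an in-memory annotation data frame
#' @param x Data frame with the columns described in
#'   [read_annotation_table()]; `topology` may already be a list-column of
#'   segment tibbles.
#' @return An `annotation_table` tibble.
#' @export
as_annotation_table <- function(x) {
  need <- c("accession", "seq_length", "mol_weight", "tm_count", "gpi_anchor")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("annotation table lacks column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "shedscan_format_error")
  }
  acc <- as.character(x$accession)
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate accession(s) in annotation table: %s",
                  paste(dup, collapse = ", ")),
          class = "shedscan_validation_error")
  }
  out <- tibble::tibble(
    accession = acc,
    gene_symbol = if ("gene_symbol" %in% names(x)) as.character(x$gene_symbol)
                  else NA_character_,
    entrez_id = if ("entrez_id" %in% names(x))
                  suppressWarnings(as.integer(x$entrez_id)) else NA_integer_,
    seq_length = as.integer(x$seq_length),
    mol_weight = as.numeric(x$mol_weight),
    tm_count = as.integer(x$tm_count),
    gpi_anchor = as.logical(as.integer(as.logical(x$gpi_anchor)))
  )
  if (any(is.na(out$seq_length)) || any(out$seq_length <= 0L)) {
    abort("seq_length must be a positive integer for every record",
          class = "shedscan_validation_error")
  }
  if (any(is.na(out$mol_weight)) || any(out$mol_weight <= 0)) {
    abort("mol_weight (kDa) must be positive for every record",
          class = "shedscan_validation_error")
  }
  if (any(is.na(out$tm_count)) || any(out$tm_count < 0L)) {
    abort("tm_count must be a non-negative integer",
          class = "shedscan_validation_error")
  }
  if ("topology" %in% names(x) && is.list(x$topology) &&
      !is.character(x$topology)) {
    out$topology <- purrr::pmap(
      list(x$topology, out$seq_length, out$accession),
      function(seg, len, a) {
        if (is.null(seg)) seg <- parse_topology(NA_character_, len, a)
        seg <- dplyr::arrange(tibble::as_tibble(seg), .data$start)
        validate_segments(seg, len, a)
        seg
      })
  } else {
    topo_str <- if ("topology" %in% names(x)) as.character(x$topology)
                else rep(NA_character_, nrow(out))
    out$topology <- purrr::pmap(
      list(topo_str, out$seq_length, out$accession), parse_topology)
  }
  n_tm_seg <- vapply(out$topology,
                     function(s) sum(s$kind == "transmembrane"), integer(1))
  has_topo <- vapply(out$topology, nrow, integer(1)) > 0
  bad_tm <- has_topo & n_tm_seg != out$tm_count
  if (any(bad_tm)) {
    abort(sprintf(
      "tm_count disagrees with transmembrane segments for: %s",
      paste(out$accession[bad_tm], collapse = ", ")),
      class = "shedscan_validation_error")
  }
  structure(out, class = c("annotation_table", class(out)))
}

#' Write an annotation table (topology re-encoded as the compact string)
#' @param x An `annotation_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(x, path) {
  flat <- dplyr::mutate(tibble::as_tibble(x),
    topology = vapply(.data$topology, format_topology, character(1)))
  readr::write_tsv(flat, path, na = "")
  invisible(path)
}

#' Read a peptide coordinate table
#'
#' TSV/CSV with columns `accession`, `start`, `end`: detected peptides as
#' 1-based inclusive residue intervals within the parent protein.
#'
#' @param path Path to the peptide file.
#' @return A tibble with `accession`, `start`, `end`.
#' @export
read_peptide_table <- function(path) {
  raw <- read_delim_quiet(path)
  need <- c("accession", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("peptide table lacks column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "shedscan_format_error")
  }
  out <- tibble::tibble(accession = as.character(raw$accession),
                        start = as.integer(raw$start),
                        end = as.integer(raw$end))
  if (any(out$start < 1L) || any(out$start > out$end)) {
    abort("peptide coordinates must satisfy 1 <= start <= end",
          class = "shedscan_validation_error")
  }
  out
}

#' Read an identifier map
#'
#' TSV/CSV with columns `accession`, `entrez_id`, `gene_symbol`. Keys must be
#' unique; several accessions may map to the same target (many-to-one).
#'
#' @param path Path to the map file.
#' @return A tibble of class `id_map`.
#' @export
read_id_map <- function(path) {
  raw <- read_delim_quiet(path)
  as_id_map(raw)
}

#' @rdname read_id_map
#' @param x Data frame with `accession` and at least one of `entrez_id`,
#'   `gene_symbol`.
#' @export
as_id_map <- function(x) {
  if (!"accession" %in% names(x)) {
    abort("id map lacks an accession column", class = "shedscan_format_error")
  }
  acc <- as.character(x$accession)
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate key(s) in id map: %s",
                  paste(dup, collapse = ", ")),
          class = "shedscan_validation_error")
  }
  out <- tibble::tibble(
    accession = acc,
    entrez_id = if ("entrez_id" %in% names(x))
                  suppressWarnings(as.integer(x$entrez_id)) else NA_integer_,
    gene_symbol = if ("gene_symbol" %in% names(x))
                    as.character(x$gene_symbol) else NA_character_)
  structure(out, class = c("id_map", class(out)))
}

#' Translate accessions through an identifier map
#'
#' Protein accessions are translated to Entrez IDs (or gene symbols) to avoid
#' nomenclature discrepancies when intersecting lists from different sources.
#' Because the map may be many-to-one, translated output is deduplicated; the
#' report records how many input identifiers merged onto a shared target.
#'
#' @param accessions Character vector of accessions to translate.
#' @param idmap An `id_map` (see [read_id_map()]).
#' @param policy `"drop"` (default) removes unmapped accessions from the
#'   output; `"keep"` passes them through untranslated.
#' @param to Target namespace: `"entrez_id"` or `"gene_symbol"`.
#' @param strip_isoform_suffix Strip a trailing `-<digits>` isoform suffix
#'   (e.g. `"P12345-2"` -> `"P12345"`) before lookup. Off by default; how
#'   isoforms should be collapsed is dataset-dependent.
#'
#' @return A list with `mapped` (translated, deduplicated, input order of
#'   first occurrence), `unmapped` (accessions without a map entry) and
#'   `n_merged` (inputs lost to many-to-one deduplication).
#' @export
map_identifiers <- function(accessions, idmap,
                            policy = c("drop", "keep"),
                            to = c("entrez_id", "gene_symbol"),
                            strip_isoform_suffix = FALSE) {
  policy <- match.arg(policy)
  to <- match.arg(to)
  accessions <- as.character(accessions)
  keys <- accessions
  if (strip_isoform_suffix) keys <- sub("-[0-9]+$", "", keys)
  idx <- match(keys, idmap$accession)
  target <- idmap[[to]][idx]
  mapped_ok <- !is.na(idx) & !is.na(target)
  unmapped <- accessions[!mapped_ok]
  vals <- if (to == "entrez_id") as.character(target[mapped_ok])
          else target[mapped_ok]
  if (policy == "keep") vals <- c(vals, unmapped)
  mapped <- vals[!duplicated(vals)]
  if (to == "entrez_id" && policy == "drop") {
    mapped_out <- as.integer(mapped)
  } else {
    mapped_out <- mapped
  }
  list(mapped = mapped_out,
       unmapped = unmapped,
       n_merged = length(vals) - length(mapped))
}

#' Read a one-column list of contaminant accessions
#' @param path Text file, one accession per line (a header line named
#'   `accession` is tolerated).
#' @return Character vector of accessions.
#' @export
read_contaminant_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[x != "" & x != "accession"]
  unique(x)
}

#' Write a protein table to TSV
#'
#' Missing intensities are written as empty cells so that a re-read through
#' [read_protein_table()] reproduces values, missingness pattern and row
#' order exactly.
#'
#' @param x A `protein_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}
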