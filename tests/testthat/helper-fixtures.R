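# Small fixtures built in code: tiny TSVs and annotation sets reused across
# test files.

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Three-segment type-I protein used throughout the topology tests.
type1_annotation <- function(accession = "P1") {
  as_annotation_table(tibble::tibble(
    accession = accession,
    gene_symbol = "G1",
    seq_length = 120L,
    mol_weight = 13.2,
    tm_count = 1L,
    gpi_anchor = FALSE,
    topology = "E:1-60;T:61-83;C:84-120"))
}

# Five-protein table with a 2-protein membrane-anchored subset.
tiny_annotations <- function() {
  as_annotation_table(tibble::tibble(
    accession = paste0("P", 1:5),
    gene_symbol = paste0("G", 1:5),
    seq_length = c(120L, 400L, 300L, 500L, 200L),
    mol_weight = c(13.2, 44, 33, 55, 22),
    tm_count = c(1L, 0L, 0L, 3L, 0L),
    gpi_anchor = c(FALSE, TRUE, FALSE, FALSE, FALSE)))
}

tiny_protein_table <- function(samples = c("s1", "s2", "s3", "s4")) {
  vals <- matrix(2^runif(5 * length(samples), 20, 26), nrow = 5,
                 dimnames = list(NULL, samples))
  df <- tibble::tibble(accession = paste0("P", 1:5),
                       gene_symbol = paste0("G", 1:5))
  df <- dplyr::bind_cols(df, tibble::as_tibble(vals))
  as_protein_table(df, sample_columns = samples)
}

# Complete two-group intensity_matrix built directly from a log2 matrix.
make_intensity_matrix <- function(m, n1 = NULL) {
  n1 <- n1 %||% (ncol(m) / 2)
  gf <- factor(rep(c("g1", "g2"), c(n1, ncol(m) - n1)),
               levels = c("g1", "g2"))
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  structure(list(log2 = m, groups = gf,
                 mask = matrix(FALSE, nrow(m), ncol(m),
                               dimnames = dimnames(m)),
                 dropped = c(contaminant = 0L, inconsistent = 0L)),
            class = "intensity_matrix")
}

`%||%` <- rlang::`%||%`
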