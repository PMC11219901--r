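# Peptide-topology evidence: classify detected peptides against annotated
# membrane topology and flag proteins whose peptide evidence is confined to
# the extracellular (shed) portion -- the signature expected of a released
# ectodomain rather than a contaminating full-length protein.

# Effective topology for classification: GPI-anchored proteins without
# transmembrane segments expose their entire chain extracellularly.
effective_segments <- function(segments, seq_length, gpi_anchor) {
  has_segs <- !is.null(segments) && nrow(segments) > 0
  if (!has_segs && isTRUE(gpi_anchor)) {
    return(tibble::tibble(kind = "extracellular", start = 1L,
                          end = as.integer(seq_length)))
  }
  if (!has_segs) return(NULL)
  segments
}

classify_interval <- function(start, end, segments) {
  if (is.null(segments) || nrow(segments) == 0) return("ambiguous")
  hit <- segments$start <= end & segments$end >= start
  if (any(hit & segments$kind == "transmembrane")) return("tm_overlapping")
  # fully covered by segments of one non-TM kind?
  for (kind in c("extracellular", "cytoplasmic")) {
    segs <- segments[segments$kind == kind, , drop = FALSE]
    if (nrow(segs) == 0) next
    covered <- 0L
    for (i in seq_len(nrow(segs))) {
      a <- max(start, segs$start[i]); b <- min(end, segs$end[i])
      if (a <= b) covered <- covered + (b - a + 1L)
    }
    if (covered == end - start + 1L) {
      return(if (kind == "extracellular") "extracellular" else "intracellular")
    }
  }
  "ambiguous"
}

#' Classify detected peptides against membrane topology
#'
#' Each peptide interval is assigned one of four classes: `extracellular`
#' (entirely within extracellular segments), `intracellular` (entirely
#' within cytoplasmic segments), `tm_overlapping` (intersects any
#' transmembrane segment), or `ambiguous` (spans unannotated residues such
#' as signal peptides or linkers, or mixes non-TM kinds). Coordinates are
#' 1-based inclusive, the UniProt convention. GPI-anchored proteins with no
#' transmembrane segments are treated as entirely extracellular.
#'
#' @param peptides A data frame with `accession`, `start`, `end` (see
#'   [read_peptide_table()]).
#' @param annotations An `annotation_table` covering the peptides'
#'   accessions.
#' @return The peptide tibble with an added `class` column.
#' @export
classify_peptides <- function(peptides, annotations) {
  peptides <- tibble::as_tibble(peptides)
  idx <- match(peptides$accession, annotations$accession)
  if (anyNA(idx)) {
    abort(sprintf("peptide accession(s) missing from annotations: %s",
                  paste(unique(peptides$accession[is.na(idx)]), collapse = ", ")),
          class = "shedscan_domain_error")
  }
  len <- annotations$seq_length[idx]
  if (any(peptides$start < 1L) || any(peptides$end > len)) {
    bad <- unique(peptides$accession[peptides$start < 1L | peptides$end > len])
    abort(sprintf("peptide coordinates out of [1, seq_length] for: %s",
                  paste(bad, collapse = ", ")),
          class = "shedscan_domain_error")
  }
  peptides$class <- vapply(seq_len(nrow(peptides)), function(i) {
    j <- idx[i]
    segs <- effective_segments(annotations$topology[[j]],
                               annotations$seq_length[j],
                               annotations$gpi_anchor[j])
    classify_interval(peptides$start[i], peptides$end[i], segs)
  }, character(1))
  peptides
}

#' Summarise peptide evidence per protein into an ectodomain verdict
#'
#' Aggregates peptide classes into one verdict per protein:
#' `ectodomain_only` when at least one peptide was detected and every
#' peptide is extracellular (the pattern expected of a shed ectodomain);
#' `mixed` when any peptide touches a transmembrane or cytoplasmic segment
#' or is ambiguous; `no_topology` when the protein carries no usable
#' topology annotation; `no_peptides` when no peptides were detected.
#' The ambiguous class disqualifies `ectodomain_only` deliberately -- a
#' conservative evidence standard.
#'
#' @param peptides Data frame of detected peptides (`accession`, `start`,
#'   `end`); may cover many proteins.
#' @param annotations An `annotation_table`; every annotation row yields one
#'   verdict (proteins without peptides get `no_peptides`).
#' @return A tibble with one row per annotation accession: `accession`,
#'   `n_peptides`, `n_extracellular`, `n_tm_overlapping`, `n_intracellular`,
#'   `n_ambiguous`, `verdict`.
#' @export
protein_evidence <- function(peptides, annotations) {
  has_topo <- vapply(seq_len(nrow(annotations)), function(j) {
    !is.null(effective_segments(annotations$topology[[j]],
                                annotations$seq_length[j],
                                annotations$gpi_anchor[j]))
  }, logical(1))

  calls <- if (nrow(peptides) > 0) {
    classify_peptides(peptides, annotations)
  } else {
    tibble::tibble(accession = character(), start = integer(),
                   end = integer(), class = character())
  }
  counts <- calls |>
    dplyr::count(.data$accession, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("extracellular", "tm_overlapping", "intracellular",
               "ambiguous")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  out <- tibble::tibble(accession = annotations$accession,
                        has_topology = has_topo) |>
    dplyr::left_join(counts, by = "accession") |>
    dplyr::mutate(dplyr::across(
      c("extracellular", "tm_overlapping", "intracellular", "ambiguous"),
      ~ tidyr::replace_na(.x, 0L)))
  out$n_peptides <- out$extracellular + out$tm_overlapping +
    out$intracellular + out$ambiguous
  out$verdict <- dplyr::case_when(
    !out$has_topology ~ "no_topology",
    out$n_peptides == 0L ~ "no_peptides",
    out$tm_overlapping == 0L & out$intracellular == 0L &
      out$ambiguous == 0L ~ "ectodomain_only",
    TRUE ~ "mixed")
  tibble::tibble(accession = out$accession,
                 n_peptides = as.integer(out$n_peptides),
                 n_extracellular = as.integer(out$extracellular),
                 n_tm_overlapping = as.integer(out$tm_overlapping),
                 n_intracellular = as.integer(out$intracellular),
                 n_ambiguous = as.integer(out$ambiguous),
                 verdict = out$verdict)
}
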