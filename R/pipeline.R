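# End-to-end orchestration: simulate (or read) inputs, extract sheddomes,
# overlap them, run the differential-abundance stage and the topology
# evidence, and write stage TSVs plus a machine-readable JSON summary
# holding the count arithmetic (sheddome sizes, percent changes, significant
# fractions).

#' Percent reduction between two set sizes
#'
#' The arithmetic behind statements like "the 2 h sheddome was 24% smaller
#' than the 1 h sheddome": `100 * (from - to) / from`.
#'
#' @param from Reference size.
#' @param to Compared size.
#' @return Percent reduction at full precision (negative for an increase).
#' @examples
#' percent_reduction(84, 64)  # 23.81, rendered "24%" at integer precision
#' @export
percent_reduction <- function(from, to) {
  stopifnot(from > 0)
  100 * (from - to) / from
}

#' Percent of significant proteins
#'
#' @param n_significant Number of significant proteins.
#' @param n_tested Number of proteins tested.
#' @return `100 * n_significant / n_tested` at full precision.
#' @examples
#' fraction_significant(7, 169)  # 4.142, rendered "4.1%" at one decimal
#' @export
fraction_significant <- function(n_significant, n_tested) {
  if (n_tested == 0) return(0)
  100 * n_significant / n_tested
}

#' Render a percentage the way the report prints it
#' @param x Percentage at full precision.
#' @param digits Decimal places (0 for size changes, 1 for fractions).
#' @return Character like `"24%"` or `"4.1%"`.
#' @export
format_percent <- function(x, digits = 0) {
  paste0(formatC(round(x, digits), format = "f", digits = digits), "%")
}

#' Run the sheddome pipeline end to end
#'
#' Executes the stages in order -- obtain inputs (simulated from a
#' [sim_config()] or read from files), extract the per-condition sheddomes,
#' compute Venn counts and the hypergeometric overlap between conditions,
#' run preprocessing / MNAR imputation / moderated t-testing, classify
#' peptide topology evidence -- writing each stage's TSV under `out_dir`
#' and a JSON summary of every headline number. Re-running with the same
#' config reproduces every output byte for byte.
#'
#' @param config Either a list, a `sim_config`, or the path of a YAML file.
#'   Recognised fields: `simulate` (list of [sim_config()] arguments) or the
#'   input paths `proteins`, `annotations`, `peptides`, `groups` (TSVs, plus
#'   `sample_columns` for the protein table), optional `contaminants`;
#'   `filters` (`mw_min`, `min_occurrence`); `stats` (`alpha`,
#'   `impute_shift`, `impute_width`); `seed`; `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`; default a
#'   temporary directory).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% tempfile("shedscan_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  filters <- config$filters %||% list()
  statpar <- config$stats %||% list()
  alpha <- statpar$alpha %||% 0.05
  log_line <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  # ---- inputs ------------------------------------------------------------
  if (!is.null(config$simulate) || inherits(config, "sim_config")) {
    sim_args <- if (inherits(config, "sim_config")) unclass(config)
                else config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    uni <- generate_universe(cfg)
    exp <- generate_experiment(uni, cfg)
    peptides <- generate_peptides(uni, cfg)
    annotations <- uni$annotations
    proteins <- exp$proteins
    groups <- exp$groups
    contaminants <- character()
    write_annotation_table(annotations, file.path(out_dir, "annotations.tsv"))
    write_protein_table(proteins, file.path(out_dir, "proteins.tsv"))
    readr::write_tsv(groups, file.path(out_dir, "groups.tsv"))
    readr::write_tsv(peptides, file.path(out_dir, "peptides.tsv"))
    readr::write_tsv(uni$truth, file.path(out_dir, "ground_truth.tsv"))
    log_line("simulate", "universe of %d proteins, %d samples",
             cfg$n_proteins, nrow(groups))
  } else {
    if (is.null(config$proteins) || is.null(config$annotations)) {
      abort("config must provide either `simulate` or `proteins` + `annotations`",
            class = "shedscan_config_error")
    }
    annotations <- read_annotation_table(config$annotations)
    groups <- if (!is.null(config$groups)) {
      readr::read_tsv(config$groups, show_col_types = FALSE)
    } else NULL
    sample_cols <- config$sample_columns %||% groups$sample
    proteins <- read_protein_table(config$proteins, sample_cols)
    peptides <- if (!is.null(config$peptides)) {
      read_peptide_table(config$peptides)
    } else NULL
    contaminants <- if (!is.null(config$contaminants)) {
      read_contaminant_list(config$contaminants)
    } else character()
    log_line("read", "%d proteins, %d annotation records",
             nrow(proteins), nrow(annotations))
  }

  summary <- list(seed = seed, n_proteins_input = nrow(proteins),
                  n_samples = length(sample_columns(proteins)))

  # ---- sheddome extraction per condition ---------------------------------
  mw_min <- filters$mw_min
  min_occ <- filters$min_occurrence
  shed_by_group <- list()
  if (!is.null(groups)) {
    for (gname in unique(groups$group)) {
      gsamples <- groups$sample[groups$group == gname]
      # condition sheddome: anchored proteins detected in that condition
      # (>= min_occurrence of its replicates; at least once by default)
      sd_set <- extract_sheddome(proteins, annotations, mw_min = mw_min,
                                 min_occurrence = min_occ %||% 1L,
                                 occurrence_samples = gsamples)
      shed_by_group[[gname]] <- sd_set
      readr::write_tsv(tibble::as_tibble(sd_set),
                       file.path(out_dir, paste0("sheddome_", gname, ".tsv")))
      log_line("filter", "sheddome[%s]: %d of %d proteins", gname,
               nrow(sd_set), nrow(proteins))
    }
  }
  full_sheddome <- extract_sheddome(proteins, annotations, mw_min = mw_min,
                                    min_occurrence = min_occ)
  readr::write_tsv(tibble::as_tibble(full_sheddome),
                   file.path(out_dir, "sheddome.tsv"))
  summary$sheddome_sizes <- c(
    list(all = nrow(full_sheddome)),
    lapply(shed_by_group, nrow))
  summary$n_unannotated <- provenance(full_sheddome)$n_unannotated

  # ---- overlap between condition sheddomes -------------------------------
  if (length(shed_by_group) == 2) {
    sets <- lapply(shed_by_group, function(s) s$accession)
    vc <- venn_counts(sets)
    readr::write_tsv(vc, file.path(out_dir, "venn_counts.tsv"))
    anchored_universe <- annotations$accession[
      classify_membrane_anchored(annotations)]
    ov <- hypergeometric_overlap_test(
      N = length(anchored_universe),
      n1 = length(sets[[1]]), n2 = length(sets[[2]]),
      k = length(intersect(sets[[1]], sets[[2]])))
    readr::write_tsv(tibble::as_tibble(ov),
                     file.path(out_dir, "overlap_test.tsv"))
    sz <- vapply(sets, length, integer(1))
    summary$venn <- setNames(vc$count, vc$region)
    summary$overlap <- as.list(tibble::as_tibble(ov))
    if (sz[1] > 0) {
      summary$percent_change_sheddome_size <-
        percent_reduction(unname(sz[1]), unname(sz[2]))
      summary$percent_change_sheddome_size_rendered <-
        format_percent(summary$percent_change_sheddome_size, 0)
    }
    log_line("overlap", "k=%d of n1=%d, n2=%d (p=%.3g)", ov$k, ov$n1, ov$n2,
             ov$p_hyper)
  }

  # ---- differential abundance on the sheddome ----------------------------
  if (!is.null(groups) && nrow(full_sheddome) > 0) {
    shed_accs <- union(full_sheddome$accession,
                       unlist(lapply(shed_by_group,
                                     function(s) s$accession)))
    sub <- proteins[proteins$accession %in% shed_accs, ]
    sub <- as_protein_table(sub, sample_columns(proteins))
    im <- preprocess(sub, groups, contaminants = contaminants)
    n_tested <- nrow(im$log2)
    if (n_tested >= 2) {
      im <- impute_mnar(im,
                        shift = statpar$impute_shift %||% 1.8,
                        width = statpar$impute_width %||% 0.3,
                        seed = seed + 10L)
      res <- moderated_t_test(im)
      vt <- volcano_table(res, alpha = alpha)
      readr::write_tsv(tibble::as_tibble(vt),
                       file.path(out_dir, "differential_abundance.tsv"))
      vs <- attr(vt, "summary")
      summary$diff <- list(
        n_tested = vs$n_tested,
        n_significant = vs$n_significant,
        n_up = vs$n_up, n_down = vs$n_down,
        percent_significant = vs$percent_significant,
        percent_significant_rendered =
          format_percent(vs$percent_significant, 1),
        alpha = alpha, d0 = attr(res, "d0"), s0sq = attr(res, "s0sq"),
        dropped = as.list(im$dropped))
      log_line("diff", "%d tested, %d significant (%s)", vs$n_tested,
               vs$n_significant, summary$diff$percent_significant_rendered)
    } else {
      summary$diff <- list(n_tested = n_tested, n_significant = 0L,
                           percent_significant = 0,
                           percent_significant_rendered = "0.0%")
    }
  } else {
    summary$diff <- list(n_tested = 0L, n_significant = 0L,
                         percent_significant = 0,
                         percent_significant_rendered = "0.0%")
  }

  # ---- topology evidence -------------------------------------------------
  if (!is.null(peptides)) {
    ev <- protein_evidence(peptides, annotations)
    readr::write_tsv(ev, file.path(out_dir, "topology_evidence.tsv"))
    summary$topology_verdicts <- as.list(table(ev$verdict))
    log_line("topology", "%d proteins with peptide evidence",
             sum(ev$n_peptides > 0))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
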