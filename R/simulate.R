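# Synthetic-data generator: annotation universes with a membrane-anchored
# subset, two-group label-free experiments with shedding effects and
# intensity-dependent (left-censored) dropout, and peptide maps restricted
# to extracellular regions for shed proteins. Every generated dataset comes
# with its ground truth, so the full pipeline can be validated end to end.

#' Simulation configuration
#'
#' Bundles every knob of the generator with defaults emulating a two-group
#' metalloprotease-inhibition experiment on brain soluble fractions:
#' four biological replicates per group, a universe with a membrane-anchored
#' subset, a minority of true sheddase substrates decreased by the inhibitor
#' (log2 fold change -1), replicate noise of 0.3 log2 units, and logistic
#' intensity-dependent detection producing left-censored missingness.
#'
#' @param n_proteins Universe size (default 500).
#' @param fraction_membrane_anchored Fraction of the universe with >= 1
#'   transmembrane domain or a GPI anchor (default 0.4, giving ~200 membrane
#'   proteins at the default universe size).
#' @param fraction_gpi_among_anchored Fraction of anchored proteins that are
#'   GPI-anchored with no transmembrane domain (default 0.15).
#' @param tm_mean Mean of the truncated-at-1 Poisson for transmembrane-domain
#'   counts of non-GPI anchored proteins (default 1.6).
#' @param length_meanlog,length_sdlog Log-normal parameters for protein
#'   length in residues (defaults 6.1 and 0.4, median ~450 aa).
#' @param min_length Minimum protein length (default 120, so that a type-I
#'   topology with a >= 40-residue ectodomain always fits).
#' @param n_per_group Replicates per group (default 4, as in an n = 4 mice
#'   per condition design).
#' @param baseline_mean,baseline_sd Mean and s.d. of per-protein baseline
#'   log2 intensity (defaults 25 and 2).
#' @param noise_sd Replicate noise s.d. in log2 units (default 0.3).
#' @param substrate_fraction Fraction of anchored proteins that are true
#'   substrates of the inhibited proteases (default 0.10).
#' @param substrate_log2fc True log2 fold change (treated minus vehicle) on
#'   substrates (default -1: shedding halved by the inhibitor).
#' @param shed_fraction Fraction of topology-bearing anchored proteins whose
#'   soluble-fraction peptides derive from a released ectodomain
#'   (default 0.6).
#' @param dropout Logical: apply intensity-dependent detection
#'   (default TRUE).
#' @param dropout_midpoint,dropout_slope Midpoint `c` and slope `s` of the
#'   logistic detection model `P(detect) = 1/(1+exp(-(y-c)/s))` on the log2
#'   scale (defaults 21.5 and 0.5: detection is near-certain two s.d. above
#'   the censoring zone and unlikely well below it).
#' @param peptides_per_protein Maximum number of detected peptides emitted
#'   per protein (default 6).
#' @param seed Integer seed fixing every draw (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500,
                       fraction_membrane_anchored = 0.4,
                       fraction_gpi_among_anchored = 0.15,
                       tm_mean = 1.6,
                       length_meanlog = 6.1,
                       length_sdlog = 0.4,
                       min_length = 120,
                       n_per_group = 4,
                       baseline_mean = 25,
                       baseline_sd = 2,
                       noise_sd = 0.3,
                       substrate_fraction = 0.10,
                       substrate_log2fc = -1,
                       shed_fraction = 0.6,
                       dropout = TRUE,
                       dropout_midpoint = 21.5,
                       dropout_slope = 0.5,
                       peptides_per_protein = 6,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_proteins >= 1, cfg$n_per_group >= 2,
            cfg$fraction_membrane_anchored >= 0,
            cfg$fraction_membrane_anchored <= 1,
            cfg$fraction_gpi_among_anchored >= 0,
            cfg$fraction_gpi_among_anchored <= 1,
            cfg$substrate_fraction >= 0, cfg$substrate_fraction <= 1,
            cfg$shed_fraction >= 0, cfg$shed_fraction <= 1)
  structure(cfg, class = "sim_config")
}

# Poisson truncated at >= 1 by rejection.
rpois_trunc1 <- function(n, lambda) {
  out <- rpois(n, lambda)
  while (any(out == 0L)) {
    z <- out == 0L
    out[z] <- rpois(sum(z), lambda)
  }
  out
}

# Type-I single-pass topology: N-terminal ectodomain, 21-residue TM,
# cytoplasmic tail.
make_type1_topology <- function(len, ctail) {
  tm_len <- 21L
  t_start <- len - ctail - tm_len + 1L
  tibble::tibble(kind = c("extracellular", "transmembrane", "cytoplasmic"),
                 start = c(1L, t_start, t_start + tm_len),
                 end = c(t_start - 1L, t_start + tm_len - 1L, len))
}

#' Generate a synthetic annotation universe with ground truth
#'
#' Draws a protein universe in which a configurable fraction is
#' membrane-anchored (transmembrane and/or GPI), synthesises type-I
#' topology (extracellular / transmembrane / cytoplasmic segments, ectodomain
#' N-terminal) for single-TM proteins, assigns molecular weight as
#' 0.110 kDa per residue, and marks ground-truth substrate and shed flags
#' (both subsets of the anchored proteins).
#'
#' @param config A [sim_config()].
#' @return A list with `annotations` (an `annotation_table`) and `truth`
#'   (tibble: `accession`, `anchored`, `substrate`, `shed`, `true_log2fc`).
#' @export
generate_universe <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_proteins
  acc <- sprintf("SIM%04d", seq_len(n))
  anchored <- rbinom(n, 1, config$fraction_membrane_anchored) == 1
  gpi <- anchored & rbinom(n, 1, config$fraction_gpi_among_anchored) == 1
  tm <- integer(n)
  n_tm_prot <- sum(anchored & !gpi)
  tm[anchored & !gpi] <- rpois_trunc1(n_tm_prot, config$tm_mean)

  len <- pmax(config$min_length,
              as.integer(round(rlnorm(n, config$length_meanlog,
                                      config$length_sdlog))))
  ctail <- sample(10:60, n, replace = TRUE)
  ctail <- pmin(ctail, len - 21L - 40L)  # keep ectodomain >= 40 residues

  topology <- vector("list", n)
  for (i in seq_len(n)) {
    topology[[i]] <- if (tm[i] == 1L) make_type1_topology(len[i], ctail[i])
                     else parse_topology(NA_character_, len[i])
  }

  has_ecto <- tm == 1L | gpi  # topology usable for ectodomain evidence
  shed <- has_ecto & runif(n) < config$shed_fraction

  idx_anchored <- which(anchored)
  n_sub <- round(config$substrate_fraction * length(idx_anchored))
  substrate <- logical(n)
  if (n_sub > 0) {
    substrate[sample(idx_anchored, n_sub)] <- TRUE
  }

  ann <- as_annotation_table(tibble::tibble(
    accession = acc,
    gene_symbol = sprintf("GENE%04d", seq_len(n)),
    entrez_id = 100000L + seq_len(n),
    seq_length = len,
    mol_weight = 0.110 * len,
    tm_count = tm,
    gpi_anchor = gpi,
    topology = topology))
  truth <- tibble::tibble(
    accession = acc,
    anchored = anchored,
    substrate = substrate,
    shed = shed,
    true_log2fc = ifelse(substrate, config$substrate_log2fc, 0))
  list(annotations = ann, truth = truth)
}

#' Generate a two-group label-free experiment
#'
#' Simulates replicate log2 intensities as baseline + group effect (the
#' substrate fold change in the treated group) + Gaussian replicate noise,
#' then applies the logistic intensity-dependent detection model so that
#' low-abundance measurements are preferentially missing (the MNAR
#' left-censoring mechanism). Intensities are exported on the linear scale,
#' with missing cells empty, exactly as a label-free quantification table
#' would arrive.
#'
#' @param universe Output of [generate_universe()].
#' @param config The same [sim_config()].
#' @return A list with `proteins` (a `protein_table`), `groups` (tibble
#'   `sample`, `group` with levels `vehicle`, `treated`), `truth` (as in the
#'   universe) and `true_log2` (the uncensored log2 matrix, for
#'   missingness diagnostics).
#' @export
generate_experiment <- function(universe, config = sim_config()) {
  set.seed(config$seed + 1000L)
  truth <- universe$truth
  n <- nrow(truth)
  n_rep <- config$n_per_group
  samples <- c(sprintf("vehicle_%d", seq_len(n_rep)),
               sprintf("treated_%d", seq_len(n_rep)))
  group <- rep(c("vehicle", "treated"), each = n_rep)

  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  effect <- outer(truth$true_log2fc, as.integer(group == "treated"))
  y <- baseline + effect +
    matrix(rnorm(n * length(samples), 0, config$noise_sd), n)
  colnames(y) <- samples

  if (isTRUE(config$dropout)) {
    pdet <- plogis((y - config$dropout_midpoint) / config$dropout_slope)
    detected <- matrix(runif(length(y)) < pdet, nrow = n)
  } else {
    detected <- matrix(TRUE, n, length(samples))
  }
  lin <- 2^y
  lin[!detected] <- NA_real_

  tab <- tibble::as_tibble(lin)
  tab <- dplyr::bind_cols(
    tibble::tibble(accession = truth$accession,
                   gene_symbol = universe$annotations$gene_symbol), tab)
  proteins <- as_protein_table(tab, sample_columns = samples)
  list(proteins = proteins,
       groups = tibble::tibble(
         sample = samples,
         group = factor(group, levels = c("vehicle", "treated"))),
       truth = truth,
       true_log2 = y)
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every lysine (K) or arginine (R) not
#' followed by proline (P) -- the Keil rule -- and returns the fragments
#' within the given length bounds, with their 1-based inclusive coordinates.
#'
#' @param sequence Amino-acid sequence (single string, one-letter codes).
#' @param min_length,max_length Peptide length bounds (defaults 7 and 30,
#'   the range typically observed by LC-MS/MS).
#' @return A tibble with `start`, `end`, `peptide`.
#' @examples
#' digest_tryptic("AAAKAAARAAAA", min_length = 1)
#' @export
digest_tryptic <- function(sequence, min_length = 7, max_length = 30) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          peptide = character()))
  }
  is_kr <- chars %in% c("K", "R")
  next_p <- c(chars[-1] == "P", FALSE)
  sites <- which(is_kr & !next_p & seq_len(L) < L)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, L)
  lens <- ends - starts + 1L
  keep <- lens >= min_length & lens <= max_length
  tibble::tibble(
    start = starts[keep], end = ends[keep],
    peptide = vapply(which(keep), function(i) {
      paste(chars[starts[i]:ends[i]], collapse = "")
    }, character(1)))
}

# Random sequence built from tryptic blocks: stretches of non-K/R residues
# (never starting with P, so the Keil rule never suppresses a cut) each
# terminated by K or R. All internal tryptic fragments fall in [7, 30].
random_tryptic_sequence <- function(len) {
  aa <- setdiff(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]], character(0))
  aa_nop <- setdiff(aa, "P")
  out <- character(0)
  while (length(out) < len) {
    blk_len <- sample(6:29, 1)
    blk <- c(sample(aa_nop, 1),
             sample(aa, blk_len - 1, replace = TRUE),
             sample(c("K", "R"), 1))
    out <- c(out, blk)
  }
  paste(out[seq_len(len)], collapse = "")
}

#' Generate detected peptides consistent with shedding ground truth
#'
#' Synthesises a random tryptic-friendly sequence per membrane-anchored
#' protein, digests it in silico, and emits up to `peptides_per_protein`
#' detected peptides. For shed proteins only peptides lying entirely within
#' extracellular segments are eligible (only the released ectodomain is
#' present in the soluble fraction); for non-shed membrane proteins peptides
#' are sampled from the whole chain.
#'
#' @param universe Output of [generate_universe()].
#' @param config The same [sim_config()].
#' @return A tibble with `accession`, `start`, `end`.
#' @export
generate_peptides <- function(universe, config = sim_config()) {
  set.seed(config$seed + 2000L)
  ann <- universe$annotations
  truth <- universe$truth
  rows <- purrr::map_dfr(which(truth$anchored), function(i) {
    len <- ann$seq_length[i]
    seqc <- random_tryptic_sequence(len)
    peps <- digest_tryptic(seqc)
    if (truth$shed[i]) {
      segs <- effective_segments(ann$topology[[i]], len, ann$gpi_anchor[i])
      ecto <- segs[segs$kind == "extracellular", , drop = FALSE]
      ok <- vapply(seq_len(nrow(peps)), function(r) {
        any(ecto$start <= peps$start[r] & ecto$end >= peps$end[r])
      }, logical(1))
      peps <- peps[ok, , drop = FALSE]
    }
    if (nrow(peps) == 0) return(NULL)
    take <- sample(nrow(peps), min(nrow(peps), config$peptides_per_protein))
    tibble::tibble(accession = ann$accession[i],
                   start = peps$start[take], end = peps$end[take])
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(accession = character(), start = integer(),
                          end = integer()))
  }
  dplyr::arrange(rows, .data$accession, .data$start)
}
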