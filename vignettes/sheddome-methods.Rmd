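---
title: "Models and methods behind shedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shedscan)
```

`shedscan` analyses the *soluble-fraction sheddome*: the set of
membrane-anchored proteins detected in a detergent-free tissue supernatant,
which — having no business being soluble as full-length molecules — are
candidate products of ectodomain shedding. This vignette explains the
models the package implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where more than one convention was defensible.

## The sheddome definition

A protein is *membrane-anchored* when its annotation records at least one
transmembrane domain or a GPI anchor (`classify_membrane_anchored()`).
`extract_sheddome()` intersects an identified proteome with that subset and
applies two optional rules:

* **Molecular weight.** Small proteins dominate soluble fractions for
  reasons unrelated to shedding, so a cutoff (typically 40 kDa) focuses the
  set on adhesion molecules and receptors. The boundary is *inclusive*:
  "below 40 kDa" is excluded, a protein at exactly 40.0 kDa is kept.
  Weight is taken from the annotation table (the UniProt-reported mass),
  never recomputed from sequence, so the filter reproduces what an analyst
  reading UniProt would do.
* **Occurrence.** Requiring detection in at least `min_occurrence`
  replicates (2 of 4 is typical) suppresses one-hit identifications.
  Occurrence can be counted over all samples or over the replicates of one
  condition (`occurrence_samples`), which is what a per-condition sheddome
  needs.

Accessions with no annotation record are treated as *not* anchored — the
conservative choice, keeping the sheddome a strict subset of annotated
anchored proteins — and their count is reported in the provenance rather
than silently dropped. The three filters commute, and raising either
threshold can only shrink the set; both properties are tested on random
fixtures.

`merge_fractions()` pools the per-fraction tables of a gel-separated sample.
Intensities for a sample shared between fractions are summed (total signal
across gel slices, on the linear scale); detection counts are recomputed
over the union of samples.

## Overlap statistics

Two sheddomes of sizes $n_1$ and $n_2$ drawn from a universe of $N$
membrane-anchored proteins share $k$ members. Under uniform random
sampling the overlap is hypergeometric, and the one-sided p-value is

$$p = \sum_{i=k}^{\min(n_1,n_2)}
      \frac{\binom{n_2}{i}\binom{N-n_2}{n_1-i}}{\binom{N}{n_1}},$$

with expectation $n_1 n_2/N$ and fold enrichment $k/(n_1 n_2 / N)$.
The universe defaults to the membrane-anchored annotation list — the set
from which a sheddome could possibly have been drawn — and is overridable.
`monte_carlo_overlap()` re-draws the first set uniformly from the universe
`reps` times and reports the permutation-convention p-value
$(1 + \#\{\text{overlap} \ge k\})/(\text{reps}+1)$, which can never be
zero, plus the empirical fold ($k$ over the mean simulated overlap). The
Monte-Carlo route exists as an internal cross-check of the analytic tail
(the two agree within Monte-Carlo error on every small instance, which the
test suite verifies) and as the natural generalisation when the null is
not uniform.

## Term enrichment with a custom background

Over-representation of annotation terms in a query set is again the
hypergeometric upper tail, with $K$ background genes carrying the term, $n$
query genes and $k$ hits. Two conventions matter:

* **The background is the membrane-anchored list, not the proteome.**
  Any sheddome is by construction membrane-anchored; tested against a
  whole-proteome background every membrane term would light up. Testing
  against the anchored universe removes that bias, and the suite checks the
  type-I property: random subsets of the background show no systematic
  enrichment.
* **Unannotated query genes count toward $n$ but never toward $k$**,
  mirroring how DAVID treats genes absent from a term namespace within a
  supplied background. They can only dilute enrichment.

Enrichment is one-sided (over-representation only). BH correction runs
within one enrichment call — one term namespace — never across namespaces.
Significance is flagged at $-\log_{10}(p_\mathrm{adj}) \ge 1.3$, i.e.
$p_\mathrm{adj} \le 0.05$; `neg_log10()` maps a hard zero to a finite
sentinel (300) so tables stay numeric. The conservative EASE variant
(DAVID's default score, which removes one hit per term before taking the
tail) is available as `ease = TRUE`; the plain hypergeometric is the
default because it is the exact test of the stated null.

## Differential abundance

The two-group stage mirrors standard label-free practice:

1. **Filtering.** Contaminant accessions are dropped. The consistency rule
   keeps a protein only if it is quantified in *all* replicates of at least
   one group (default) or in at least $k$ of one group
   (`consistency = k`). A protein quantified 4/4 in vehicle and 0/4 in
   treated is kept — complete absence in one condition is a biological
   signal under censoring, not an inconsistency.
2. **log2 transform.** Zero intensities were already treated as missing at
   read time (the MaxLFQ convention that zero means not quantified).
3. **MNAR imputation.** Missing label-free values are predominantly
   left-censored low-abundance measurements. Each missing cell in sample
   $s$ is drawn from $N(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$, where
   $\mu_s,\sigma_s$ are the observed mean and s.d. of that sample — the
   field-standard down-shifted-Gaussian instantiation with its usual
   defaults (shift 1.8, width 0.3), both exposed as parameters. A sample
   needs at least three observed values; the imputation is bit-reproducible
   from its seed, and every imputed cell is recorded in a mask that
   propagates to the result table.
4. **Moderated t.** Per protein, the ordinary two-sample statistics
   (difference of group means; pooled variance $s_g^2$ on $d = n_1+n_2-2$
   df) are moderated by an empirical-Bayes prior: $(d_0, s_0^2)$ are
   estimated by the method of moments on $\log s_g^2$ (the excess of
   $\mathrm{var}(\log s_g^2)$ over the sampling term
   $\psi'(d/2)$ identifies $d_0$ through the inverse trigamma; the mean
   identifies $s_0^2$), and the posterior variance is the convex
   combination $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0+d)$. The
   moderated $t = \Delta/(\tilde s_g\sqrt{1/n_1+1/n_2})$ has $d_0+d$
   degrees of freedom; p-values are two-sided, BH-adjusted across proteins.
   $d_0 = 0$ recovers the ordinary pooled t exactly and
   $d_0 \to \infty$ the fixed-variance z-form; both limits are tested, and
   the whole fit is cross-checked against the independent `limma`
   implementation in the suite.

Numerical choices: zero per-protein variances are excluded from the prior
fit (with $d_0>0$ their posterior variance is still positive); when the
moment equation has no positive root — data less dispersed than pure
sampling noise allows — $d_0$ is capped at $10^6$, i.e. near-complete
shrinkage, with a logged note; if *every* variance is zero the input is
degenerate and the fit errors, except in the exactly-identical-groups case
where $t=0,\ p=1$ is returned. The cap also protects the inverse-trigamma
Newton iteration, which is seeded at $0.5 + 1/y$ and converges in a few
steps elsewhere.

`volcano_table()` classifies proteins at *strict* thresholds
($p < \alpha$, $|\mathrm{log_2FC}| >$ threshold): a protein exactly on the
dashed line is not significant. The significant list uses BH-adjusted p by
default while the conventional dashed plotting line sits at raw
$p = 0.05$ ($y = 1.3$); both are reported because published volcanoes are
usually drawn with the raw-p line even when the list is FDR-controlled.

## Peptide topology evidence

A shed ectodomain can only yield peptides from extracellular residues. With
UniProt-style topology segments (1-based inclusive coordinates throughout),
each detected peptide is classified `extracellular` or `intracellular`
(entirely within segments of that kind), `tm_overlapping` (touches any TM
segment), or `ambiguous` (spans unannotated residues — signal peptides,
linkers — or mixes kinds). A protein's verdict is `ectodomain_only` only
when it has at least one peptide and *no* peptide is anything but
extracellular: ambiguity disqualifies, a deliberately conservative
standard. GPI-anchored proteins without TM segments are treated as entirely
extracellular (they have no cytoplasmic domain). Multi-pass proteins are
handled per segment; no topology is inferred from TM order. Classification
is exhaustive (every peptide gets exactly one class) and
translation-invariant; both are property-tested.

## What the generator simulates — and what it does not

`sim_config()` fixes the study conditions; all downstream draws derive from
its single seed:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 500 | soluble-fraction scale identification list |
| `fraction_membrane_anchored` | 0.4 | ~200 membrane proteins in the universe |
| `n_per_group` | 4 | four biological replicates per condition |
| `baseline_mean`, `baseline_sd` | 25, 2 (log2) | typical MaxLFQ dynamic range |
| `noise_sd` | 0.3 (log2) | replicate CV of ~20% |
| `substrate_fraction` | 0.10 | a minority of anchored proteins respond |
| `substrate_log2fc` | −1 | inhibitor halves shedding of true substrates |
| `dropout_midpoint`, `dropout_slope` | 21.5, 0.5 | detection falls off ~2 s.d. below the mean |
| `shed_fraction` | 0.6 | most soluble-fraction membrane proteins are shed products |

Detection is logistic in the true log2 intensity,
$P(\text{detect}) = \mathrm{logit}^{-1}((y-c)/s)$, chosen over a hard
threshold to produce realistic partial missingness; the step-function limit
($s \to 0$) is exact and tested. Missingness is therefore MNAR by
construction — the mean true intensity of missing cells is below that of
observed cells in every simulation. Anchored single-TM proteins get type-I
topology (N-terminal ectodomain, 21-residue TM, 10–60-residue tail),
matching the adhesion-molecule class that dominates validated substrates
and keeping topology ground truth unambiguous; molecular weight is
0.110 kDa per residue. Sequences are random over the amino-acid alphabet
with K/R planted so every tryptic fragment falls in the 7–30-residue
window (composition realism is a non-goal); digestion follows the Keil
rule (cleave after K/R, not before P).

What it does **not** emulate: correlated protein abundances, batch or
run-order effects, shared-peptide quantification ambiguity, isoforms,
signal peptides, or real annotation errors. Passing the recovery benchmark
therefore shows that the statistical machinery is correct under its own
assumptions — not that any particular real dataset satisfies them.

The recovery benchmark (`recovery_benchmark()`) runs the full stack — 200
membrane proteins, 4 vs 4, 10% substrates at log2 FC −1, noise 0.3, MNAR
dropout — over 20 seeds and scores discoveries at BH 0.05 against the
planted substrates; the suite requires mean observed FDR ≤ 0.10 and mean
sensitivity ≥ 0.7, and re-imputation with a fresh seed must leave the
significant set nearly unchanged (Jaccard ≥ 0.8). These problem sizes keep
a full run of the suite around half a minute while leaving the binomial
error of the estimates well inside the asserted margins.

## Design choices that were genuinely open

* **Identifier isoforms.** Whether `P12345-2` should collapse onto
  `P12345` before translation to Entrez IDs depends on the upstream search
  configuration, so `map_identifiers()` exposes `strip_isoform_suffix`
  (default off) instead of hard-coding either behaviour. Many-to-one maps
  deduplicate the output and report the number of merged inputs.
* **Consistency rule.** "Quantified consistently within a condition" is
  ambiguous between *all replicates* and *at least k*; the default is the
  stricter all-replicates rule, with `consistency = k` as the relaxation.
* **Fraction merging.** Summing shared-sample intensities (rather than
  taking the maximum) treats gel slices as partitions of the same protein
  pool, which is what electrophoretic fractionation is.
* **Occurrence scope.** Counted within one condition's replicates when a
  per-condition sheddome is built (the pipeline does this), over all
  samples otherwise.
* **GPI proteins in topology evidence.** A GPI protein with no TM segments
  has no cytoplasmic side, so the whole chain is treated as extracellular
  rather than "no topology"; this lets shed GPI proteins reach the
  `ectodomain_only` verdict they deserve.
* **Reporting precision.** Percentages are kept at full precision in the
  JSON report and rounded only for display — integer for size changes,
  one decimal for significant fractions (`format_percent()`).

## Known limitations

Only two-group designs are supported (no multi-factor linear models or
ANOVA-style contrasts); peptide-to-protein rollup, batch correction and
topology prediction are out of scope — annotations are inputs. Exact
reproduction of any published sheddome's absolute counts requires that
study's supplementary protein lists and a matching UniProt snapshot;
`shedscan` reproduces the *procedures* and validates them on synthetic
ground truth instead.
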