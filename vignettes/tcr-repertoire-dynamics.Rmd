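---
title: "Longitudinal TCRβ repertoire dynamics: models, metrics, and design decisions"
author: "tcrdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal TCRβ repertoire dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdyn)
```

## The problem

Bulk TCRβ immunosequencing of peripheral blood yields, per sample, a table of
rearrangements: a CDR3 junction nucleotide sequence, V and J gene calls, and
a read count. In a longitudinal treatment cohort the scientific questions are
comparative: does the repertoire contract or broaden between baseline (T1)
and completion of therapy (T2); does convergent clonal selection differ
between patients who achieve disease control (partial response or stable
disease, the DCG) and those with progressive disease (PD); and do these
repertoire dynamics track overall survival? `tcrdyn` implements this analysis
as a reusable pipeline plus a synthetic cohort generator with known ground
truth, so every stage can be validated without access to patient data.

## Data model and clonotype definition

Input is the AIRR Rearrangement TSV dialect (`v_call`, `j_call`, `junction`,
optional `duplicate_count`, defaulting to 1 per record). A **clonotype** is
the key (CDR3 nucleotide sequence, V gene, J gene); records are collapsed
onto that key with counts summed. Junctions are translated in reading frame 1
under the standard genetic code; a junction is *productive* when its length
is divisible by three and the translation contains no stop codon.
Unproductive junctions are removed before any metric is computed — the
amino-acid-level convergence definition presupposes translatable sequences —
but their read mass is tallied so parsing stays lossless
(`depth + discarded_reads` equals the file total). Any `junction_aa` column
in the input is ignored and recomputed by translation, which guarantees that
the nucleotide and amino-acid levels can never disagree internally.

Gene calls are normalized to **gene level**: allele suffixes (`*01`) are
stripped and the first gene of a multi-assignment (`TRBV6-2/TRBV6-3`) is
kept. Convergence is defined on "V gene segments", not alleles, and typical
clonotype callers do not resolve alleles reliably at CDR3-targeted read
lengths.

## Convergence

A **convergent group** is an equivalence class of clonotypes under exact
(V gene, CDR3 amino-acid) identity whose members span at least two distinct
nucleotide sequences. Two deliberate consequences:

- the J gene is *not* part of the convergence key (the definition names only
  the CDR3 amino-acid sequence and the V gene), and
- two rows that share a nucleotide sequence but differ in J do not form a
  group by themselves — the nucleotide sequences must be distinct.

The **convergence frequency** of a sample is the summed read count of all
convergent groups divided by the sample depth, a dimensionless proportion in
[0, 1]. No fuzzy amino-acid matching is attempted. The implementation groups
by key; the test suite checks it against a brute-force all-pairs oracle
(compare every clonotype pair, take connected components) on randomized
repertoires.

```{r convergence-example}
s <- read_repertoire(system.file("extdata", "example_repertoire.tsv",
                                 package = "tcrdyn"))
convergent_groups(s)[, c("v_gene", "cdr3_aa", "n_variants",
                         "aggregate_count", "aggregate_frequency")]
```

## Rarefaction and per-sample metrics

Sequencing depth varies across samples, and both the unique-clone count and
Shannon diversity are depth-dependent, so all metrics are computed after
**rarefaction**: drawing exactly `d` reads without replacement (multivariate
hypergeometric over clonotype counts, delegated to `vegan::rrarefy`). The
default target is the minimum depth across samples passing QC; a fixed
target can be configured instead, in which case shallower samples are
excluded with a logged reason. One draw is made per sample per analysis,
governed by the single pipeline seed; replicate-averaged rarefaction is not
used, keeping each reported metric attributable to one concrete subsample.

Per sample the pipeline reports depth, unique clones, Shannon diversity
`H = −Σ p_i ln p_i`, Pielou evenness `J = H / ln S`, and convergence
frequency. Natural logarithms are used throughout (the base cancels in `J`).
Evenness is reported missing for single-clone repertoires rather than zero,
since `J` is undefined at `S = 1`. Percent declines are kept at full
precision internally and rounded to integer percent only for display; other
metrics display at 2–4 decimals.

## Multivariate structure

The clone-frequency matrix has one row per sample and one column per
(V gene, CDR3 amino-acid) class — amino-acid keying matches the biological
framing of convergence and shared antigen recognition; nucleotide-level
keying is available by option. The union of keys is truncated to the
`top_m = 500` columns by mean frequency (ties broken lexicographically) to
bound dimensionality; with ~15 samples the retained columns carry virtually
all of the non-noise variance. PCA uses column-mean centering without
variance scaling or log transform — raw proportions are the quantity of
interest, and scaling would inflate the influence of rare clones. Because
principal axes are defined only up to sign, a deterministic convention is
applied (the largest-magnitude loading of each component is made positive),
making scores reproducible across linear-algebra backends. Group differences
on a component are tested with the Wilcoxon rank-sum test on scores; the
per-group score range and standard deviation quantify dispersion (e.g. wide
PC2 scatter in PD versus a compact DCG cluster).

## Inference

All tests are two-sided. The Wilcoxon rank-sum test uses the exact null
distribution whenever the smaller group has at most 10 observations and
there are no ties — the regime of this design (groups of ~4 and ~11) — and
otherwise the normal approximation with tie and continuity corrections.
The Spearman trend statistic is the Pearson correlation of mid-ranks of a
metric against the ordinal time point (T1/T2 coded 1/2); its p-value uses
the full permutation null for `n ≤ 8` (40,320 permutations, tie-safe) and
the t approximation on `n − 2` degrees of freedom beyond that. The exact
branch is capped at 8 rather than 10 because the 9! and 10! enumerations buy
negligible accuracy over the t approximation at those sizes; all exactness
checks in the test suite operate at `n ≤ 8`.

Multiplicity is handled with the Benjamini–Hochberg step-up over **exactly
the registered primary-test family** — by default the Spearman
convergence-versus-time trend in the DCG, the Wilcoxon test on T1→T2
delta-clone counts between groups, and the Wilcoxon test on PC1 scores by
group. Descriptive p-values outside the registry are reported uncorrected
and never enter the family. Significance requires both `p < 0.05` and
`q < 0.05`. A test whose inputs are degenerate (an empty group, constant
values) is reported not-evaluable with a note and the pipeline continues;
q-values are then computed over the evaluable members of the family.

Pooled inference is restricted to T1 and T2. T3 samples — drawn at confirmed
progression, from a small, biologically selected subset — are summarized per
patient only and never enter group tests.

Overall survival uses the Kaplan–Meier product-limit estimator with right
censoring and the two-group log-rank test (via the survival package).
Patients whose response is not evaluable (NE) have no defined group and are
excluded from stratified analyses, with the count reported; when no events
occurred the test is returned as undefined rather than a numeric p.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_dcg`, `n_pd` | 11, 4 | post-treatment evaluable group sizes of the target design |
| `clones_t1` | 2,500 | desk-scale baseline richness (per-patient lognormal jitter, sd 0.08) |
| `depth` | 50,000 reads | desk-scale stand-in for multi-million-read assays |
| `abundance_shape` | 0.8 | power-law rank-abundance exponent giving realistic dominance skew |
| `retention_dcg`, `retention_pd` | 0.84, 0.59 | complements of ~16% / ~41% unique-clone declines |
| `convergence_injection_dcg/pd` | 0.0040, 0.0023 | baseline convergent read-mass targets per group |
| `conv_trend_dcg`, `conv_trend_pd` | 0.6, 3.0 | declining DCG trend; transient PD post-treatment rise |
| `t3_conv_trend_pd`, `t3_retention` | 2.0, 0.7 | T3 reversal of the PD rise, with further attrition |
| `hazard_dcg`, `hazard_pd` | 4e-4, 3.5e-3 /day | rare DCG deaths vs ~50% PD mortality by ~200 days |
| `censor_day` | 500 | administrative follow-up cutoff |

Mechanics worth knowing:

- **Codon degeneracy is the convergence engine.** A planted convergent group
  replaces one clonotype by 2–4 distinct synonymous nucleotide encodings of
  its CDR3 (random codon choices under the standard genetic code), splitting
  its read mass with random proportions. Clonotypes are selected in random
  order (each individually under 1% frequency) until the cumulative planted
  mass reaches the injection target, so the realized convergent read
  fraction is an approximately unbiased, slightly-overshooting estimate of
  the target. With injection 0, (V, CDR3aa) keys are kept unique, so
  convergence is exactly zero.
- **Group-structured dominance drives the PCA geometry.** DCG patients share
  a pool of `n_shared_dcg = 30` dominant clonotypes occupying the top
  abundance ranks; PD patients receive idiosyncratic dominant clones. This
  reproduces the qualitative multivariate phenotype — a compact DCG cluster
  versus wide PD dispersion — without hand-placing any score.
- **T2 derivation.** Each T1 base clonotype survives to T2 with the
  patient's realized retention probability (Beta-distributed around the
  group mean, sd 0.04); surviving abundances are renormalized, a small mass
  (2%) of 60 newly primed clones is added, and convergence is re-planted at
  the group's T2 target. The T1→T2 decline in observed unique clones
  therefore recovers `100 × (1 − retention)` up to sampling noise.
- **Survival** is exponential per group with administrative censoring;
  responses within the DCG are split PR/SD at the configured fraction
  (default 4/11).

What the generator does *not* emulate: VDJ recombination statistics, thymic
selection or HLA restriction, sequencing error, PCR amplification bias, true
inter-locus correlations of V/J usage, or batch effects. Passing tests
therefore demonstrate correctness of the analysis pipeline under the stated
statistical structure, not biological fidelity of any simulated repertoire —
conclusions about real cohorts still require real data.

## Numerical choices and degenerate inputs

- One global seed governs a run; per-sample rarefaction seeds are derived
  from it deterministically, and all seeded code paths restore the caller's
  RNG state. Reruns reproduce every numeric output bit-identically.
- Clonotype tables are ordered by descending count, then lexicographic key,
  making outputs insensitive to input row order.
- Metrics tables are serialized with 17 significant digits so a write/read
  round trip is the identity on doubles.
- Frequency vectors are validated strictly (positive entries, sum within
  1e-9 of 1); zero-depth samples, constant vectors, empty groups, and
  out-of-range targets raise immediate errors rather than propagating NaNs,
  except inside the pipeline's test registry where they downgrade to
  not-evaluable results.
- PCA refuses constant matrices (zero variance) and `k` beyond
  `min(rows − 1, cols)`.

## Problem sizes used in the packaged checks

The test suite validates oracle equivalence on randomized repertoires of up
to 200 clonotypes (100 replicates), exact-test enumeration at `n ≤ 8` per
group, and parameter recovery on 20 synthetic cohorts at the default
configuration (15 patients, 50,000 reads per sample) — sizes chosen so the
entire suite completes in a few minutes on a single core while still
exercising every code path at the study's group sizes.

## Known limitations

- Convergence uses exact amino-acid identity; near-identical CDR3s (one
  mismatch) are not grouped, by design.
- V-gene matching trusts the caller's first listed gene; no re-annotation
  against germline references is performed.
- The log-rank test is unstratified and no multivariable survival modeling
  (Cox regression) is provided.
- The rarefaction target policy ("minimum across passing samples") makes the
  metric scale cohort-relative; cross-cohort comparisons should fix an
  absolute depth.
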