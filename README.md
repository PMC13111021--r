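# tcrdyn

Longitudinal analysis of T-cell receptor beta (TCRβ) repertoires for
treatment cohorts: how does the circulating T-cell compartment reorganize
between a baseline blood draw (T1), completion of systemic therapy (T2), and
disease progression (T3), and do those dynamics separate patients who achieve
disease control (DCG: partial response or stable disease) from those with
progressive disease (PD)?

The package is aimed at translational immunologists and biostatisticians
working with bulk TCRβ immunosequencing (AIRR rearrangement tables). It
implements the full analysis path:

- **Clonotypes** are unique CDR3 nucleotide sequences combined with V and J
  gene usage; junctions are translated in frame 1 and unproductive
  rearrangements (frameshift or stop codon) are removed with their read mass
  tallied.
- **Convergence.** A convergent group is a set of clonotypes with an
  identical CDR3 amino-acid sequence and V gene segment encoded by two or
  more *distinct* nucleotide sequences — a surrogate for antigen-driven
  convergent selection. The convergence frequency of a sample is the
  cumulative read fraction of all such groups,
  `C = (1/N) Σ_g Σ_{i∈g} n_i ∈ [0, 1]`.
- **Diversity.** Shannon diversity `H = −Σ p_i ln p_i` (nats) and Pielou
  evenness `J = H / ln S`, computed after rarefaction (hypergeometric
  subsampling without replacement) to a uniform depth so samples are
  comparable.
- **Dynamics.** Per-patient unique-clone deltas T1→T2 and percent declines;
  clone-frequency PCA across samples (keys at the (V, CDR3aa) level,
  column-centered, deterministic sign convention) with score dispersion by
  group.
- **Inference.** Shapiro–Wilk gate, exact small-sample Wilcoxon rank-sum,
  Spearman trend with a permutation-exact branch, Benjamini–Hochberg
  correction over the registered primary-test family (default three tests),
  Kaplan–Meier curves with the log-rank test.
- **Synthetic cohorts.** A generator that plants all of the above structure
  with known ground truth — power-law clone abundances, codon-degenerate
  convergent groups, group-specific clone retention, convergence trends, and
  survival hazards — so every pipeline stage is testable without sequencing
  data.

## Worked example

Simulate a cohort of 11 disease-control and 4 progressive-disease patients at
the default study conditions and run the full analysis:

```r
library(tcrdyn)

cfg     <- sim_config(seed = 42)                     # 15 patients, 50k reads/sample
cohort  <- simulate_longitudinal_cohort(cfg)
manifest <- write_cohort(cohort, "demo_cohort")      # AIRR TSVs + manifest.csv
report  <- run_pipeline(run_config(manifest, out_dir = "demo_run", seed = 42))
report
```

```
<run_report> seed 42 | rarefaction depth 50000
  samples: 34  patients with deltas: 15
  primary tests:
                           name statistic         p         q significant
 spearman_convergence_trend_dcg   -0.8672 1.764e-07 5.126e-07        TRUE
          wilcoxon_delta_clones   44.0000 1.465e-03 1.465e-03        TRUE
             wilcoxon_pc1_group  176.0000 3.417e-07 5.126e-07        TRUE
  log-rank p: 1.392e-05
```

The three rows are the primary-test family: convergence declines over time in
the disease-control group (negative Spearman rho), the T1→T2 loss of unique
clones is larger in PD than in DCG, and PC1 of the clone-frequency matrix
separates the groups; q-values are BH-adjusted over exactly these three
tests. Group-level summaries come straight off the report tables:

```r
aggregate(percent_decline ~ group, report$deltas, median)
#   group percent_decline
# 1   DCG        17.10744
# 2    PD        39.83912
sapply(report$km$curves, km_median)
# DCG  PD
# Inf 112
```

PD patients lose ~40% of their unique clones versus ~17% in DCG (the
generator's retention defaults are 0.59 and 0.84), and the PD median overall
survival is reached at 112 days while the DCG curve never drops to 0.5.
Every table is also written under `demo_run/` (`metrics.tsv`, `deltas.tsv`,
`tests.tsv`, `pca_scores.tsv`, `attrition.tsv`, `run_log.jsonl`).

A single sample can be inspected without the pipeline:

```r
s <- read_repertoire(system.file("extdata", "example_repertoire.tsv",
                                 package = "tcrdyn"))
convergent_groups(s)          # one TRBV5-1/CASSF group, 2 nt variants
sample_metrics(s, "demo", "T1")
```

A thin command-line wrapper with `simulate` / `run` / `metrics` subcommands
is installed at `inst/scripts/tcrdyn-cli.R`.

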