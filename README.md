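# slestrat

Whole-blood transcriptomic stratification of systemic lupus erythematosus
(SLE) heterogeneity.

SLE patients differ widely in which immune gene-expression programs are
active in their blood — interferon-stimulated genes, plasma cells,
granulocytes, T/B/NK lymphocytes, and more — and the mix is entangled with
ancestry, autoantibody profile and standard-of-care drugs. `slestrat` is
an R implementation of a full stratification workflow for such cohorts,
aimed at researchers who want to score, call and model immune signatures
in bulk whole-blood expression data, or to study the statistical behaviour
of that workflow on simulated cohorts.

## What it computes

* **Module enrichment scores.** For each sample and gene module, a
  nonparametric score in [−1, +1] from a Gaussian-kernel CDF statistic
  ( z_ij = Σ_k Φ((x_ij − x_ik)/h_i), h_i = s_i/4 ) and a
  Kolmogorov–Smirnov-like random walk over the within-sample gene ranking
  weighted by r_i = |N/2 − rank_i|; the score is the sum of the largest
  positive and negative walk deviations.
* **Signature calls.** Healthy controls define a per-module normal range
  (mean ± 1 SD); patient scores become +1 / 0 / −1 calls. Frequencies per
  group with Fisher exact tests; score contrasts with Sidak-adjusted
  Welch t.
* **Differential expression.** Empirical-Bayes moderated t (moment-matched
  variance prior), BH FDR, a randomized half-split negative control, and
  Fisher's-exact gene-list overlap.
* **Stepwise odds ratios.** Each signature call modeled against 26 binary
  clinical predictors (ancestry, drugs, manifestations, serology groups,
  complement, age, duration) with Spearman collinearity screening, Rao
  score-test entry / Wald removal at 0.05, Hosmer–Lemeshow gating, and the
  interval-graph OR→line-width mapping (reciprocal display for OR < 1;
  widths 1/5/10/20 pt).
* **Ancestry classification.** Elastic-net logistic regression on module
  genes with stratified 10-fold cross-validation, pooled-probability
  ROC/AUC and top-25 gene importance.
* **Sex QC.** XIST + TSIX − (UTY + RPS4Y1 + USP9Y) score with discordance
  reporting.
* **Synthetic cohorts.** A generator that reproduces the emulated study's
  reported composition (216/1118/232 patients + 17 HC; anti-RNP 62/30/51%,
  corticosteroids 70/70/92%, dsDNA∧lowC 23/29/37%, ...) and plants
  ancestry/drug/serology effects on module genes, so every stage is
  testable end to end without patient data.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic cohort (60 AA / 120 EA / 60 NAA patients + 17 HC, 2,000 genes)
and write their tables under `results/`. Running them in order prints,
among other things:

```
$ Rscript analysis/02_score.R
scored 34 modules x 257 samples; range [-0.852, 0.867]
mean plasma-cell score by ancestry:
    AA     EA    NAA
 0.322 -0.078 -0.190

$ Rscript analysis/03_signatures.R
48 of 204 module/direction/pair contrasts differ (Fisher p < 0.05)
plasma-cell call frequencies by ancestry (%):
 group   pct_up pct_down
    AA 78.33333 10.00000
    EA 33.33333 27.50000
   NAA 25.00000 46.66667

$ Rscript analysis/04_diffexpr.R
AA vs EA: 79 DE transcripts at FDR < 0.05 (prior df 4.6)
randomized half-split DEG counts within EA: 0, 0, 1, 0, 0
replication overlap: 52/79 vs 70 genes, OR 200.2, p 5.66e-67

$ Rscript analysis/06_classify.R
cross-validated classifier: AUC 0.967, accuracy 0.878 (sens 0.683, spec 0.975) over 10 folds
```

Reading: every score is inside the [−1, +1] bound; the planted AA
plasma-cell shift surfaces both as a higher mean score (0.32 vs −0.08)
and as a higher +1-call frequency (78% vs 33%); ancestry differential
expression replicates across two independently generated cohorts while
the randomized self-split control finds essentially nothing; and the
planted ancestry signature makes AA vs EA patients separable from module
genes (AUC 0.97). The same quantities on a null cohort (no planted
effects) collapse to chance — the tests verify both directions.

In code, the core loop is:

```r
library(slestrat)
cfg    <- cohort_config(n_per_ancestry = c(AA = 40, EA = 80, NAA = 40),
                        n_hc = 17, seed = 1)
meta   <- generate_metadata(cfg)
mods   <- default_modules(n_genes = 2000, seed = 2)
expr   <- generate_expression(meta, mods, n_genes = 2000, seed = 3)
scores <- enrichment_scores(expr, mods)                  # modules x samples
calls  <- trichotomize(scores,
                       fit_normal_range(scores, meta$sample_id[meta$is_control]))
```

Real data enter the same way: `read_expression()` (genes × samples TSV),
`read_metadata()` (CSV) and `read_gmt()` (gene sets; a small synthetic
example lives in `inst/extdata/demo_modules_synthetic.gmt`).

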