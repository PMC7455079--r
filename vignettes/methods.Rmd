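---
title: "Methods: module scoring, signature calling and association modelling in slestrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module scoring, signature calling and association modelling in slestrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slestrat)
```

# The problem

Whole-blood transcriptomes of systemic lupus erythematosus (SLE) patients
are heterogeneous: interferon, plasma-cell, granulocyte and other immune
signatures wax and wane across patients, and the mix differs between
ancestral groups. `slestrat` implements a complete stratification workflow
for such cohorts — per-sample gene-module enrichment scores, trichotomized
signature calls against a healthy-control (HC) reference band, frequency
and distributional comparisons between groups, moderated differential
expression with a randomized-split negative control, a 26-predictor
stepwise logistic odds-ratio framework over the signature calls, penalized
ancestry classification, and transcriptome-based sex QC — together with a
synthetic-cohort generator so every stage is testable without patient
data.

# Per-sample module scores

## Gene-level kernel CDF

For gene $i$ and sample $j$ with log2 expression $x_{ij}$ the relative
expression statistic is a Gaussian-kernel CDF estimate across the cohort,

$$z_{ij} = \sum_k \Phi\!\left(\frac{x_{ij} - x_{ik}}{h_i}\right),
\qquad h_i = s_i/4,$$

with $s_i$ the gene's sample SD. The bandwidth $s_i/4$ is the standard
kernel choice for continuous microarray-scale intensities. $z$ is strictly
increasing in $x_{ij}$, so it carries rank information into the walk
without distributional assumptions. Zero-variance genes receive a floor
bandwidth of $10^{-8}$ (with a warning) rather than exclusion, keeping the
gene universe identical across samples.

## KS-like random walk

Within each sample, genes are ranked by decreasing $z$; ties are broken by
gene identifier (lexicographic), so results cannot depend on input row
order. With the symmetric rank weight $r_i = |N/2 - \mathrm{rank}_i|$ the
walk over the ranked list gains $r_i^\tau / \sum_{g\in G} r_g^\tau$ at
genes of module $G$ and loses $1/(N-m)$ elsewhere ($\tau = 1$ by default).
The score is the sum of the largest positive and the largest negative walk
deviation, which is bounded in $[-1, +1]$ by construction: $+1$ when the
module occupies exactly the top ranks, $-1$ at the bottom, $\approx 0$ for
incoherent modules. A `single_extreme` flag reports the single
largest-magnitude deviation instead. The walk statistic itself is the
score; no cohort-level rescaling is applied afterwards, and the score
matrix is the pipeline's central intermediate.

The test suite pins this implementation to an independently coded
brute-force walk at $N \le 50$, and fuzz tests assert boundedness, shift
invariance and monotonicity under module-gene upshifts.

# Signature calls and group comparisons

Scores of at least two HC samples give a per-module normal range: HC mean
$\pm$ 1 SD (sample SD, $n-1$). Patient calls are $+1$ above the band,
$-1$ below, $0$ inside; boundary values call $0$ because the band is
defined by strict inequalities. Under a Gaussian null, each tail collects
$1 - \Phi(1) \approx 15.9\%$ of patients — a property the tests verify by
simulation, and worth remembering when reading call frequencies: a third
of a null cohort is called non-normal by design.

Call frequencies per group are compared with two-sided Fisher exact tests
for every unordered group pair and direction. Score distributions are
compared by Welch's unequal-variance $t$; the pair family within each
module can be Sidak-adjusted ($1-(1-p)^m$). Tukey's multiple-comparison
procedure, used in the source workflow through commercial software, is
deliberately not reimplemented; Sidak-adjusted Welch contrasts are the
documented substitute.

# Moderated differential expression

Two-group DE uses the empirical-Bayes moderated $t$: per-gene pooled
variances $s_g^2$ on $d_g$ df are shrunk toward a prior $(d_0, s_0^2)$
fitted by moment-matching the log-variance distribution (digamma/trigamma
closed forms, with a Newton inverse for the trigamma), giving posterior
variances $(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and $d_0 + d_g$ df. The
global-prior form is implemented; an intensity-dependent ("local") prior
is not, as a single gene-level matrix is in scope. `d0 = 0` recovers the
ordinary $t$ and `d0 = Inf` the pooled-variance statistic; the estimated
prior is cross-checked against the standard Bioconductor empirical-Bayes
fit in the tests. Discovery lists use BH FDR < 0.05 by default; list
construction at FDR < 0.2 (the cross-platform convention) is exposed as a
parameter of the overlap machinery.

`randomization_control()` implements the workflow's negative control:
split a putatively homogeneous sample set into random balanced halves and
count discoveries — a homogeneous group yields zero for the large
majority of seeds, and a group hiding two subtypes does not.

# Outlier-stratum ("SNOR") module derivation

The derived outlier modules are built by (1) computing PC1 of the centered
log2 matrix over HC + patients (covariance scaling; the first component of
a plain PCA), (2) selecting the patients whose PC1 coordinate lies within
the HC min–max band — the patients PCA fails to separate from controls,
(3) running moderated DE of that stratum versus HC, and (4) taking the 7
most increased and 7 most decreased transcripts (ranked by log2 fold
change, not $p$) among those with FDR < 0.005. Whether the original
procedure used one or two components, or correlation scaling, is not
recorded; PC1 with the HC range is the minimal reading and the
implementation keeps both the FDR cut and `n_top` configurable. When fewer
than `n_top` transcripts pass, the shorter list is returned with a warning
— never padded.

# Stepwise logistic odds ratios

Each of the 34 signature outcomes (indicator of a $+1$ call, or of a $-1$
call for "low" outcomes — which outcomes are "low" is metadata of the
outcome panel) is modeled against 26 binary predictors: 3 ancestry
indicators, 7 drugs, 5 manifestations, 4 mutually exclusive serology
groups plus low C3 and low C4, age > 50, and 4 disease-duration
categories. Before modelling, a tie-corrected Spearman screen flags the
later-listed member of any pair with $|\rho| > 0.5$ (the rule that removed
a redundant ethnicity indicator at $\rho = 0.54$ in the source analysis).

Selection is SAS-style p-value stepwise: the candidate with the smallest
Rao score-test $p$ enters while $p < 0.05$; included terms with Wald
$p > 0.05$ are removed, iterated to stability with a visited-state guard
(cap 50 cycles). Entry and stay thresholds default to 0.05/0.05, the
common convention where none is stated. One numerical guard matters in
practice: for a (quasi-)separated predictor the Wald $p$ collapses toward
1 (Hauck–Donner), which would evict precisely the most informative term;
terms whose standard error exceeds 5 therefore fall back to a
likelihood-ratio $p$ for the removal decision. Final models are refit,
odds ratios reported as $e^\beta$ with 95% Wald intervals, and gated by
the Hosmer–Lemeshow decile-of-risk test (g = 10, df = g − 2, ties kept
together, zero-expectation groups merged): models with HL $p < 0.05$ are
flagged `discarded`. The g − 2 reference assumes the probabilities come
from a model fitted to the same data — handing the test the true
generating probabilities inflates its null rejection rate to ~11%, which
the calibration tests exercise with fitted models for exactly that
reason.

For visualization, odds ratios below 1 are displayed as reciprocals with
negative direction, and line widths follow the interval rule: display-OR
< 2 → 1 pt, [2, 3) → 5 pt, [3, 10) → 10 pt, ≥ 10 → 20 pt (the only
internally consistent reading of the published interval strings). The
transform is reciprocal-symmetric: width(x) = width(1/x) with direction
flipped.

# Ancestry classification

The native engine is elastic-net logistic regression (via glmnet) on the
module genes, with per-gene standardization fitted on training folds only
— a consistent affine rescaling of the input matrix therefore leaves
test-fold predictions unchanged, which the tests assert. Stratified
10-fold cross-validation collects out-of-fold class probabilities; pooled
probabilities give the ROC curve and trapezoidal AUC (identical to the
normalized Mann–Whitney U, an identity the tests pin), and thresholding at
0.5 gives per-fold sensitivity/specificity/accuracy, then averaged.
"Gene importance" is not defined in the source description; here it is the
absolute standardized-input coefficient, with lexicographic tie-breaks, and
the top 25 are reported by default. A maximum-margin engine can be plugged
in behind the same `engine` contract; the published SVM-vs-GLM accuracy
comparison on the real cohorts is out of scope.

# Sex QC

The sex module score is `XIST + TSIX − (UTY + RPS4Y1 + USP9Y)` on log2
expression; positive infers female, negative male, exactly zero (not
covered by the published rule) is reported as indeterminate. Matching is
case-insensitive with an optional alias map for probe-level identifiers,
and samples whose inference contradicts the recorded sex are flagged in a
discordance report.

# The synthetic cohort

The generator emulates the statistical structure of the emulated study
population, not its biology:

* **Sizes.** Defaults are 216 AA / 1118 EA / 232 NAA female patients and
  17 female HC. The bundled analysis scripts score a 60/120/60 + 17
  subcohort on 2,000 genes so the full workflow (scoring is the expensive
  stage, quadratic in samples within each gene) completes in about half a
  minute on one core; metadata-level analyses use the full sizes.
* **Frequencies.** Reported rates are reproduced exactly: anti-RNP
  62/30/51% (AA/EA/NAA), anti-Sm 24/12%, corticosteroids 70/70/92%,
  any-immunosuppressive 39/39/58%, anti-dsDNA 57.5% and low complement
  40% marginally, and the joint dsDNA-with-low-C 23/29/37% — low C is
  drawn conditionally on dsDNA so marginals and joint agree
  simultaneously. Rates not reported anywhere (NSAIDs 25%, antimalarials
  60%, vasculitis 5%, SSA 25–35%, SSB 10–15%, anti-Sm in NAA 20%,
  age > 50 20%, duration mix 15/35/25/25%, the one-of-four
  immunosuppressive split 35/30/30/5%, the C3/C4 split 45/25/30%) are
  fixed field-plausible defaults chosen once and documented here.
  Autoantibody flags are drawn independently per antibody — the joint
  dependence structure within a patient is unknown, and independence is
  flagged as an assumption; joint combination frequencies can be supplied
  directly instead.
* **Expression.** Per-gene Gaussian noise on the log2 scale, baseline
  means uniform on [4, 12] and SDs on [0.2, 0.8]; heavier-tailed platform
  noise, probe effects and batch structure are deliberately absent.
  Planted effects are additive log2 shifts applied uniformly to all genes
  of a module for samples carrying a covariate (per-gene heterogeneity is
  available but off by default). The default effect table encodes the
  reported qualitative directions — corticosteroids ↑ LDG/granulocyte/
  monocyte/antiinflammation, MTX and MMF ↓ plasma cell/Ig, AZA ↓ NK (and
  T-cytotoxic/B cells), the RNP⁺dsDNA⁺ serology group ↑ plasma cell/
  interferon/cell-cycle/Treg, AA ↑ B/plasma-cell/Ig/Treg, NAA ↑
  LDG/granulocyte/inflammasome/IL-1 — with magnitudes of 0.2–1.0 log2
  units that are artifact defaults, not measurements.

Because effects are uniform and noise is Gaussian, passing tests
demonstrate that the statistical machinery recovers what was planted at
realistic sizes and noise levels; they do not demonstrate robustness to
platform artifacts, correlated genes within modules beyond the planted
shifts, or autoantibody dependence — all absent from the generator by
design.

# Numerical choices and degenerate inputs

* Walk ties broken lexicographically by gene identifier; zero-variance
  bandwidth floor $10^{-8}$; a module spanning the whole universe is an
  error (the walk is undefined), a module with no measured genes is
  omitted with a warning.
* Boundary scores call 0; missing scores propagate as missing calls and
  are counted in a QC attribute.
* Variance-prior fitting falls back to the pooled common variance (with a
  warning) when the log-variance spread is no wider than the sampling
  distribution implies ($d_0 \to \infty$).
* Logistic fits error on perfect separation (|coef| > 15) and singular
  designs, naming the predictor; stepwise results report huge CIs for
  retained quasi-separated terms instead of erroring, since discarding a
  maximally informative association would misreport the screen.
* Hosmer–Lemeshow merges zero-expectation risk groups with a neighbor
  (adjusting df) and reports NA when fewer than three informative groups
  remain; g < 3 is an error.
* The pipeline driver fans one user seed into per-stage child seeds drawn
  once from the seeded RNG, so stages can be rerun in isolation and a
  rerun with the same configuration is bit-identical (verified by
  manifest checksums).

# Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_per_ancestry = c(AA = 40, EA = 80, NAA = 40),
                     n_hc = 17, seed = 1)
meta <- generate_metadata(cfg)
modules <- default_modules(n_genes = 2000, seed = 2)
expr <- generate_expression(meta, modules, n_genes = 2000, seed = 3)

scores <- enrichment_scores(expr, modules)
nr <- fit_normal_range(scores, meta$sample_id[meta$is_control])
calls <- trichotomize(scores, nr)

pat <- meta$sample_id[!meta$is_control]
X <- build_predictor_matrix(meta)
y <- outcome_vector(calls[, pat], "IGS", "high")
stepwise_select(y[rownames(X)], X, outcome_name = "IGS_high")
```

The numbered scripts under `analysis/` run the same sequence end to end
and write their tables under `results/`.

# Known limitations

The generator's independence and uniform-effect assumptions above; no
probe-level or count-based (RNA-seq) scoring mode; no multinomial
outcomes; CIRCOS rendering is reduced to its numeric edge mapping; the
published headline numbers from the real trial cohorts (e.g. specific
odds ratios and classifier accuracies) depend on those data and are not
reproduced by the synthetic workflow — the pipeline reproduces the
*procedures* and their statistical guarantees.
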