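---
title: "Penalized Cox signature discovery: models, procedures and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized Cox signature discovery: models, procedures and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`survsig` implements a complete discovery-and-validation workflow for small
prognostic gene-expression signatures in right-censored cohort data, of the
kind used to ask whether a targeted qPCR gene panel predicts breast-cancer
mortality and recurrence as well as, or better than, standard clinical
staging information. This vignette explains the statistical machinery, the
tunable parameters, the synthetic-cohort generator used to exercise every
stage, and the design decisions taken where more than one reasonable choice
existed.

## The model

All survival modelling is proportional hazards,

$$\lambda(t \mid x) = \lambda_0(t)\, \exp\!\Big(\sum_{j=1}^p x_j \beta_j\Big),$$

with an unspecified baseline $\lambda_0(t)$ and coefficients estimated by
maximizing the log partial likelihood $l(\beta)$. Covariates are either log2
relative expression values (one unit = one doubling of expression, so
$e^{\beta_j}$ is the hazard ratio per doubling) or clinical contrasts (stage,
receptor status, and so on). Two outcomes are carried side by side: overall
survival (time to disease-related death) and disease-free survival (time to
recurrence); patients who were never disease-free are excluded from
recurrence models but retained for mortality, and all other missingness is
handled by per-analysis complete cases — no imputation anywhere, because the
workflow this package reproduces reports none.

Variable selection uses the L1-penalized partial likelihood

$$\hat\beta(\lambda) = \arg\max_\beta \; l(\beta) - \lambda \sum_j |\beta_j|,$$

which shrinks unimportant coefficients exactly to zero. The shrinkage
parameter $\lambda$ is chosen by 10-fold cross-validation: folds are
stratified on the event indicator and each grid value scored by the
cross-validated partial likelihood $l_{\text{full}}(\hat\beta_{-k}) -
l_{\text{train}}(\hat\beta_{-k})$ summed over folds.

## The discovery pipeline

1. **Univariate screen** (`univariate_screen`). One Cox model per variable on
   that variable's complete cases. Gene p-values are adjusted by
   Benjamini–Yekutieli — valid under the arbitrary dependence that highly
   intercorrelated expression values produce — while clinical contrasts use
   plain Benjamini–Hochberg. Gene rows are sorted by raw p-value; clinical
   factors use conventional reference levels (stage 1, grade 1,
   node-positive, ER+/PR+).

2. **Stability selection** (`stability_selection`). The core procedure:
   repeat, over many (canonically 1000) stage-stratified 70/30 train/test
   splits, a cross-validated LASSO fit on the training set, and count how
   often each gene keeps a nonzero coefficient. Significance is calibrated by
   a permutation null: each replicate jointly shuffles the outcome
   (time, event) pairs across patients, runs one split + CV + fit, and
   records the retained genes; the threshold is the *highest per-gene total
   count* over the permuted replicates, and observed genes are declared
   significant only when their count is strictly greater. Genes whose
   coefficient sign is inconsistent across splits are flagged and dropped
   from the final signature.

3. **Model comparison** (`compare_models`). The selected genes are re-fitted
   as a fixed set (no re-selection) over fresh splits, against a clinical
   model (3-level stage with stages 3–4 pooled, ER, PR) and a combined
   model. Performance is Harrell's C on the test set; patients are
   classified low/high risk at the median training linear predictor, and
   per-class Kaplan–Meier curves are retained. Summaries are medians with
   empirical 95% (2.5th/97.5th percentile) intervals, and model contrasts
   are *paired* per-split differences with percentile intervals. Subgroup
   C-indexes for ER+ and ER− test patients use the all-patient fits.

4. **Diagnostics** (`residual_cox`, `detectable_hr`, `interaction_scan`).
   `residual_cox` explains sign flips in correlated panels: the target gene
   is regressed (OLS) on its correlated partners and the residual enters a
   univariate Cox model, separating the hazard carried by the gene's own
   variation from what it shares with the block. `detectable_hr` evaluates
   the study-power formula $\log HR = \sqrt{(z_{1-\alpha} +
   z_{1-\beta})^2 / (D\sigma^2)}$ literally. `interaction_scan` Wald-tests
   gene-by-clinical product terms with BH adjustment across genes.

## The synthetic cohort generator

Every stage is exercised end to end on synthetic cohorts
(`sim_config` / `generate_cohort`) whose defaults emulate the structure the
analysis assumes:

* **Expression.** 32 genes, per-gene SD 1.8 and means near the study-table
  medians. The hormone-receptor block (PGR, ESR1, NAT1, SLC39A6, TBC1D9,
  LRBA) is realized by a single latent factor with positive loadings
  0.60–0.80 (pairwise correlations ≈ 0.36–0.60) and GABRP loads at −0.35
  (correlations ≈ −0.21 to −0.34 with the block). A one-factor model was
  chosen because any loading vector with $|l| < 1$ yields a positive
  definite covariance, for every requested strength.
* **ER linkage.** Block genes are shifted up by 1.2 log2 units in ER+
  carcinomas and GABRP up in ER−, giving gene–ER point-biserial correlations
  around ±0.3.
* **The LRBA sign-flip.** LRBA's hazard contribution is planted on its
  *residual* component (coefficient 0.20 per log2 unit on the factor-free
  part), so its marginal hazard ratio is near 1 while the
  residual-adjusted hazard ratio exceeds 1 — the phenomenon `residual_cox`
  is designed to expose — by construction rather than by accident.
* **Outcomes.** Exponential baseline (0.0035/month for mortality,
  0.0042/month for recurrence) on mean-centered covariates, with modest
  planted protective effects on the signature genes and stage/receptor
  effects matching the magnitude of the study's univariate clinical hazard
  ratios. Censoring is the minimum of an independent exponential
  (0.008/month) and a 220-month administrative horizon; these rates were set
  once so that the default cohort shows roughly 30% events and a median
  follow-up near 60 months, and are not revisited.
* **Clinical marginals.** Stage 51/143/27/8, ER/PR 133/17/30/53 (as exact
  count ratios rather than the rounded percentages, which do not sum to 1),
  grade 13/86/105, node-positive 58%, and sporadic missingness at the
  study's observed rates (4/225 stage, 14/225 size, 16/225 nodes), with
  7/225 never disease-free.

What the generator does **not** emulate: heavy-tailed or skewed expression
(it is Gaussian given ER status, so the average IQR is ≈ 2.5 rather than the
study's 3.0), plate/batch effects, dependence between the two outcomes
beyond shared covariates, informative censoring, and any real biological
pathway structure beyond the single ER factor. Green tests therefore
demonstrate that the *procedures* behave as specified under the assumed
data-generating model, not that the biological findings transfer.

Reproducibility uses one master seed with per-purpose child seeds derived by
a fixed congruential map (`child_seed(seed, stream, index)`), so any split,
permutation replicate or generator stage can be regenerated independently.

## Numerical choices

* **Ties.** Breslow for all penalized fitting (matching the penalized-Cox
  software family), Efron for unpenalized fits (the survival-analysis
  default); both selectable. They coincide exactly when no event times tie.
* **Newton fitting.** Step-halving line search, tolerance $10^{-9}$ on the
  log-likelihood change, 50 iterations. A monotone (separating) likelihood
  is capped at $|\beta| \le 15$ and flagged per coefficient rather than
  iterated forever; standard errors come from the inverse observed
  information.
* **Coordinate descent.** Cyclic coordinate-wise Newton steps passed through
  the soft-threshold operator, with per-step halving so the penalized
  objective is non-decreasing; convergence at $10^{-7}$ maximum coefficient
  change, at most 1000 sweeps, with active-set iteration between full
  sweeps. No covariate standardization by default (the panel is already on
  a common log2 scale); an optional flag standardizes and back-transforms.
* **Penalty grid.** 50 log-spaced values from $\lambda_{\max} = \max_j
  |\partial l/\partial\beta_j(0)|$ down to $10^{-3}\lambda_{\max}$.
* **CV rule.** The default picks the literal maximizer of the
  cross-validated partial likelihood (ties toward the larger penalty). Under
  pure noise that rule admits a spurious variable or two in roughly a third
  of runs — the same behavior other cross-validated penalized-Cox
  implementations show — so a one-standard-error parsimony rule is available
  as `rule = "1se"`.
* **Tie-breaks.** Largest-remainder stratified allocation breaks remainder
  ties by stratum order; risk classification sends scores equal to the
  training median to the low-risk class; probe collapse keeps the first
  probe on exact variance ties; the comparable-pair convention treats a tied
  time with exactly one event as the event failing first, and tied risk
  scores count 1/2.
* **Degenerate inputs.** Zero events, constant covariates, singular
  information, negative times, collinear adjusters and empty complete-case
  sets all raise immediate, named errors; failing resampling splits are
  re-drawn once from a derived seed and then dropped with a warning, with
  counts reported against successful splits.

## Design decisions on genuinely open points

* **What is permuted.** The null procedure shuffles outcome (time, event)
  pairs jointly across patients, leaving all covariates (including the stage
  variable used for stratification) attached to their patients. Permuting
  expression rows instead would break the gene–clinical correlation
  structure, which should survive under the null.
* **Permutation budget.** "1000 total permutations" is implemented as 1000
  replicates of (permute → one split → one CV + LASSO fit), so observed and
  null counts are on the same per-fit scale. Re-running the full 1000-split
  pipeline inside every permutation would cost a thousand times more for the
  same exchangeability argument.
* **Sign consistency.** The verbal rule for dropping ambiguous-sign genes is
  made concrete as: a gene is sign-ambiguous when neither sign accounts for
  at least 90% of its nonzero per-split coefficients.
* **Power formula sidedness.** The formula is implemented literally with the
  one-sided quantile $z_{1-\alpha}$ (configurable to two-sided). The printed
  minimal detectable hazard ratio of 1.116 at $\alpha = 0.05/32$, $\beta =
  0.2$, $D = 68$, $\sigma = 1.8$ is *not* reproduced by literal evaluation
  under either sidedness convention (literal evaluation gives a larger
  ratio), so the package documents the discrepancy and treats only the
  formula, not the printed value, as normative.
* **Node-status reference.** The clinical screen reports node-negative
  against a node-positive reference, reproducing the source table's printed
  convention even though a hazard ratio above 1 for node-*negative* disease
  is clinically unexpected; reverse the contrast externally if the
  conventional direction is wanted.

## Problem sizes in the test suite

The shipped tests run the full machinery at sizes chosen to make the
statistical assertions sharp while keeping a complete run lightweight:
oracle equivalence on hundreds of small random instances; coefficient
recovery at $n = 2000$–5000 with planted $|\beta| = 0.3$ (several sampling
SDs inside the ±15% band); stability-selection recovery at the study's
$n = 225$ with 100 splits and 100 permutation replicates; and chance-level
calibration of the permuted pipeline over 200 splits. The canonical
1000-split, 1000-permutation runs are a parameter away (`n_splits`,
`n_perm`) and scale linearly.

## Known limitations

Time-varying covariates, stratified baselines, robust variance, elastic-net
penalties, time-dependent AUC and calibration measures are out of scope.
Class-size reproduction in model comparison is approximate because per-split
complete-case filtering depends on which patients land in each split.
Selection aggregates over genes individually and ignores which gene
*combinations* co-occur in models; and the two-stage use of the full data
(selection, then evaluation on new splits of the same data) leaves the final
accuracy estimate slightly optimistic — an external cohort, prepared via
`collapse_probes` and a center covariate in every model, is the honest
check.
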