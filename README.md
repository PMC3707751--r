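# survsig

Discovery and validation of small prognostic gene-expression signatures for
right-censored cancer outcomes.

## The problem

Targeted expression panels (for example, a 32-gene qPCR panel measured in
breast-carcinoma biopsies, with overall survival and disease recurrence as
outcomes) pose a recurring analysis problem: among a modest number of
highly intercorrelated candidate genes, which subset carries reproducible
prognostic information, and does it add anything to standard clinical
covariates such as stage and hormone-receptor status? Single train/test
splits are unstable at cohort sizes of a few hundred patients, and stepwise
selection overfits badly on correlated panels.

`survsig` implements the resampling-based answer, end to end:

1. **Univariate screening.** One Cox proportional-hazards model
   `λ(t|x) = λ₀(t) exp(Σⱼ xⱼβⱼ)` per variable, with hazard ratios per unit
   log2 expression; gene p-values controlled by Benjamini–Yekutieli (valid
   under the dependence that correlated expression induces), clinical
   contrasts by Benjamini–Hochberg.
2. **Stability selection with a permutation threshold.** Over many
   stage-stratified 70/30 train/test splits, an L1-penalized Cox model
   (`max l(β) − λΣ|βⱼ|`, λ by 10-fold cross-validation) is fitted on each
   training set and the genes with nonzero coefficients are counted.
   Permutation replicates — outcome (time, event) pairs shuffled across
   patients, then one split + CV + fit — give a null count distribution;
   genes whose observed counts strictly exceed the highest permuted count
   are significant, and genes with inconsistent coefficient signs across
   splits are dropped from the final signature.
3. **Concordance-based model comparison.** The fixed signature, a clinical
   model, and their combination are re-fitted over fresh splits; test-set
   performance is Harrell's C, patients are stratified at the median
   training linear predictor into low/high risk classes with Kaplan–Meier
   curves, and differences between models are paired per-split contrasts
   with empirical 95% intervals.
4. **Diagnostics.** Residual-adjustment Cox models (`residual_cox`) explain
   why a gene that is marginally null can carry hazard after adjustment for
   a correlated block; `detectable_hr` evaluates the study-power formula
   `logHR = sqrt((z₁₋α + z₁₋β)² / (D·σ²))`; `interaction_scan` tests
   gene-by-clinical interactions.

A synthetic-cohort generator (`sim_config` / `generate_cohort`) reproduces
the data structure the analysis assumes — a positively intercorrelated
hormone-receptor gene block with one anti-correlated gene, ER-linked
expression shifts, proportional-hazards outcomes at ~30% events with
~60-month median follow-up, study-like clinical marginals and missingness —
so the whole pipeline is testable without access to any real cohort. The
Cox machinery (Newton fitting, coordinate-descent LASSO path, CV, C-index)
is implemented in the package with an Rcpp core and is cross-checked in the
test suite against `survival`, `glmnet` and brute-force oracles.

## Worked example

```r
library(survsig)

cohort <- generate_cohort(sim_config(seed = 42))
cohort
#> Cohort: 225 patients, 32 panel genes
#>   OS events: 74/225   DFS events: 83 (1 missing, 8 never disease-free)

scr <- univariate_screen(cohort, outcome = "os")
head(as.data.frame(scr)[, c("variable", "hr", "ci_lower", "ci_upper", "p", "p_adj")], 3)
#>   variable        hr  ci_lower  ci_upper          p p_adj
#> 1     ESR1 0.8628436 0.7613216 0.9779035 0.02089821     1
#> 2   TBC1D9 0.8736114 0.7762579 0.9831744 0.02499676     1
#> 3  SLC39A6 0.8655081 0.7612924 0.9839903 0.02734793     1

prof <- stability_selection(cohort, "os", n_splits = 50, n_perm = 50,
                            master_seed = 42)
prof
#> Stability selection (OS): 50/50 successful splits
#>   top selections: TBC1D9 (22.0%), ESR1 (20.0%), SLC39A6 (18.0%), BUB1 (12.0%), ...
#>   permutation threshold: 4 of 50 (8.0%)
#>   significant: TBC1D9, ESR1, SLC39A6, BUB1, CENPA
#>   signature: TBC1D9, ESR1, SLC39A6, BUB1, CENPA

ev <- compare_models(cohort, "os", gene_set = prof$signature,
                     n_splits = 50, master_seed = 42)
ev
#> Model comparison (OS), 50/50 successful splits
#>   genes    median C = 0.581 (95% CI 0.432-0.683), median low/high = 34/33
#>   clinical median C = 0.582 (95% CI 0.471-0.697), median low/high = 40/26
#>   combined median C = 0.635 (95% CI 0.509-0.713), median low/high = 35/31
#>   genes_vs_clinical      median dC = +0.005 (95% CI -0.269 to +0.152)
#>   combined_vs_clinical   median dC = +0.044 (95% CI -0.117 to +0.127)

rc <- residual_cox(cohort, "LRBA", c("PGR", "NAT1", "SLC39A6", "ESR1", "TBC1D9"), "os")
round(unlist(hazard_ratios(rc)), 3)
#>    hr lower upper
#> 1.126 0.976 1.298

detectable_hr(power_params())$hr
#> [1] 1.291486
```

Reading the output: the univariate screen flags the protective
hormone-receptor block (hazard ratios below 1 per log2 unit — about a 13%
hazard reduction per doubling of TBC1D9 expression — though none survive
the conservative BY adjustment at this cohort size and effect strength);
stability selection counts how often each gene survives the per-split
CV-LASSO, and the permutation threshold (here 4 of 50 splits, 8%) separates
five genes into the signature; the model comparison puts the gene signature
on par with the clinical model (median test C 0.58 for both) with a small
gain for the combined model. The LRBA residual hazard ratio (1.13) exceeds
its marginal one — the sign-flip diagnostic the generator plants by
construction — and `detectable_hr` gives the minimal hazard ratio (1.29 per
log2 unit) detectable with 80% power at the default design. The vignette
(`vignettes/signature-discovery.Rmd`) explains each quantity and every
tunable parameter.

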