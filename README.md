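# metabopress

Serum metabolite–blood pressure association analysis for chronic kidney
disease (CKD) cohorts.

Untargeted LC-MS metabolomics yields tens of thousands of serum features,
most of them redundant readouts (adducts, isotopologues) of far fewer
compounds, and in CKD patients any apparent metabolite–blood pressure
association is confounded by kidney function. `metabopress` implements the
full replication-design pipeline for this problem, for analysts who want to
run, audit, or stress-test each stage from R:

- **Stage coding** — systolic/diastolic readings classified into the five
  conventional blood pressure groups (coded 1–5), the 4-level display
  staging, and a normal/high dichotomization (`stage_bp()`).
- **Feature reduction** — greedy pivot-based correlation clustering: draw a
  random pivot, absorb every remaining feature with |Pearson r| > t
  (t = 0.45), repeat; keep one representative (the pivot/hub) per cluster
  (`correlation_cluster()`, `select_representatives()`).
- **Replication regression** — per feature, OLS of the BP code on the
  feature with a feature × CKD-stage interaction in the discovery cohort;
  features significant in both discovery and validation (α = 0.05) are
  *replicated*; replicated features are refit on the pooled cohorts with
  full clinical adjustment (CKD stage, eGFR, age, weight, BMI) and
  Benjamini–Hochberg corrected: for ranked p-values the adjusted value is
  `min_{j ≥ i} min(1, m p_(j) / j)` (`screen_features()`, `combined_fit()`,
  `bh_adjust()`).
- **Variance and discrimination accounting** — nested adjusted-R²
  trajectories (`cumulative_r2()`) and midrank Mann–Whitney ROC AUC
  (`roc_auc()`).
- **Ablation importance** — a seed-deterministic dense neural network
  predicts the BP stage from covariates + metabolites; each input is
  removed and the model retrained on the same split; the accuracy drop is
  the feature's importance (`train_classifier()`, `ablation_importance()`,
  `accuracy_curve()`).
- **Synthetic cohorts** — because real data of this kind are not publicly
  deposited, a first-class generator emulates the design: two cohorts of
  824/552 samples across six CKD strata, block-collinear log-normal
  features, covariates drawn per stratum, and blood pressure produced from
  a latent linear model with planted causal features (`sim_config()`,
  `simulate_cohorts()`).

All user-facing functions are data-frame-first and return tibbles; fitted
objects have `tidy()`/`glance()` methods and result types have
`autoplot()` displays.

## Worked example

```r
library(metabopress)

cfg <- sim_config(seed = 42)          # 824 + 552 samples, 200 features,
run <- run_pipeline(cfg, seed = 7)    # 50 blocks, 10 planted effects
run
#> <bp_run>
#>   cohorts: 824 discovery + 552 validation samples
#>   features: 200 -> 50 representatives (t = 0.45 )
#>   replicated: 8 | combined p < 0.05 : 8 | BH-adjusted < 0.05 : 8
```

The printout says: the 200 simulated LC-MS features collapsed to 50
cluster representatives at |r| > 0.45; eight representatives were
significant in both cohorts; all eight stayed significant in the pooled
covariate-adjusted model, before and after BH correction. Eight of the ten
planted signal clusters were recovered at this seed pair, with no false
positives. The association table mirrors the usual published layout:

```r
head(tibble::as_tibble(run$assoc), 3)[, c("feature_id", "p_discovery",
                                          "p_validation", "p_combined",
                                          "p_adjusted", "replicated")]
#> # A tibble: 3 x 6
#>   feature_id p_discovery p_validation p_combined p_adjusted replicated
#>   <chr>            <dbl>        <dbl>      <dbl>      <dbl> <lgl>
#> 1 F0023      0.000000812 0.00000426     4.88e-28   3.90e-27 TRUE
#> 2 F0030      0.000111    0.0000000322   3.79e-26   1.51e-25 TRUE
#> 3 F0033      0.00000109  0.00332        2.99e-24   7.97e-24 TRUE
```

A shipped reference table of 31 metabolites from a published two-cohort
CKD study (`read_reference_associations()`) provides a worked BH example:
recomputing `bh_adjust()` over its combined p-values reproduces the
published adjusted column to three significant figures, ten rows have
combined raw p < 0.05, and six survive BH at 0.05.

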