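# twinmeth

Twin-based epigenome-wide association and variance-component analysis in R.

`twinmeth` implements the statistical core of a twin EWAS of pubertal timing:
it relates DNA methylation measured in adulthood to pubertal development
scores and pubertal age collected in adolescence, using the twin design to
separate genetic from environmental contributions. Everything runs on a
seeded synthetic twin cohort with known ground truth, so each stage of the
pipeline can be validated end to end.

## What it does

- **Synthetic twin cohort** (`generate_cohort`, `cohort_config`): MZ/DZ
  families with a latent pubertal-timing liability under a configurable
  A/C/E decomposition, pubertal development scale (PDS) questionnaire items
  at two waves, censored pubertal-age reports, adult covariates (smoking,
  alcohol, blood cell proportions, array batch) and two overlapping
  methylation array panels.
- **Methylation simulation** (`cpg_spec`, `generate_methylation`): per-CpG
  beta values with exact classical twin covariance structure and optional
  phenotype linkage (individual-level causal, family-confounded, or
  genetic-confounded).
- **Family-aware EWAS** (`ewas_design`, `estimate_consensus_correlation`,
  `run_ewas`, `moderate_statistics`): per-CpG generalized least squares with
  a consensus within-pair residual correlation pooled across CpGs, plus
  empirical-Bayes variance moderation, AIC-vote covariate selection and
  robust bias/inflation diagnostics.
- **Dual-platform meta-analysis** (`run_meta_pipeline`): t statistics are
  converted to partial correlations, combined by inverse-variance fixed
  effects, and re-estimated by DerSimonian–Laird random effects where the
  Benjamini–Hochberg-corrected Cochran Q flags heterogeneity; hits are
  tiered at genome-wide and suggestive thresholds with an effect-size
  filter.
- **Twin variance-component models** (`fit_twin_model`,
  `select_best_model`, `check_candidate`): full-information maximum
  likelihood for ACE/ADE/AE/CE/DE/E with nonnegative paths, incomplete
  pairs, profile-likelihood confidence intervals, saturated-model
  assumption checks and likelihood-based model selection.
- **Sex differences** (`wilcoxon_sex_test`, `fit_sex_limitation`,
  `omnibus_sex_test`, `parameter_sex_tests`): rank tests on methylation
  plus five-group sex-limitation models testing quantitative (magnitude)
  and qualitative (different genes; opposite-sex genetic correlation rg)
  differences.
- **Discordant-pair analysis** (`fit_within_between`,
  `classify_discordance`): within/between-pair decomposition in a linear
  mixed model, classifying associations as environmentally driven when the
  within-pair signal is consistent in MZ pairs.
- **meQTL integration** (`generate_meqtl_table`, `count_meqtls`,
  `spearman_correlation`): genotype simulation that respects twin sharing,
  genome-wide significant meQTL counts, and their rank correlation with
  heritability.
- **Pipeline** (`pipeline_config`, `run_full_analysis`): one call that runs
  phenotype scoring, per-platform EWAS, meta-analysis, candidate selection
  and all follow-up stages, returning a `twinmeth_report`.

## Worked example

The classical twin model is the package's centrepiece: one fitting function
returning a classed object with the usual methods (`print`, `summary`,
`coef`, `logLik`, `vcov`, `confint`, `simulate`).

```r
library(twinmeth)

pairs <- simulate_twin_pairs(n_mz = 2500, n_dz = 2500,
                             r_mz = 0.89, r_dz = 0.78, seed = 7)
fit <- fit_twin_model(pairs, "ACE", covariates = character())
summary(fit)
#> Twin ACE model (FIML), logLik = -11114.66, 2500 MZ / 2500 DZ pairs
#>    a2    c2    d2    e2
#> 0.236 0.655 0.000 0.110
#> Total variance: 1.0054  AIC: 22237.31
#> Implied twin correlations: r_MZ = 0.890, r_DZ = 0.772

round(confint(fit), 3)
#>    lower upper
#> a2 0.209 0.264
#> c2 0.630 0.677
#> e2 0.104 0.116

select_best_model(pairs, covariates = character())
#> Best-fitting twin model: ACE
#>  model    loglik n_params      AIC         lrt_p
#>    ACE -11114.66        4 22237.31            NA
#>    ADE -11500.24        4 23008.48            NA
#>     AE -11500.24        3 23006.48 1.000818e-169
#>     CE -11278.74        3 22563.48  2.411969e-73
#>     DE -11860.45        3 23726.90 1.086787e-158
#>      E -14212.27        2 28428.54  0.000000e+00
```

With MZ pairs correlating 0.89 and DZ pairs 0.78, most of the variance is
attributed to the shared environment — the defining signature of pubertal
timing scores in twin data.

The full pipeline on a synthetic cohort with one causal CpG spiked among
nulls:

```r
specs <- c(list(cpg_spec("cg_causal", a2 = 0.6, c2 = 0.2, e2 = 0.2,
                         linkage_mode = "causal_individual",
                         linkage_beta = 0.35)),
           lapply(1:29, function(i) cpg_spec(sprintf("cg_null%02d", i),
                                             a2 = 0.5, c2 = 0.1, e2 = 0.4)))
cfg <- pipeline_config(cohort_config(n_families = 250), specs,
                       models = c("pds12_all", "pds14_all"))
report <- run_full_analysis(cfg, seed = 42)
#> 1 candidate CpG(s) at the suggestive tier
report
#> twinmeth analysis report (config 054f3e09, seed 42)
#>   models analysed: 2; candidate CpGs: 1
#>   twin-modelled CpGs: 1 eligible of 1

twin_table(report)
#>      cpg_id      r_mz      r_dz      mean        sd best_model heritability
#> 1 cg_causal 0.7804946 0.5596581 0.5524206 0.3010817        ACE    0.4857593
#>   shared_environment unique_environment
#> 1          0.3165969          0.1976439
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "twinmeth", load_package = "installed")'
```

The suite validates every module against independent oracles: `lm`/explicit
whole-covariance GLS, `limma::squeezeVar`, `metafor::rma`, brute-force
Benjamini–Hochberg, complete small-sample enumerations of the rank tests,
Falconer closed forms, direct bivariate-normal likelihood evaluation, and
type-I-error calibration of the family-aware EWAS under strong twin
clustering.

## Documentation

Function documentation is in the roxygen comments in `R/`; the methods
vignette (`vignettes/twin-ewas-methods.Rmd`) describes the model, the
synthetic-cohort design choices, numerical details and limitations.
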