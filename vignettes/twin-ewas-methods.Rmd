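---
title: "Methods: twin models and family-aware EWAS in twinmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin models and family-aware EWAS in twinmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in `twinmeth`,
the assumptions behind them, the design of the synthetic twin cohort, and
the numerical choices that matter when reproducing results.

## 1. The classical twin model

For a trait measured on both members of a twin pair, the phenotypic
variance is decomposed into additive genetic (A), shared-environment (C)
or dominance (D), and unique-environment (E) components. Writing the path
coefficients $a, c, d, e$ (so the component variances are their squares),
the expected cotwin covariance is

$$\mathrm{cov}(y_1, y_2) = k_A a^2 + k_C c^2 + k_D d^2,$$

with $(k_A, k_C, k_D) = (1, 1, 1)$ for monozygotic (MZ) pairs and
$(1/2, 1, 1/4)$ for dizygotic (DZ) pairs. C and D are not jointly
identifiable from MZ/DZ data alone, so the model families are ACE, ADE and
their submodels (AE, CE, DE, E).

`fit_twin_model()` maximizes the full-information bivariate-normal
likelihood over pairs (full information: incomplete pairs contribute
univariate terms instead of being dropped). Design decisions:

- **Nonnegative paths.** Path coefficients are bounded below by zero under
  `L-BFGS-B`, so standardized components are proper fractions and boundary
  solutions (for example $c^2 = 0$) are representable exactly.
- **Sufficient statistics.** Without mean-model covariates, the
  log-likelihood of each zygosity stratum depends on the data only through
  per-stratum sums ($n$, $\sum y_i$, $\sum y_i^2$, $\sum y_1 y_2$, plus the
  analogous singleton sums). Each likelihood evaluation is then O(1)
  regardless of sample size, which is what makes the replicate-heavy test
  suite and the acceptance script fast. With covariates (per-twin age, sex)
  the per-pair path is used.
- **Multi-start optimization.** Starting values come from the Falconer
  moment estimates ($a^2 \approx 2(r_{MZ} - r_{DZ})$,
  $c^2 \approx 2 r_{DZ} - r_{MZ}$) and are jittered for additional starts;
  the best converged solution wins.
- **Profile-likelihood intervals.** `confint()` profiles each path, locating
  the deviance crossing by bisection and converting the bound to a
  standardized share at the profile solution. A bound that cannot be
  bracketed before the path hits zero (or the search ceiling) is returned
  as `NA`; this is the expected outcome for components estimated at the
  boundary, not an error.

Model selection (`select_best_model()`) accepts a reduced model when its
likelihood-ratio test against the family's full model is non-significant,
prefers the most parsimonious accepted model within each family, and
arbitrates the ACE- and ADE-family winners by AIC. The assumption checks in
`check_candidate()` compare a saturated bivariate-normal model per zygosity
against versions with means or variances equated across twin order or
zygosity — the classical prerequisites for interpreting the variance
decomposition — and additionally require a minimum methylation SD, since
twin modelling of near-constant beta values is meaningless.

## 2. Sex-limitation models

`fit_sex_limitation()` fits the five-group model (MZ male, MZ female, DZ
male, DZ female, DZ opposite-sex) with sex-indexed means and paths. The
opposite-sex cotwin covariance is $r_g a_m a_f + c_m c_f$: the shared
environment is assumed fully shared across sexes, while the additive
genetic correlation $r_g$ is bounded in $[0, 0.5]$, with $0.5$ meaning the
same genes act in both sexes (the same-sex DZ value). Quantitative sex
differences are tested by equating parameters across sexes (the `"var"`
constraint equates the total variance while leaving its composition free,
implemented by deriving $e_f$ from the male total); the qualitative test
frees $r_g$ and compares against $r_g = 0.5$ by likelihood ratio. Because
$r_g$ is tested on the boundary of its range, the nominal chi-square
reference is conservative there; the test suite verifies the test stays
null when data are generated at $r_g = 0.5$ and fires when generated at
$r_g = 0$.

## 3. Family-aware EWAS

Per-CpG association models regress methylation on an exposure plus
covariates. Twin relatedness is handled by a consensus-correlation
strategy: ordinary least-squares residuals give a within-pair residual
correlation per CpG, these are pooled across CpGs by a 10% trimmed mean on
the Fisher-z scale, and every CpG is then fitted by generalized least
squares with that single correlation inside complete pairs. GLS is
implemented by whitening second pair members
($y_2^* = (y_2 - \rho y_1)/\sqrt{1 - \rho^2}$), which reproduces the
explicit whole-covariance solution exactly and reduces to OLS at
$\rho = 0$; both identities are asserted in the tests. The test suite also
checks calibration directly: with a within-pair correlation of 0.6 and a
null exposure, the fraction of CpGs with $p < 0.05$ stays near the nominal
level, whereas ignoring the correlation would not.

Residual variances are moderated by empirical Bayes before testing: the
log sample variances are moment-matched to a scaled inverse-chi-square
prior via digamma/trigamma identities (the trigamma inverse is computed by
a Newton iteration), giving prior degrees of freedom $d_0$ and scale
$s_0^2$, posterior variances $(d_0 s_0^2 + d s^2)/(d_0 + d)$ and a
moderated t on $d_0 + d$ degrees of freedom. The two limits are exact: at
$d_0 = 0$ the moderated t is the raw t; at $d_0 = \infty$ all variances
collapse to the pooled value and the reference becomes normal. The
implementation is cross-checked against `limma::squeezeVar` in the tests
but does not depend on limma.

Covariate-model choice uses a per-CpG AIC vote (ties to the smaller
design); test-statistic quality control uses robust surrogates — bias as
the median z-score and inflation as the normal-scaled median absolute
deviation — which are insensitive to the handful of true associations
present in a well-powered study.

## 4. Dual-platform meta-analysis

Per-platform t statistics are converted to partial correlations
$r = t/\sqrt{t^2 + \mathrm{df}}$ with sampling variance
$(1 - r^2)^2/\mathrm{df}$. Whether the intercept is counted when computing
the residual df from the coefficient count is ambiguous in published
descriptions; `count_intercept` exposes both conventions (default: count
it, i.e. df = n − p). Platforms are combined by inverse-variance fixed
effects; Cochran Q p-values are Benjamini–Hochberg corrected across CpGs
and CpGs with corrected Q p below 0.01 are re-estimated by
DerSimonian–Laird random effects. Significance is tiered at a strict
array-wide threshold (2.4e-7) and a suggestive threshold (1e-5), with an
absolute effect-size filter at 0.13.

## 5. Discordant-pair analysis

For candidate CpGs, the exposure is split into a between-pair predictor
(the pair mean) and a within-pair predictor (each twin's exposure minus the
cotwin's — the full difference, not half of it). Consequently an
individual-level causal effect $\beta$ appears as $\beta$ on the between
axis and $\beta/2$ on the within axis, while purely familial confounding
loads only on the between axis. The model
`y ~ between + within + covariates + (1 | family)` is fitted by REML via
`lme4`, with Wald normal tests. A CpG is classified as environmentally
driven when the pooled within-pair effect is significant, the MZ-only
within-pair effect is at least suggestive, and the two agree in sign — the
MZ condition is what excludes genetic confounding.

## 6. The synthetic cohort

The generator emulates a two-cohort twin study: pubertal development items
at ages 12 and 14 in the younger cohort, retrospective pubertal age in
both, blood methylation in adulthood on two overlapping array panels.
Every downstream stage sees only the observable tables; the latent truth
(per-individual A/C/E deviates and liability) is kept alongside for
validation.

Unstated population quantities were fixed once, before any testing, at
conventional values and are exposed as configuration:

- `mz_fraction = 1/3`: the MZ:DZ ratio is not pinned down by any published
  count for the emulated sample; one third is a conventional population
  value.
- `os_dz_fraction = 1/2`: opposite-sex pairs are half of DZ pairs, the
  Mendelian expectation.
- `rg_os = 0.5`: opposite-sex DZ genetic correlation at its null value, so
  the default cohort contains no qualitative sex difference.
- Pubertal-age means 12.9 (girls) and 13.9 (boys) with SD 1.2, censored at
  the questionnaire ("not yet" coded as the event occurring at 17), and a
  small missingness rate.

Methylation is generated Gaussian on the beta-value scale:
baseline + total_sd × (standardized A/C/D/E mixture), clamped to
(0.001, 0.999). A logistic latent scale would look more like real beta
distributions near the boundaries, but would distort the exact MZ/DZ
covariance algebra the twin models are validated against; capping
`total_sd` at 0.2 keeps clamping negligible (a warning fires if more than
1% of values clamp). Phenotype linkage is injected per CpG as
individual-level (causal), family-mean (shared-environment confounding) or
genetic-deviate (genetic confounding) terms, which is exactly the contrast
the discordant-pair classifier is designed to separate.

Random numbers are organized hierarchically: a master seed is hashed with
string/integer keys into independent 31-bit substreams (`derive_seed`),
one per cohort and one per CpG, so adding CpGs to a simulation never
perturbs the cohort or earlier CpGs. All generators save and restore the
caller's RNG state.

## 7. meQTL simulation

Genotypes are drawn for simulated parents and transmitted: MZ cotwins are
genetically identical, DZ cotwins receive independent transmissions.
Association tests use one twin per family, so the per-SNP p-values are
calibrated rather than inflated by family clustering; the tests verify
uniformity of the null p-values and recovery of spiked causal SNPs.
Genome-wide significant meQTLs are counted at p < 5e-8 (strict
inequality), and their relation to per-CpG heritability is summarized by a
Spearman rank correlation with midrank ties and a t approximation for the
p-value.

## 8. Limitations

- The twin models assume bivariate normality within zygosity groups;
  methylation beta values near 0 or 1 violate this, which is why the
  pipeline gates twin modelling on a minimum SD and on saturated-model
  assumption tests rather than fitting every CpG.
- The consensus correlation assumes a single within-pair residual
  correlation shared across CpGs and zygosities; CpGs with strong genetic
  control actually have higher MZ than DZ residual correlation, which the
  pooled value averages over.
- Profile-likelihood intervals are reported as `NA` at boundaries rather
  than switching to mixture (boundary-corrected) references; likewise the
  qualitative $r_g$ test uses the nominal chi-square reference, which is
  conservative on the boundary.
- The Wald normal tests in the discordant-pair mixed model ignore
  small-sample df corrections; with hundreds of pairs this is immaterial,
  but the p-values are approximate for small candidate sets.
- The meQTL module simulates unlinked SNPs with equal effects; linkage
  disequilibrium and allelic heterogeneity are out of scope.
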