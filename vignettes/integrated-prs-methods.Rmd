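---
title: "Methods: building and evaluating an integrated polygenic risk score"
author: "iprs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating an integrated polygenic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iprs)
```

## The scientific problem

Clinical 10-year cardiovascular risk is routinely estimated with
pooled-cohort-equation (PCE) style models: a proportional-hazards linear
predictor over age, sex, lipids, blood pressure, smoking, diabetes and
treatment status, converted to an absolute risk through a baseline
survival term. Polygenic risk scores (PRSs) summarize the genetic
contribution to the same disease as a weighted sum of allele dosages,
with weights derived from GWAS summary statistics. The question this
package operationalizes is whether an *integrated* PRS — a tuned linear
combination of several component PRSs built from several GWAS sources —
adds predictive value on top of the clinical equation, measured by
discrimination (Harrell's C, hazard ratios per SD), calibration
(decile tables, Greenwood-Nam-D'Agostino test), and reclassification
(categorical and continuous NRI, IDI) at the clinically used 7.5%
10-year risk threshold.

Because individual-level biobank data are access-restricted, the package
ships a synthetic-cohort generator that reproduces the *structure* of
such a study — multi-source GWAS summary statistics with sampling noise,
block-LD genotypes, a prevalent case–control tuning set, and incident
Weibull proportional-hazards outcomes — with recorded ground truth, so
every stage of the pipeline is testable for parameter recovery.

## Study design

The generated population is split the way tuning-plus-testing biobank
analyses are organized:

1. **Tuning set**: all prevalent cases (disease present at baseline,
   defined by a liability threshold) plus an equal number of controls
   drawn by simple random sampling. Used for AUC-based tuning of PRS
   candidates and for fitting the integration coefficients. Simple
   random sampling is used for controls; no frequency matching on age or
   sex is attempted, since nothing in the emulated design requires it.
2. **Testing cohort**: every remaining individual free of prevalent
   disease, followed prospectively for incident events under
   administrative censoring. Tuning and testing never overlap.

## The synthetic-data generator

`sim_config()` holds every generator knob; the defaults are the
package's declared study conditions and are not tuned per run.

* **Genotypes** (`sim_genotypes()`): a latent Gaussian threshold model.
  Each haplotype draws a latent normal equicorrelated within an LD block
  (`block_rho`, default 0.6 across 30 blocks of 20 variants) and
  independent across blocks; the alternate allele is carried when the
  latent value falls below the quantile of the variant's drawn MAF
  (uniform on 0.05–0.5). Dosages are the two-haplotype sum. Realized
  dosage correlation is attenuated relative to the latent correlation,
  so LD is always *measured on dosages* downstream — the clumping oracle
  and the summary-statistic generator both use the empirical dosage
  correlations, which keeps the two consistent by construction.
* **Effects and liability** (`sim_effects_and_liability()`):
  point-normal architecture — 10% of variants causal by default, i.i.d.
  normal effects rescaled so the genetic score variance is
  `h2_liability` (default 0.3). The liability is genetic score +
  clinical component (variance 0.1, carried by the same covariates that
  drive incident hazard, so prevalent and incident risk share both
  genetic and clinical axes) + independent noise topping the variance up
  to 1. Prevalent disease is liability above its empirical
  `1 - prevalence` quantile (default prevalence 6.5%).
* **Summary statistics** (`sim_sumstats()`): GWAS effects are
  *marginal*, so the reported true effect of variant *j* is the
  LD-weighted combination of causal effects in its block,
  \(b_j = \sum_k \beta_k \widehat{\mathrm{Cov}}(x_j, x_k) /
  \widehat{\mathrm{Var}}(x_j)\); this is what makes clumping meaningful
  in the synthetic world. Sampling noise has
  \(se_j = 1/(\mathrm{sd}(x_j)\sqrt{n})\) for a unit-variance phenotype;
  p-values are two-sided Wald. Three default source cohorts (n =
  180k/120k/160k) emulate two same-ancestry GWAS plus one
  cross-ancestry GWAS whose true effects are attenuated by 30%
  (`ancestry_shift`), the simplest defensible transfer model. A
  configurable fraction of variants is emitted on the opposite allele to
  exercise alignment.
* **Outcomes** (`sim_survival()`): Weibull proportional hazards,
  \(H(t\mid x) = (t/\lambda)^k e^{\mathrm{lp}}\) with shape 1.3, scale 90
  years, linear predictor `log(1.6)` per SD of genetic score plus the
  clinical log-hazard predictor; administrative censoring at 12 years
  (no competing risks — competing deaths are treated as censoring).

What the generator does **not** emulate: genotyping batch effects,
relatedness, population stratification and ancestry assignment,
non-administrative (dropout) censoring, and time-varying covariates. A
passing test suite therefore demonstrates correctness of the
*procedures* under a clean data-generating process, not robustness to
the artifacts of real cohort data.

## Summary-statistic processing

* **QC** (`qc_filter()`): INFO > 0.3, MAF > 1%, genotype-panel HWE p >
  1e-10, missing rate < 10%, strand-ambiguous (A/T, C/G) variants
  removed. All thresholds are strict inequalities, matching how they
  are conventionally printed. HWE and missingness are genotype-panel
  statistics, not summary-file columns: dosages carry no genotype
  counts, so hard calls are obtained by deterministic rounding before
  the 1-df chi-square test. Each filter is a per-variant predicate, so
  filtering is idempotent and order-independent; removals are tallied
  per filter.
* **Alignment** (`align_alleles()`): every record is forced onto the
  reference alternate allele; reversed records have beta negated and
  EAF complemented; records whose allele pair does not match the
  reference site are dropped and tallied. Aligning twice equals
  aligning once.
* **Meta-analysis** (`fixed_effect_meta()`): fixed-effect
  inverse-variance pooling with per-variant subset behavior (a variant
  present in a subset of studies is pooled over that subset — the
  convention of standard GWAS meta tools), sample sizes summed. How to
  pool EAF across studies is not standardized; the n-weighted mean is
  used and declared. No genomic control, heterogeneity statistics, or
  sample-overlap correction.

## PRS construction and integration

* **Clumping + thresholding** (`ld_clump()`, `ct_grid()`): greedy index
  scan by ascending p (ties broken by chromosome then position, for
  reproducibility), keeping a variant iff no kept same-chromosome
  variant within the window exceeds the r² threshold (dosage Pearson
  correlation squared on the designated LD panel; the tuning-set
  genotypes by default, any panel via argument). The default grid —
  p-thresholds {5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1},
  r² {0.1, 0.2, 0.5}, 250 kb windows — is a conventional C+T grid and
  fully config-overridable; it is declared, not derived from any
  external source. Bayesian shrinkage PRS methods are deliberately not
  re-implemented; their weight files enter through `read_weights()` as
  additional candidates.
* **Tuning** (`tune_grid()`): each candidate is scored on the tuning
  genotypes and entered into a logistic regression of case status with
  the baseline covariates (clinical risk linear predictor, plus any
  principal components or batch indicators supplied); the in-sample AUC
  of fitted probabilities ranks candidates, best per method/source
  kept. Ties break toward the simpler model (larger p-threshold, then
  larger r²). In-sample AUC on a dedicated tuning set mirrors the
  single-tuning-set design; a cross-validated mode was considered and
  left out to keep the tuning contract identical to the study design
  being emulated. Complete separation falls back to a
  ridge-stabilized IRLS fit (fixed penalty 1e-3, intercept
  unpenalized), flagged in the output.
* **Integration** (`forward_select_and_integrate()`): greedy forward
  selection on tuning AUC, stopping when the best increment is ≤
  `min_delta` (default 1e-4 — an exact-zero stopping rule is
  numerically fragile, and 1e-4 of AUC is far below any decision
  relevance). The final coefficients come from **one joint logistic
  fit** of the selected component scores (plus covariates); the
  integrated score is \(\sum_j \hat\beta_j \mathrm{PRS}_j\). Joint
  refitting, rather than accumulating stepwise coefficients, is what a
  single coefficient vector in the integration formula implies, and it
  guarantees the nested-model deviance property asserted in the tests.

## Clinical risk engine

`risk_equation()` is a generic PH absolute-risk engine: per-stratum
term lists (coefficient × transformed covariate, products for
interactions), a mean linear predictor for centering, and a 10-year
baseline survival; risk is \(1 - S_0^{\exp(\mathrm{LP} -
\overline{\mathrm{LP}})}\). Published coefficient values are *not*
embedded — they belong to external publications; a JSON template ships
in `inst/extdata/` and `read_risk_equation()` loads filled-in configs.
For synthetic studies, `sim_risk_equation()` plays the role of the
external publication by exposing the generator's true clinical log
hazard ratios as an equation. The classification boundary is declared
as risk ≥ threshold ⇒ high (the guideline phrase is ambiguous between
"greater than" and "at or above"; at-or-above is implemented and
tested). Race enters as a binary flag, matching the emulated equation's
convention. Out-of-range physiological values warn rather than error;
missing covariates error by name, since the emulated design excludes
such individuals upstream.

## Evaluation machinery

* **Cox fits** use `survival::coxph` with Efron tie handling (many ties
  at coarse time units) and Breslow-type baseline survival at the
  horizon.
* **Harrell's C** (`harrell_c()`) is computed by
  `survival::concordance`, with the asymptotic infinitesimal-jackknife
  standard error; a brute-force pair-enumeration oracle validates it in
  the tests. Bootstrap differences (`c_difference()`) compare nested
  models. C is computed over full follow-up; absolute risks, NRI and
  IDI use the fixed 10-year horizon.
* **Recalibration** (`recalibrate()`): Cox fit of the target outcomes
  on the fixed linear predictor (slope) plus the Breslow baseline at
  the horizon estimated in the target cohort.
* **GND test** (`gnd_test()`): deciles of predicted risk; per-decile
  KM observed probability with Greenwood variance; χ² =
  Σ(KM − mean predicted)²/Var, df = number of groups used. Deciles with
  fewer than 5 events are merged with a neighbor first — the published
  recommendation for the test's small-cell behavior. With externally
  specified (true) risks each cell contributes an asymptotically
  standard normal deviate, which is why the null distribution is χ²
  with df equal to the group count, and why the test suite can check
  p-value uniformity by simulation.
* **NRI/IDI** (`reclassification` functions): the count-based
  categorical NRI excludes individuals censored event-free before the
  horizon (tallying them), exactly mirroring the published accounting
  of cases/noncases/censored; the KM-adjusted variant instead estimates
  each movement cell's event probability by Kaplan-Meier and assembles
  the components by Bayes' rule, reducing *exactly* to the count-based
  version when nobody is censored early. Both are reported, labeled,
  because headline NRIs in the literature are frequently computed
  either way and the two differ under censoring. Continuous NRI and
  IDI follow the standard definitions. CIs are nonparametric bootstrap
  over individuals (default 1000 resamples, seeded).

## Numerical and reproducibility choices

* One global seed fans out to per-stage seeds through a fixed counter
  derivation (`stage_seed()`), so each stage is independently
  reproducible and identical configs give bit-identical outputs.
* Prevalence is imposed with the *empirical* liability quantile, so the
  realized prevalent fraction equals the configured one up to rounding.
* Clumping tie-breaks (equal p) use ascending chromosome/position;
  candidate ties in tuning break toward the simpler parameter pair.
* Degenerate inputs: empty clumping input returns an empty set; all-tied
  scores give C = 0.5; quintiles emptied by ties merge with a warning;
  all-censored simulated cohorts warn and are flagged.

## Problem sizes used by the packaged checks

The test suite and the acceptance script exercise the full pipeline at
n = 20000 individuals and 600 variants — large enough for stable
parameter recovery (HR per SD within 3 SEs, calibration slope within
[0.9, 1.1], C-statistic comparisons with bootstrap p-values) while
keeping a complete run in tens of seconds. Oracle-equivalence checks run
on hundreds of small random instances; null-distribution checks (GND
uniformity) use 500 replicates of n = 1000. These sizes are the
package's own reproducibility choices.

## Known limitations

* The synthetic world has clean block LD and no stratification, so C+T
  behaves better there than on real imputed data.
* In-sample tuning AUC mildly favors complex candidates; the forward
  selection stopping rule bounds but does not remove this optimism.
* The combined clinical+PRS model is fit on the testing cohort (as in
  tuning/testing biobank designs that refit the combination slope), so
  its calibration slope is exactly 1 by construction; the clinical
  model's slope is the informative one.
* KM-adjusted NRI assumes censoring independent of risk within
  movement cells.
* No competing-risks modeling; absolute risks are interpreted under
  censoring-as-independent assumptions.
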