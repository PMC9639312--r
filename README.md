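# iprs — integrated polygenic risk scores for clinical risk prediction

`iprs` implements, as a tested and reusable R pipeline, the construction
of an **integrated polygenic risk score** (PRS) from multiple GWAS
summary-statistic sources and its evaluation **on top of a
pooled-cohort-equation (PCE) style clinical risk model** in a
prospective cohort. It is aimed at biostatisticians and genetic
epidemiologists who want every step of such a study — from summary-stat
QC to net reclassification — as composable, unit-tested functions rather
than a chain of one-off scripts.

## What it computes

**PRS construction.** GWAS summary statistics are quality-filtered
(INFO > 0.3, MAF > 1%, HWE p > 1e-10, missingness < 10%,
strand-ambiguous A/T and C/G variants removed), aligned to a reference
alternate-allele convention, and combined across same-ancestry sources
by fixed-effect inverse-variance meta-analysis
(w<sub>i</sub> = 1/se<sub>i</sub>², β\* = Σw<sub>i</sub>β<sub>i</sub>/Σw<sub>i</sub>,
se\* = (Σw<sub>i</sub>)<sup>−1/2</sup>). Component PRSs are built
internally by LD **clumping and thresholding** (greedy index-variant
scan by ascending p, dosage-r² pruning within a window, then a p-value
cutoff grid) or imported from external weight files, and scored as
score<sub>i</sub> = Σ<sub>v</sub> w<sub>v</sub>·dosage<sub>iv</sub>.
Candidates are tuned by logistic-regression AUC on a prevalent
case–control **tuning set**, then greedily forward-selected; the
integrated score is **Σ<sub>j</sub> β̂<sub>j</sub>·PRS<sub>j</sub>** with
coefficients from one joint logistic fit.

**Clinical risk.** A generic proportional-hazards absolute-risk engine:
risk = 1 − S₀^exp(LP − mean LP), with per-stratum coefficients supplied
by configuration (no published coefficient values are embedded).

**Evaluation** on the independent testing cohort: Harrell's
C-statistic with asymptotic CIs and bootstrap model comparisons, hazard
ratios per SD, recalibration (testing-cohort baseline survival +
calibration slope), decile calibration with the
Greenwood–Nam–D'Agostino χ² test, per-quintile Kaplan–Meier cumulative
incidence with top/bottom fold ratios, and reclassification at the 7.5%
threshold: categorical NRI
(P(up|case) − P(down|case) − P(up|noncase) + P(down|noncase)) in both
count-based and Kaplan–Meier-adjusted forms, continuous NRI, and IDI.

**Synthetic cohorts.** Because the biobank data such studies use are
access-restricted, the package ships a first-class generator —
block-LD genotypes from a latent Gaussian threshold model, liability
-threshold prevalent disease, multi-cohort GWAS summary statistics with
sampling noise and allele flips, Weibull proportional-hazards incident
outcomes — with recorded ground truth, so parameter recovery is
testable end to end. See the methods vignette
(`vignettes/integrated-prs-methods.Rmd`) for the model and every
default.

## Worked example

```r
library(iprs)

cfg <- pipeline_config(
  sim = sim_config(n_individuals = 10000, seed = 2024),
  boot_B = 100
)
res <- run_pipeline(cfg)
print(res)
```

```
Integrated-PRS synthetic study
  tuning: 650 cases / 650 controls; testing: 8700 (751 events)
  integrated PRS: 1 component(s), tuning AUC 0.814
  C(prs) = 0.586 (95% CI 0.565-0.606)
  C(pce) = 0.692 (95% CI 0.674-0.710)
  C(pce_prs) = 0.710 (95% CI 0.692-0.728)
  delta C (PCE+PRS vs PCE) = 0.0175, one-sided bootstrap p = 0.0099
NRI (count-based): cases +0.0149, noncases +0.0145, overall +0.0294
```

The lines mean: out of 10,000 simulated individuals, the 650 prevalent
cases plus 650 random controls formed the tuning set and the remaining
8,700 disease-free individuals the testing cohort (751 incident events
over 12 years). AUC-based forward selection kept one
clumping-and-thresholding component. On the testing cohort the
integrated PRS alone discriminates modestly (C = 0.586), the clinical
model better (C = 0.692), and adding the PRS to the clinical model
raises the C-statistic by 0.0175 (one-sided bootstrap p = 0.0099) and
gives a positive overall net reclassification of +0.029 at the 7.5%
threshold.

Individual pieces are available directly, e.g.:

```r
print(res$evaluation$models$pce_prs)
#> C-statistic 0.710 (95% CI 0.692-0.728)
#> HR per SD 2.273 (95% CI 2.106-2.452)
#> Calibration slope 1.000; GND chi-sq 8.05 (df 10), p = 0.624
#> Top/bottom quintile incidence fold: 8.90
```

`write_report(res, "report.json")` serializes the whole comparison with
its configuration and seed.

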