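---
title: "Within-sibship Mendelian randomization: models, estimators and the family simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-sibship Mendelian randomization: models, estimators and the family simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instruments for an
exposure to estimate its causal effect on an outcome. For social and
behavioural exposures such as educational attainment, genetic association
estimates from samples of unrelated individuals are contaminated by three
mechanisms that have nothing to do with direct effects of inheriting an
allele:

* **population stratification** — ancestry is associated with both allele
  frequencies and phenotypes, distorting genotype–phenotype associations;
* **assortative mating** — mate choice on a heritable phenotype induces
  correlations between parental genotypes, and hence between otherwise
  independent trait-increasing alleles in offspring;
* **indirect parental genetic effects** — parental genotypes shape the
  rearing environment, so non-transmitted parental alleles associate with
  offspring phenotypes.

Genetic differences between full siblings arise from random segregation at
meiosis and are independent of all three mechanisms. A regression that
exploits only within-sibship genotype variation therefore yields genetic
association estimates robust to them, and MR built on such estimates
inherits that robustness. `sibmr` implements the full chain — association
models, polygenic score (PGS) construction, MR estimators, shrinkage and
meta-analysis — together with a family simulator in which all three
mechanisms are switched on or off at will, so every estimator has a
parameter-recovery test with known ground truth and no external data.

## Population and within-sibship models

For outcome $y_{ij}$ of sibling $i$ in sibship $j$ and exposure $x_{ij}$
(educational attainment, or an educational-attainment PGS):

* **population model**: $y_{ij} = \alpha + \beta_{Pop}\, x_{ij} + \varepsilon_{ij}$;
* **within-sibship model**: $y_{ij} = \alpha + \beta_{WS}\,(x_{ij} - \bar
  x_j) + \beta_B\, \bar x_j + \varepsilon_{ij}$,

where $\bar x_j$ is the sibship mean exposure. The coefficient on the
centred term is identified by within-family exposure differences only; the
sibship-mean covariate absorbs everything shared by siblings (parental
genotypes, rearing environment, ancestry). Both models cluster standard
errors by sibship with a sandwich estimator; `sibmr` uses the plain CR0
form (`sandwich::vcovCL(type = "HC0", cadjust = FALSE)`), with the
$G/(G-1)$ small-sample correction behind a flag (`small_sample = TRUE`).
For two-sibling families the within-sibship coefficient is algebraically
the sib-difference regression slope, which the tests verify to `1e-8`.

Mortality uses Cox proportional hazards with **age as the timescale**
(origin at date of birth). `entry_age > 0` is honoured as delayed entry by
default; `left_truncate = FALSE` reproduces the no-truncation behaviour,
since the source analyses do not state one. Ties use the Efron
approximation. The within-sibship Cox carries the centred and sibship-mean
terms in the linear predictor rather than stratifying: that mirrors the
linear-model construction, while the twin replication separately implements
pair-stratified baselines (`fit_twin_stratified_cox`), where only
exposure-discordant same-sex pairs carry information. For pairs with a
single event the stratified partial likelihood coincides with conditional
logistic regression, which the tests check against a hand-written
likelihood.

Exposures, continuous outcomes and the PGS are standardized after
residualizing on birth year and sex (`residualize_standardize`; the PGS on
age and sex, `prepare_pgs`). The SD uses the $n-1$ denominator — a
convention that had to be fixed for reproducibility. Analyses restrict to
sibships with two or more members after per-outcome complete-case
filtering (`min_sibship_size = 2`, relaxable to 1); every filter logs
before/after counts.

## Polygenic score

`clump()` performs PLINK-style greedy index-variant clumping: drop
$p \ge 5\times 10^{-8}$, then repeatedly take the smallest-$p$ survivor as
index and remove same-chromosome variants within 10 000 kb with
$r^2 \ge 0.001$. Boundary semantics are deliberately explicit (strict
$r^2 < 0.001$ survives; strict $p <$ threshold retained) and ties in $p$
break by (chrom, pos) so the output is invariant to input order. LD is
supplied as a matrix (or `identity_ld()` for unlinked variants), never
estimated from a reference panel; a variant pair inside a window with
unknown LD is an error rather than a silent assumption.
`compute_pgs()` forms $\sum_k \hat\beta_k\, d_{ik}$ with exact-string
allele harmonization (swapped alleles flip the dosage; anything else is an
error — strand flips and palindromic-frequency logic are intentionally
out of scope because the fixtures control their alleles).

## MR estimators

* **Wald ratio** (`wald_ratio`): $\hat\beta_{MR} = \hat\beta_{GY} /
  \hat\beta_{GX}$ with first-order delta SE
  $\sqrt{\sigma_Y^2/\beta_X^2 + \beta_Y^2 \sigma_X^2 / \beta_X^4}$,
  assuming zero covariance between numerator and denominator (the
  two-sample convention, kept in one-sample use; a $10^5$-draw parametric
  bootstrap in the tests quantifies the approximation at the 5% level).
* **Summary-level IVW** (`ivw`): over harmonized variants $k$,
  $$\beta_{MR} = \frac{\sum_k \beta_{EA,k}\,\beta_{Out,k}/\sigma_{Out,k}^2}
  {\sum_k \beta_{EA,k}^2/\sigma_{Out,k}^2},\qquad
  SE = \Big(\textstyle\sum_k \beta_{EA,k}^2/\sigma_{Out,k}^2\Big)^{-1/2},$$
  identical to weighted least squares of outcome betas on exposure betas
  through the origin. Two properties matter scientifically and are tested:
  the PGS Wald approach agrees with IVW on per-variant estimates from the
  same model, and multiplying both arms by a common factor leaves the
  estimate unchanged to `1e-12` — the reason balanced population-to-within
  attenuation of both arms preserves MR estimates.
* **Shrinkage** (`shrinkage`): $(\beta_{Pop} - \beta_{WS})/\beta_{Pop}$
  with a delta-method SE using both variances and their covariance. The
  two estimates share individuals, so independence is indefensible; the
  default pathway is a sibship-level paired bootstrap
  (`shrinkage_bootstrap`, B = 1000 by default in direct use, seeded) that
  supplies the covariance, with the bootstrap SD of the proportion kept as
  a check on the delta approximation. Passing no covariance assumes zero
  and warns. How the covariance should be treated is genuinely open in the
  source analyses; the bootstrap default is this package's resolution.
* **Fixed-effects meta-analysis** (`meta_fixed`): inverse-variance
  pooling; Cochran's Q reported, never acted on; mixing scales (log-HR vs
  SD) is an error. Cross-checked against `metafor::rma(method = "FE")` in
  the tests.

Binary outcomes are handled on the risk-difference scale through linear
probability models when needed; 95% CIs use 1.96 throughout.

## The family simulator

`sim_params()` + `simulate_cohort()` generate: parents (genotypes binomial
in subpopulation allele frequencies; exposure phenotype = genetic value +
subpopulation shift + noise), spouse pairing, meiotic transmission to
`sibs_per_family` siblings, phenotypes and exponential survival. The
offspring exposure liability is

$$L_i = \sum_j b_j x_{ij} + s \sum_j b_j\,(x^{mat}_{fj} + x^{pat}_{fj})
      + a_{k(f)} + c_f + e_i$$

with direct effects $b$, `indirect_scale` $s$ on the **parental dosage
sum** (transmitted plus non-transmitted alleles — the vehicle of indirect
parental effects), subpopulation shift $a_k$, family confounder $c_f$ and
noise. Using the parental sum rather than the midparent mean is a
deliberate choice: the population-level covariance between offspring score
and parental-sum score equals the score variance, so at $s = 1$ the
parental contribution to the population score–liability slope equals the
direct contribution — the population slope is $(1+s)\times$ the
within-sibship slope and the expected attenuation is $s/(1+s)$, i.e.
exactly one half at $s=1$. That gives the attenuation-recovery tests an
analytic target.

Design choices worth knowing:

* **Assortment** operates on the exposure phenotype via Gaussian-copula
  rank matching of spouses *within subpopulation*, giving direct control
  of the spousal correlation. Consequently `am_correlation` is the
  correlation conditional on subpopulation; with stratification active the
  marginal spousal correlation is higher because spouses also share
  ancestry. Both realized correlations are recorded. Calibration is tight:
  at a 0.4 target and 20 000 families the realized correlation lands
  within ±0.02.
* **One generation** of assortment is simulated — no multi-generation
  equilibrium. The induced sibling-score correlation above 0.5 and
  non-transmitted-allele associations are qualitatively correct but
  equilibrium magnitudes are not attempted.
* **Education years** are a threshold coarsening of the liability
  (default: empirical quartiles mapped to 10/12/13/16 years, a
  national-survey-style scheme). The cohort table also carries the
  continuous liability readout (`edu_cont`). Recovery analyses instrument
  the continuous measure so the estimand (effect per SD of liability)
  matches the generator's `causal_effects` exactly; instrumenting the
  coarsened years instead rescales estimates by the within-family
  years-on-liability slope — the liability-versus-measured-phenotype
  distinction inherent to categorical exposures, not an estimator defect.
* **Outcomes** are `causal * z(L) + c_f + a_k + noise`, reported on
  familiar raw scales (BMI-like 27 ± 4, pack-years-like 8 ± 6, SBP-like
  135 ± 18) via affine maps only, so re-standardization is lossless. The
  default outcome noise SD (0.85) keeps total outcome variance near 1
  under the default mechanism settings, making `causal_effects`
  approximately SD/SD; the truth ledger stores the exact realized SD-scale
  effects. Note the outcomes are confounded *directly* (confounder and
  ancestry shifts enter both liability and outcome), so the population
  phenotypic regression and population MR are both biased by design, while
  within-sibship estimators recover the truth.
* **Survival** is exponential with rate `baseline_hazard * exp(lp)`,
  `lp = causal_log_hr * z(L)` (+ optional confounder term), administrative
  censoring `censor_time` years after entry; memorylessness makes delayed
  entry exact. Defaults (0.02 events/person-year, 40-year horizon) give
  roughly half the cohort an event.
* Sex is Bernoulli(1/2) (shared within family for twin-style data),
  birth year uniform on a 20-year window; both are pure nuisance
  covariates.
* The `truth_ledger` (realized correlations, per-variant effects,
  liabilities, parental and non-transmitted scores) is consumed only by
  tests — estimators never see it.

What the simulator deliberately does **not** emulate: linkage
disequilibrium between causal variants (LD enters only through the
clumping test matrices), X-chromosome inheritance, imputation dosage
uncertainty, sibling-on-sibling indirect effects, participation/selection
bias, and multi-generation assortment equilibrium. Passing tests therefore
demonstrate estimator correctness under the modelled mechanisms, not
robustness to everything real cohorts contain. The relative magnitudes of
the three mechanisms are chosen for testability (each large enough to be
detected, none dominant), not calibrated to any cohort.

## Education coding and sibship inference

`edu_scheme()` maps reported qualifications to years of full-time
education, taking the highest qualification when several are reported and
coding unknown labels as missing, never erroring. Only a handful of
anchor assignments are externally sourced (degree 17 and A-levels 14 in
the UK-style scheme; 10/12/13/16 in the Norwegian-style scheme; the 4- and
17-year endpoints of the Finnish twin scheme); the remaining categories
carry conventional values and are trivially replaceable via a custom
mapping or a two-column file.

`infer_sibships()` applies KING-style full-sibling criteria — kinship in
[0.177, 0.355], IBD2 share > 0.08 and IBD0 share > 0.04 (the IBD0
criterion excludes parent–offspring pairs, which share one allele
essentially everywhere) — and takes connected components of the
sibling-pair graph as sibships. Thresholds are arguments, so an
IBS0-based variant is the same interface with different numbers.

## The pipeline

`run_config()` + `run_pipeline()` wire the stages together for one or more
cohorts: simulate, standardize, discovery GWAS of the exposure **in the
parental generation of the first cohort** (a sample disjoint from all
sibling analyses, mirroring a siblings-excluded discovery design), clump,
score, fit population and within-sibship models per outcome for both the
phenotypic exposure and the PGS, then meta-analyse the PGS associations
across cohorts and form Wald-ratio MR *from the meta-analysed PGS
estimates* (meta before ratio — the alternative order is a one-line
change but the default matches the source design), plus summary IVW from
per-variant estimates meta-analysed per variant. Shrinkage is reported
per cohort with the bootstrap covariance and at the meta level with zero
covariance (cohorts are independent, but the population/within pair within
each still shares individuals; the zero-covariance meta-level figure is
logged as an approximation). Everything is a pure function of the
configuration: cohort seeds are derived from the master seed, and two runs
of the same config produce bitwise-identical output files.

Problem sizes used by the test suite and the acceptance script are chosen
as sensible desk-scale defaults: 25 000 sibling pairs x 100 variants for
recovery under full confounding, 15 000 pairs for attenuation and
survival, 8 000 twin pairs for the stratified Cox, 200 replicates of
1 200 pairs for CI calibration. At those sizes the Monte Carlo error of
each check is several times smaller than the effect being verified.

## Known limitations

* The within-sibship PGS analyses use discovery weights from a population
  GWAS; with indirect effects present such weights are themselves shifted,
  which is exactly the attenuation the shrinkage statistic measures — the
  package quantifies it rather than correcting it.
* Pleiotropy-robust estimators (MR-Egger, median/mode), multivariable MR,
  Steiger filtering and sample-overlap corrections are out of scope.
* The one-sample Wald SE omits the numerator–denominator covariance; the
  bootstrap comparison bounds the error at the settings tested.
* Zygosity is an input label; no classification algorithm is provided.
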