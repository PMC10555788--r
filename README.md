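# sibmr

Within-sibship Mendelian randomization (MR) in R: association models that
isolate within-family genetic variation, polygenic-score and summary-level
MR estimators, shrinkage and meta-analysis, and a family simulator with
known causal structure for end-to-end validation.

## Why

MR uses genetic variants as instruments for an exposure (here: liability
to educational attainment) to estimate causal effects on health outcomes
(BMI, smoking, blood pressure, mortality). Genetic association estimates
from unrelated individuals are distorted by population stratification,
assortative mating and indirect parental genetic effects. Genetic
differences between full siblings come from random segregation at meiosis
and are immune to all three, so models that use only within-sibship
genotype variation yield cleaner instruments.

The two association models, for sibling *i* in sibship *j*:

* population: `y_ij = a + b_pop * x_ij + e_ij`
* within-sibship: `y_ij = a + b_ws * (x_ij - xbar_j) + b_b * xbar_j + e_ij`

with standard errors clustered by sibship (CR0 sandwich), linear for
continuous outcomes and Cox on an age timescale for mortality (plus a
twin-pair-stratified Cox for twin data). The MR layer provides the Wald
ratio with delta-method SE, the inverse-variance-weighted (IVW) estimator

```
b_MR = sum_k( bEA_k * bOut_k / sOut_k^2 ) / sum_k( bEA_k^2 / sOut_k^2 )
SE   = 1 / sqrt( sum_k( bEA_k^2 / sOut_k^2 ) )
```

population-to-within-sibship shrinkage `(b_pop - b_ws)/b_pop` with a
delta-method SE fed by a sibship-level paired bootstrap, and fixed-effects
meta-analysis across cohorts. The polygenic score is built from clumped
genome-wide-significant variants (r² < 0.001, 10 000 kb, p < 5e-8) and
standardized after residualizing on age and sex.

The bundled simulator (`sim_params()` / `simulate_cohort()`) generates
multi-sibling cohorts in which stratification, assortative mating
(Gaussian-copula spouse matching), indirect parental effects, a family
confounder and the true causal effect are all configurable, with a truth
ledger read only by tests. See the methods vignette
(`vignettes/within-sibship-mr.Rmd`) for the generative model and all
numerical conventions.

## Worked example

Simulate 10 000 sibling pairs with all three bias mechanisms active and a
true effect of -0.2 SD BMI per SD of liability, then compare estimators:

```r
library(sibmr)
params <- sim_params(n_families = 10000, n_variants = 50,
                     am_correlation = 0.4, indirect_scale = 1,
                     causal_effects = c(bmi = -0.2), seed = 2024)
sim <- simulate_cohort(params)
cohort <- sim$cohort
cohort$edu   <- residualize_standardize(cohort$edu_cont, cohort$birth_year, cohort$sex)
cohort$z_bmi <- residualize_standardize(cohort$bmi, cohort$birth_year, cohort$sex)

fit_population(cohort, "edu", model_spec("z_bmi"))
#> population model, z_bmi ~ phenotype: beta = 0.0181 (SE 0.0078, 95% CI 0.0028, 0.0335)
fit_within_sibship(cohort, "edu", model_spec("z_bmi"))
#> within_sibship model, z_bmi ~ phenotype: beta = -0.2318 (SE 0.0160, 95% CI -0.2632, -0.2003)

gx <- gwas_scan(cohort, sim$dosages, "edu",   model = "within_sibship")
gy <- gwas_scan(cohort, sim$dosages, "z_bmi", model = "within_sibship")
ivw(harmonize_sumstats(gx, gy), model = "within_sibship", outcome = "bmi")
#> MR (ivw_summary, within_sibship model): estimate = -0.2352 (SE 0.0356, 95% CI -0.3049, -0.1654)

fit_cox_mortality(cohort, "edu", "within_sibship")
#> within_sibship model, mortality ~ phenotype: log-HR = -0.1369 (SE 0.0256, ...)
#>   HR = 0.8721 (95% CI 0.8295, 0.9169)
```

The population regression is badly biased (+0.02, wrong sign) by the
family confounder and ancestry shifts, while the within-sibship phenotypic
and IVW estimates recover the simulated -0.2 within sampling error, and
the within-sibship Cox recovers the simulated mortality hazard ratio
(truth 0.90) within sampling error.

An end-to-end multi-cohort run (simulate, PGS from a parental discovery
GWAS, all model fits, cross-cohort meta, Wald and IVW MR, shrinkage) is one
call: `run_pipeline(run_config(...))`, or from the shell via
`exec/sibmr run --config cfg.yaml --out results/`.

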