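test_that("subpopulation allele frequencies diverge as configured", {
  p <- sim_params(n_families = 5000L, n_variants = 10L, n_subpops = 2L,
                  freq_divergence = 0.1, seed = 3L)
  pa <- simulate_parents(p, seed = 3L)
  dos <- rbind(pa$mother, pa$father)
  sp <- rep(pa$subpop, 2L)
  f1 <- colMeans(dos[sp == 1L, , drop = FALSE]) / 2
  f2 <- colMeans(dos[sp == 2L, , drop = FALSE]) / 2
  # configured offsets are -0.1 and +0.1 around the base frequency
  expect_equal(unname(f2 - f1), rep(0.2, 10L), tolerance = 0.05)
})

test_that("spousal phenotype correlation hits the assortment target", {
  # independence case: |r| below 3 Monte Carlo SEs
  p0 <- sim_params(n_families = 2000L, n_variants = 20L, am_correlation = 0,
                   strat_shift = 0, freq_divergence = 0, seed = 1L)
  pa0 <- simulate_parents(p0, seed = 1L)
  expect_lt(abs(pa0$realized_spousal_r), 3 / sqrt(2000))

  # copula-matched case: realized r within +/-0.02 of the 0.4 target
  p <- sim_params(n_families = 20000L, n_variants = 20L, am_correlation = 0.4,
                  strat_shift = 0, freq_divergence = 0, seed = 2L)
  pa <- simulate_parents(p, seed = 2L)
  expect_equal(pa$realized_spousal_r, 0.4, tolerance = 0.02 / 0.4)

  # with stratification on, the within-subpopulation correlation is the
  # targeted quantity and the marginal one is larger
  p2 <- sim_params(n_families = 20000L, n_variants = 20L, am_correlation = 0.4,
                   seed = 4L)
  pa2 <- simulate_parents(p2, seed = 4L)
  expect_equal(pa2$realized_spousal_r_within, 0.4, tolerance = 0.06)
  expect_gt(pa2$realized_spousal_r, pa2$realized_spousal_r_within)
})

test_that("meiotic transmission follows Mendelian expectations", {
  p <- tiny_params(n_variants = 1L)
  pa <- simulate_parents(p, seed = 5L)

  # homozygote parent pairs are deterministic
  pa00 <- pa; pa00$mother[] <- 0L; pa00$father[] <- 0L
  off <- transmit_genotypes(pa00, 2L, seed = 1L)
  expect_true(all(off$dosage == 0L))
  pa22 <- pa; pa22$mother[] <- 2L; pa22$father[] <- 2L
  off <- transmit_genotypes(pa22, 2L, seed = 1L)
  expect_true(all(off$dosage == 2L))

  # double heterozygote: offspring dosage ~ (1/4, 1/2, 1/4)
  pa11 <- pa; pa11$mother <- matrix(1L, 4000, 1); pa11$father <- matrix(1L, 4000, 1)
  pa11$fid <- sprintf("F%05d", 1:4000)
  pa11$params$n_families <- 4000L
  off <- transmit_genotypes(pa11, 2L, seed = 6L)
  tab <- tabulate(off$dosage + 1L, 3L) / length(off$dosage)
  expect_equal(tab, c(0.25, 0.5, 0.25), tolerance = 0.05)

  # sib-sib dosage correlation ~ 0.5 per variant when parental genotypes
  # vary across families (fixed double-het parents leave no between-family
  # variance, so there the correlation is 0 by design)
  p5 <- tiny_params(n_families = 4000L, n_variants = 5L, am_correlation = 0)
  sim5 <- simulate_cohort(p5)
  r <- vapply(1:5, function(j) {
    cor(sim5$dosages[sim5$offspring$sib_index == 1L, j],
        sim5$dosages[sim5$offspring$sib_index == 2L, j])
  }, numeric(1))
  expect_equal(mean(r), 0.5, tolerance = 0.06)

  # fractional dosages are rejected
  pa_bad <- pa; pa_bad$mother[1, 1] <- 0.7
  expect_error(transmit_genotypes(pa_bad, 2L), "hard calls")
})

test_that("assortative mating inflates sibling genetic-score sharing", {
  base <- list(n_families = 4000L, n_variants = 30L, n_subpops = 1L,
               freq_divergence = 0, strat_shift = 0, indirect_scale = 0,
               family_confounder_sd = 0, exposure_noise_sd = 0.3,
               h2_direct = 0.8, seed = 11L)
  sib_score_cor <- function(am) {
    p <- do.call(sim_params, c(base, list(am_correlation = am)))
    sim <- simulate_cohort(p)
    g <- drop(sim$dosages %*% p$direct_effects)
    s1 <- g[sim$offspring$sib_index == 1L]
    s2 <- g[sim$offspring$sib_index == 2L]
    cor(s1, s2)
  }
  r0 <- sib_score_cor(0)
  r6 <- sib_score_cor(0.6)
  expect_equal(r0, 0.5, tolerance = 3 * 0.016 / 0.5)
  expect_gt(r6, 0.52)
})

test_that("non-transmitted parental score associates with exposure only under
           indirect effects or assortment", {
  slope_t <- function(...) {
    p <- do.call(sim_params, c(list(n_families = 3000L, n_variants = 20L,
                                    n_subpops = 1L, freq_divergence = 0,
                                    strat_shift = 0, family_confounder_sd = 0,
                                    h2_direct = 0.5, seed = 12L), list(...)))
    sim <- simulate_cohort(p)
    fit <- lm(sim$cohort$edu_cont ~ sim$truth$nontransmitted_pgs)
    summary(fit)$coefficients[2, c("Estimate", "t value")]
  }
  off <- slope_t(am_correlation = 0, indirect_scale = 0)
  ind <- slope_t(am_correlation = 0, indirect_scale = 1)
  am <- slope_t(am_correlation = 0.6, indirect_scale = 0)
  expect_lt(abs(off["t value"]), 3)
  expect_gt(ind["t value"], 5)
  expect_gt(am["t value"], 3)
})

test_that("true-weight polygenic score recovers the exposure slope in the
           mechanism-free scenario", {
  p <- clean_params(n_families = 4000L, n_variants = 20L, seed = 13L)
  sim <- simulate_cohort(p)
  g <- drop(sim$dosages %*% p$direct_effects)
  fit <- lm(sim$cohort$edu_cont ~ g)
  se <- summary(fit)$coefficients[2, 2]
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 3 * se)
})

test_that("equal direct and parental contributions halve the within-sibship
           score-exposure slope relative to the population slope", {
  p <- sim_params(n_families = 10000L, n_variants = 30L, n_subpops = 1L,
                  freq_divergence = 0, strat_shift = 0, am_correlation = 0,
                  indirect_scale = 1, seed = 14L)
  sim <- simulate_cohort(p)
  ch <- sim$cohort
  g <- drop(sim$dosages %*% p$direct_effects)
  sp <- model_spec("edu_cont")
  bp <- fit_population(ch, g, sp)$beta
  bw <- fit_within_sibship(ch, g, sp)$beta
  expect_equal(bw / bp, 0.5, tolerance = 0.08)
})

test_that("exponential survival generator matches its parameters", {
  p <- tiny_params(n_families = 5000L, baseline_hazard = 0.05,
                   censor_time = 1e6)
  surv <- simulate_survival(rep(0, 10000), p, seed = 15L)
  expect_equal(mean(surv$exit_age), 1 / 0.05, tolerance = 0.05)
  expect_true(all(surv$event == 1L))

  # population Cox recovers a configured log hazard ratio
  p2 <- sim_params(n_families = 10000L, n_variants = 20L, n_subpops = 1L,
                   freq_divergence = 0, strat_shift = 0, am_correlation = 0,
                   indirect_scale = 0, family_confounder_sd = 0,
                   causal_log_hr = log(0.8), seed = 16L)
  sim <- simulate_cohort(p2)
  ch <- sim$cohort
  est <- fit_cox_mortality(ch, std_exposure(ch), "population")
  expect_equal(est$beta, log(0.8), tolerance = 3 * est$se / abs(log(0.8)))

  # degenerate censoring: no events, Cox refuses
  p3 <- tiny_params(censor_time = 0)
  sim3 <- simulate_cohort(p3)
  expect_true(all(sim3$cohort$event == 0L))
  expect_error(fit_cox_mortality(sim3$cohort, std_exposure(sim3$cohort),
                                 "population"),
               "no events")
})

test_that("population and within-sibship models agree when every mechanism is
           off", {
  p <- clean_params(n_families = 4000L, n_variants = 20L, seed = 17L)
  sim <- simulate_cohort(p)
  ch <- sim$cohort
  x <- std_exposure(ch)
  sp <- model_spec("bmi")
  ch$z_bmi <- std_outcome(ch, "bmi")
  sp <- model_spec("z_bmi")
  bp <- fit_population(ch, x, sp)
  bw <- fit_within_sibship(ch, x, sp)
  expect_equal(bp$beta, bw$beta, tolerance = 3 * bw$se / max(abs(bp$beta), 0.05))
})

test_that("simulation is fully determined by parameters and seed", {
  p <- tiny_params(seed = 99L)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$dosages, s2$dosages)

  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  write_fixture(s1, d1, seed = 7L)
  write_fixture(s2, d2, seed = 7L)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(sim_params(base_allele_freq = 0.005), "0.01")
  expect_error(sim_params(freq_divergence = 0.5), "divergence")
  expect_error(sim_params(am_correlation = 1), "am_correlation")
  expect_error(sim_params(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_params(education_thresholds = c(1, 1, 2),
                          education_years_map = c(10, 12, 13, 16)),
               "increasing")
  expect_error(sim_params(sibs_per_family = 1), "sibs_per_family")
})
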