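fake_est <- function(beta, se, model = "population", scale = "sd") {
  structure(list(beta = beta, se = se, model = model, scale = scale,
                 outcome = "y"), class = "assoc_estimate")
}

test_that("Wald ratio point estimate and delta SE follow the formulas", {
  # identity instrument passes the outcome estimate through
  wr <- wald_ratio(fake_est(1, 1e-12), fake_est(0.17, 0.03))
  expect_equal(wr$estimate, 0.17, tolerance = 1e-9)
  expect_equal(wr$se, 0.03, tolerance = 1e-6)

  # null outcome: estimate 0, SE = se_y / |beta_x|
  wr0 <- wald_ratio(fake_est(0.5, 0.05), fake_est(0, 0.02))
  expect_equal(wr0$estimate, 0)
  expect_equal(wr0$se, 0.02 / 0.5)

  # generic case matches the closed form
  wr2 <- wald_ratio(fake_est(0.5, 0.05), fake_est(0.12, 0.02))
  expect_equal(wr2$estimate, 0.24)
  expect_equal(wr2$se, sqrt(0.02^2 / 0.5^2 + 0.12^2 * 0.05^2 / 0.5^4))

  expect_error(wald_ratio(fake_est(0, 0.05), fake_est(0.1, 0.02)), "zero")
  expect_error(wald_ratio(fake_est(0.5, 0.05, model = "population"),
                          fake_est(0.1, 0.02, model = "within_sibship")),
               "different models")
})

test_that("Wald delta SE agrees with a parametric bootstrap", {
  set.seed(51)
  bx <- rnorm(1e5, 0.5, 0.05)
  by <- rnorm(1e5, 0.12, 0.02)
  wr <- wald_ratio(fake_est(0.5, 0.05), fake_est(0.12, 0.02))
  expect_equal(wr$se, sd(by / bx), tolerance = 0.05)
})

test_that("IVW reproduces the printed-formula arithmetic and the WLS
           oracle", {
  # hand-evaluated two-variant case: numerator 120, denominator 500
  s2 <- data.frame(beta_exp = c(0.1, 0.2), beta_out = c(0.02, 0.05),
                   se_out = c(0.01, 0.01))
  est <- ivw(s2, model = "within_sibship")
  expect_equal(est$estimate, 120 / 500)
  expect_equal(est$se, 1 / sqrt(500))

  # single variant reduces to the Wald ratio with the exposure arm exact
  s1 <- data.frame(beta_exp = 0.4, beta_out = 0.1, se_out = 0.05)
  e1 <- ivw(s1)
  expect_equal(e1$estimate, 0.25)
  expect_equal(e1$se, 0.05 / 0.4)

  # exact proportionality is recovered exactly
  sp <- data.frame(beta_exp = runif(10, 0.05, 0.3))
  sp$beta_out <- -0.37 * sp$beta_exp
  sp$se_out <- runif(10, 0.01, 0.05)
  expect_equal(ivw(sp)$estimate, -0.37, tolerance = 1e-12)

  # random 50-variant set equals weighted regression through the origin
  set.seed(52)
  sr <- data.frame(beta_exp = rnorm(50, 0, 0.1), beta_out = rnorm(50, 0, 0.05),
                   se_out = runif(50, 0.005, 0.05))
  wls <- lm(beta_out ~ 0 + beta_exp, data = sr, weights = 1 / sr$se_out^2)
  expect_equal(ivw(sr)$estimate, coef(wls)[["beta_exp"]], tolerance = 1e-10)

  # SE shrinks monotonically as variants accumulate
  ses <- vapply(2:50, function(k) ivw(sr[1:k, ])$se, numeric(1))
  expect_true(all(diff(ses) < 0))

  expect_error(ivw(sr[0, ]), "empty")
  bad <- sr; bad$se_out[3] <- 0
  expect_error(ivw(bad), "positive")
})

test_that("multiplying both GWAS arms by the same factor leaves the IVW
           estimate unchanged", {
  set.seed(53)
  sr <- data.frame(beta_exp = rnorm(40, 0.1, 0.03),
                   beta_out = rnorm(40, -0.02, 0.01),
                   se_out = runif(40, 0.005, 0.02))
  full <- ivw(sr)
  for (c_ in c(0.5, 0.25, 0.9)) {
    att <- sr
    att$beta_exp <- c_ * att$beta_exp
    att$beta_out <- c_ * att$beta_out
    expect_equal(ivw(att)$estimate, full$estimate, tolerance = 1e-12)
  }
})

test_that("allele harmonization aligns or rejects summary-statistic arms", {
  ex <- data.frame(snp = c("v1", "v2", "v3"), ea = c("A", "A", "A"),
                   oa = c("G", "G", "G"), beta = c(0.1, 0.2, 0.15),
                   se = c(0.01, 0.01, 0.01), model = "within_sibship")
  out <- ex
  out$beta <- c(0.02, -0.05, 0.01)
  out$ea[2] <- "G"; out$oa[2] <- "A"  # swapped labels
  h <- harmonize_sumstats(ex, out)
  expect_equal(h$beta_out, c(0.02, 0.05, 0.01))
  expect_equal(attr(h, "model"), "within_sibship")

  out$ea[3] <- "T"
  expect_error(harmonize_sumstats(ex, out), "v3")
  out$ea[3] <- "A"
  out$model <- "population"
  expect_error(harmonize_sumstats(ex, out), "mix")
})

test_that("shrinkage proportion and delta SE behave as the formula dictates", {
  expect_equal(shrinkage(fake_est(0.2, 0.01), fake_est(0.2, 0.01), 0)$proportion, 0)
  expect_equal(shrinkage(fake_est(0.2, 0.01), fake_est(0, 0.01), 0)$proportion, 1)
  sh <- shrinkage(fake_est(0.10, 0.01), fake_est(0.05, 0.01), 0)
  expect_equal(sh$proportion, 0.5)
  expect_equal(sh$se, sqrt((0.05^2 / 0.10^4) * 1e-4 + 1e-4 / 0.10^2))

  # positive covariance reduces the variance of the difference
  sh2 <- shrinkage(fake_est(0.10, 0.01), fake_est(0.05, 0.01), 5e-5)
  expect_lt(sh2$se, sh$se)

  expect_warning(shrinkage(fake_est(0.1, 0.01), fake_est(0.05, 0.01)),
                 "assuming 0")
  expect_error(shrinkage(fake_est(0, 0.01), fake_est(0.05, 0.01), 0), "zero")
})

test_that("sibship bootstrap covariance feeds a delta SE close to the
           bootstrap SD of the proportion", {
  p <- sim_params(n_families = 3000L, n_variants = 20L, n_subpops = 1L,
                  freq_divergence = 0, strat_shift = 0, am_correlation = 0,
                  indirect_scale = 1, seed = 61L)
  sim <- simulate_cohort(p)
  ch <- sim$cohort
  ch$pgs <- prepare_pgs(compute_pgs(sim$dosages, data.frame(
    snp = sim$variants$snp, beta = p$direct_effects, ea = "A", oa = "G")),
    age = 2000 - ch$birth_year, sex = ch$sex)
  ch$x <- std_exposure(ch)
  sh <- shrinkage_bootstrap(ch, "pgs", "x", B = 400L, seed = 62L)
  # true attenuation s/(1+s) = 0.5 at indirect_scale 1
  expect_equal(sh$proportion, 0.5, tolerance = 0.15)
  expect_equal(sh$se, sh$boot_sd, tolerance = 0.1)
})

test_that("fixed-effects meta-analysis pools by inverse variance", {
  e <- fake_est(0.2, 0.1)
  m1 <- meta_fixed(list(e))
  expect_equal(m1$beta, 0.2)
  expect_equal(m1$se, 0.1)

  m2 <- meta_fixed(list(e, fake_est(0.2, 0.1)))
  expect_equal(m2$beta, 0.2)
  expect_equal(m2$se, 0.1 / sqrt(2))

  set.seed(63)
  b <- rnorm(5); s <- runif(5, 0.05, 0.2)
  m5 <- meta_fixed(lapply(seq_len(5), function(i) fake_est(b[i], s[i])))
  w <- 1 / s^2
  expect_equal(m5$beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(m5$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_lte(m5$se, min(s))

  # independent cross-check against the standard meta-analysis package
  rma <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m5$beta, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(m5$se, rma$se, tolerance = 1e-8)

  expect_error(meta_fixed(list(e, fake_est(0.1, 0.1, scale = "log_hr"))),
               "different scales")
})
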