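make_linear_cohort <- function(n_fam, beta = 0.3, icc = 0, seed = 1,
                               sibs = 2L, x_icc = 0) {
  set.seed(seed)
  n <- n_fam * sibs
  fid <- rep(sprintf("f%05d", seq_len(n_fam)), each = sibs)
  x <- sqrt(x_icc) * rep(rnorm(n_fam), each = sibs) +
    sqrt(1 - x_icc) * rnorm(n)
  fam_eff <- rep(rnorm(n_fam, 0, sqrt(icc)), each = sibs)
  y <- beta * x + fam_eff + rnorm(n, 0, sqrt(1 - icc))
  structure(data.frame(iid = paste0(fid, "_", rep(seq_len(sibs), n_fam)),
                       fid = fid, x = x, y = y, stringsAsFactors = FALSE),
            class = c("cohort_table", "data.frame"))
}

test_that("population slope on doubly standardized data is the Pearson
           correlation", {
  ch <- make_linear_cohort(500, seed = 2)
  ch$x <- as.numeric(scale(ch$x))
  ch$y <- as.numeric(scale(ch$y))
  est <- fit_population(ch, "x", model_spec("y"), min_sibship_size = 1L)
  expect_equal(est$beta, cor(ch$x, ch$y), tolerance = 1e-10)
})

test_that("with singleton sibships the clustered SE is the
           heteroskedasticity-robust SE", {
  ch <- make_linear_cohort(300, seed = 3)
  ch <- ch[!duplicated(ch$fid), ]  # one sibling per family
  est <- fit_population(ch, "x", model_spec("y"), min_sibship_size = 1L)
  # independent HC0 oracle for the slope with an intercept
  xc <- ch$x - mean(ch$x)
  b <- sum(xc * ch$y) / sum(xc^2)
  e <- ch$y - mean(ch$y) - b * xc
  se_hc0 <- sqrt(sum(xc^2 * e^2)) / sum(xc^2)
  expect_equal(est$beta, b, tolerance = 1e-10)
  expect_equal(est$se, se_hc0, tolerance = 1e-10)
})

test_that("population OLS recovers a simulated slope", {
  ch <- make_linear_cohort(5000, beta = 0.3, icc = 0.2, seed = 4)
  est <- fit_population(ch, "x", model_spec("y"))
  expect_equal(est$beta, 0.3, tolerance = 3 * est$se / 0.3)
})

test_that("within-sibship coefficient equals the sib-difference regression
           for two-sibling families", {
  ch <- make_linear_cohort(400, beta = 0.25, icc = 0.4, seed = 5)
  est <- fit_within_sibship(ch, "x", model_spec("y"))
  d <- do.call(rbind, lapply(split(ch, ch$fid), function(fam) {
    data.frame(dy = diff(fam$y), dx = diff(fam$x))
  }))
  b_diff <- coef(lm(dy ~ 0 + dx, data = d))[[1]]
  expect_equal(est$beta, b_diff, tolerance = 1e-8)
})

test_that("degenerate exposures are refused", {
  ch <- make_linear_cohort(50, seed = 6)
  ch$x <- 1
  expect_error(fit_population(ch, "x", model_spec("y")), "no variance")
  ch2 <- make_linear_cohort(50, seed = 7)
  ch2$x <- rep(rnorm(50), each = 2)  # constant within every sibship
  expect_error(fit_within_sibship(ch2, "x", model_spec("y")),
               "within-family variance")
})

test_that("family confounding biases the population model but not the
           within-sibship model", {
  p <- tiny_params(n_families = 4000L, n_variants = 20L,
                   causal_effects = c(bmi = 0), family_confounder_sd = 0.7,
                   seed = 31L)
  sim <- simulate_cohort(p)
  ch <- sim$cohort
  x <- std_exposure(ch)
  ch$z_bmi <- std_outcome(ch, "bmi")
  sp <- model_spec("z_bmi")
  pop <- fit_population(ch, x, sp)
  ws <- fit_within_sibship(ch, x, sp)
  expect_lt(abs(ws$beta / ws$se), 3)       # null recovered within siblings
  expect_gt(abs(pop$beta / pop$se), 5)     # confounded between families
})

test_that("clustered SE tracks the sibship bootstrap and dominates the
           classical SE under intra-sibship correlation", {
  # exposure shares a family component (like a polygenic score, sibling
  # correlation 0.5), so clustering inflates the population-model variance
  ch <- make_linear_cohort(5000, beta = 0.2, icc = 0.5, seed = 8, x_icc = 0.5)
  est <- fit_within_sibship(ch, "x", model_spec("y"))
  pop <- fit_population(ch, "x", model_spec("y"))

  ols_se <- summary(lm(y ~ x, data = ch))$coefficients["x", 2]
  expect_gt(pop$se, ols_se)

  set.seed(9)
  B <- 400
  fams <- split(seq_len(nrow(ch)), ch$fid)
  boot <- replicate(B, {
    rows <- unlist(fams[sample.int(length(fams), replace = TRUE)],
                   use.names = FALSE)
    x <- ch$x[rows]; y <- ch$y[rows]
    fidb <- rep(seq_len(length(fams)), each = 2L)
    xm <- stats::ave(x, fidb)
    sum((x - xm) * y) / sum((x - xm)^2)
  })
  expect_equal(est$se, sd(boot), tolerance = 0.1)
})

test_that("per-variant scans reproduce the single-fit estimators exactly", {
  sim <- simulate_cohort(tiny_params(n_families = 200L, n_variants = 6L))
  ch <- sim$cohort
  ch$z_bmi <- std_outcome(ch, "bmi")
  for (mdl in c("within_sibship", "population")) {
    scan <- gwas_scan(ch, sim$dosages, "z_bmi", model = mdl)
    fitter <- if (mdl == "population") fit_population else fit_within_sibship
    for (j in c(1L, 4L, 6L)) {
      est <- fitter(ch, sim$dosages[match(ch$iid, rownames(sim$dosages)), j],
                    model_spec("z_bmi"))
      expect_equal(scan$beta[j], est$beta, tolerance = 1e-10)
      expect_equal(scan$se[j], est$se, tolerance = 1e-10)
    }
  }
})

test_that("Cox fits respect the null, delayed entry and the age timescale", {
  p <- tiny_params(n_families = 2000L, seed = 32L)
  sim <- simulate_cohort(p)
  ch <- sim$cohort
  x <- std_exposure(ch)

  set.seed(33)
  est0 <- fit_cox_mortality(ch, sample(x), "population")
  expect_lt(abs(est0$beta / est0$se), 3)

  # entry_age = 0 for all: identical fit with and without truncation handling
  a <- fit_cox_mortality(ch, x, "within_sibship", left_truncate = TRUE)
  b <- fit_cox_mortality(ch, x, "within_sibship", left_truncate = FALSE)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)

  # delayed entry shifts the age axis but the exponential hazard keeps the
  # estimand; estimates stay within sampling error of the truth
  p2 <- tiny_params(n_families = 4000L, entry_age = 50, seed = 34L)
  sim2 <- simulate_cohort(p2)
  ch2 <- sim2$cohort
  expect_true(all(ch2$entry_age == 50))
  est2 <- fit_cox_mortality(ch2, std_exposure(ch2), "within_sibship")
  expect_equal(est2$beta, log(0.9), tolerance = 3 * est2$se / abs(log(0.9)))
})

test_that("twin-pair-stratified Cox equals the conditional-logistic oracle
           when each pair has one event", {
  set.seed(41)
  npair <- 300
  fid <- rep(sprintf("t%04d", seq_len(npair)), each = 2)
  x <- rnorm(2 * npair)
  # within each pair: first listed twin has the event at t=5, co-twin
  # censored later, so each stratum contributes exp(bx1)/(exp(bx1)+exp(bx2))
  event <- rep(c(1L, 0L), npair)
  exit <- rep(c(5, 10), npair)
  ch <- structure(data.frame(
    iid = paste0(fid, "_", rep(1:2, npair)), fid = fid,
    sex = rep(rbinom(npair, 1, 0.5), each = 2),
    birth_year = 1950, edu_years = 10, bmi = 25,
    packyears = rnorm(2 * npair, 8, 2), sbp = 130,
    entry_age = 0, exit_age = exit, event = event,
    zygosity = "DZ", x = x, stringsAsFactors = FALSE),
    class = c("cohort_table", "data.frame"))

  est <- fit_twin_stratified_cox(ch, "x", zygosity = "DZ",
                                 adjust_smoking = FALSE)
  x1 <- x[seq(1, 2 * npair, 2)]
  x2 <- x[seq(2, 2 * npair, 2)]
  nll <- function(b) -sum(b * x1 - log(exp(b * x1) + exp(b * x2)))
  b_or <- optimize(nll, c(-3, 3), tol = 1e-10)$minimum
  # agreement limited only by the partial-likelihood optimizer precision
  expect_equal(est$beta, b_or, tolerance = 1e-3)

  # exposure-concordant pairs carry no information
  ch2 <- ch
  ch2$x <- rep(rnorm(npair), each = 2)
  expect_error(fit_twin_stratified_cox(ch2, "x", zygosity = "DZ"),
               "discordant")
})
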