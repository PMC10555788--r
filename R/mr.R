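# Mendelian randomization layer: Wald ratio from polygenic-score
# association estimates, summary-level inverse-variance-weighted (IVW)
# estimation, population-to-within-sibship shrinkage, and fixed-effects
# meta-analysis.

new_mr_result <- function(estimate, se, method, model, n_variants, scale = "sd",
                          outcome = NA_character_) {
  if (!is.finite(se) || se <= 0) stop_sibmr("MR standard error is not positive")
  structure(list(estimate = as.numeric(estimate), se = as.numeric(se),
                 ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
                 method = method, model = model,
                 n_variants = as.integer(n_variants), scale = scale,
                 outcome = outcome),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s, %s model): estimate = %.4f (SE %.4f, 95%% CI %.4f, %.4f)\n",
              x$method, x$model, x$estimate, x$se, x$ci_low, x$ci_high))
  if (identical(x$scale, "log_hr")) {
    cat(sprintf("  HR = %.4f (95%% CI %.4f, %.4f)\n",
                exp(x$estimate), exp(x$ci_low), exp(x$ci_high)))
  }
  cat(sprintf("  %d variant(s)/instrument(s)\n", x$n_variants))
  invisible(x)
}

.est_val <- function(x) if (inherits(x, "mr_result")) x$estimate else x$beta
.est_se <- function(x) x$se
.est_scale <- function(x) x$scale %||% "sd"

#' Wald-ratio Mendelian randomization estimate
#'
#' The instrumental-variable point estimate is the ratio of the
#' instrument-outcome and instrument-exposure associations,
#' `gy$beta / gx$beta`, with a first-order delta-method standard error
#' \deqn{SE = \sqrt{\sigma_y^2/\beta_x^2 + \beta_y^2 \sigma_x^2/\beta_x^4}}
#' assuming zero covariance between the two estimates (the two-sample
#' convention). For a Cox outcome the ratio is taken on the log
#' hazard-ratio scale.
#'
#' @param gx instrument-exposure `assoc_estimate` (or anything with
#'   `beta`/`se`).
#' @param gy instrument-outcome `assoc_estimate`.
#' @return An `mr_result` with `method = "wald_pgs"`.
#' @export
wald_ratio <- function(gx, gy) {
  bx <- .est_val(gx); sx <- .est_se(gx)
  by <- .est_val(gy); sy <- .est_se(gy)
  if (!is.finite(bx) || bx == 0) {
    stop_sibmr("instrument-exposure association is zero: Wald ratio undefined")
  }
  mx <- gx$model %||% NA_character_
  my <- gy$model %||% NA_character_
  if (!is.na(mx) && !is.na(my) && !identical(mx, my)) {
    stop_sibmr("exposure and outcome estimates come from different models (",
               mx, " vs ", my, ")")
  }
  est <- by / bx
  se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  new_mr_result(est, se, "wald_pgs", mx %||% my, n_variants = 1L,
                scale = .est_scale(gy), outcome = gy$outcome %||% NA_character_)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Merges two per-variant summary tables on the variant id and aligns the
#' outcome arm to the exposure arm's effect allele, flipping the sign of
#' the outcome beta where the allele labels are swapped; any other allele
#' configuration is an error (strand inference is deliberately not
#' attempted).
#'
#' @param exposure,outcome data frames with `snp`, `ea`, `oa`, `beta`,
#'   `se` (the exposure arm may carry `se` as well; only the outcome arm's
#'   `se` enters the IVW weights).
#' @return Data frame with `snp`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out` and a `model` attribute when both arms agree on one.
#' @export
harmonize_sumstats <- function(exposure, outcome) {
  m <- merge(exposure, outcome, by = "snp", suffixes = c("_exp", "_out"))
  if (nrow(m) == 0L) stop_sibmr("no shared variants to harmonize")
  same <- m$ea_exp == m$ea_out & m$oa_exp == m$oa_out
  swap <- m$ea_exp == m$oa_out & m$oa_exp == m$ea_out
  bad <- !(same | swap)
  if (any(bad)) {
    stop_sibmr("unresolvable allele mismatch for variant(s): ",
               paste(utils::head(m$snp[bad], 5), collapse = ", "))
  }
  m$beta_out[swap] <- -m$beta_out[swap]
  out <- data.frame(snp = m$snp, beta_exp = m$beta_exp, se_exp = m$se_exp,
                    beta_out = m$beta_out, se_out = m$se_out,
                    stringsAsFactors = FALSE)
  mod_cols <- intersect(c("model_exp", "model_out"), names(m))
  mods <- unique(unlist(m[mod_cols]))
  if (length(mods) == 1L) attr(out, "model") <- mods
  if (length(mods) > 1L) {
    stop_sibmr("exposure and outcome arms mix association models: ",
               paste(mods, collapse = ", "))
  }
  out
}

#' Inverse-variance-weighted Mendelian randomization estimate
#'
#' Summary-level IVW across `k = 1..n` harmonized variants:
#' \deqn{\beta_{MR} = \frac{\sum_k \beta_{EA,k}\beta_{Out,k}/\sigma_{Out,k}^2}
#'                          {\sum_k \beta_{EA,k}^2/\sigma_{Out,k}^2},\qquad
#'       SE(\beta_{MR}) = \frac{1}{\sqrt{\sum_k \beta_{EA,k}^2/\sigma_{Out,k}^2}}}
#' which equals weighted least squares of the outcome betas on the
#' exposure betas through the origin with weights `1/se_out^2`. With a
#' single variant it reduces to the Wald ratio with the exposure-arm
#' uncertainty ignored.
#'
#' @param summary data frame with `beta_exp`, `beta_out`, `se_out`
#'   (e.g. from [harmonize_sumstats()]); an optional `model` attribute or
#'   argument labels the estimate.
#' @param model association model label carried into the result.
#' @param scale `"sd"`, `"log_hr"` or `"risk_diff_pct"`.
#' @param outcome outcome label.
#' @return An `mr_result` with `method = "ivw_summary"`.
#' @export
ivw <- function(summary, model = attr(summary, "model") %||% NA_character_,
                scale = "sd", outcome = NA_character_) {
  need <- c("beta_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(summary))
  if (length(miss)) stop_sibmr("summary table missing column(s): ",
                               paste(miss, collapse = ", "))
  if (nrow(summary) == 0L) stop_sibmr("empty variant set")
  if (any(summary$se_out <= 0)) stop_sibmr("all outcome standard errors must be positive")
  w <- 1 / summary$se_out^2
  denom <- sum(summary$beta_exp^2 * w)
  if (denom <= 0) stop_sibmr("exposure associations are all zero")
  est <- sum(summary$beta_exp * summary$beta_out * w) / denom
  se <- 1 / sqrt(denom)
  new_mr_result(est, se, "ivw_summary", model, nrow(summary), scale, outcome)
}

#' Population-to-within-sibship shrinkage
#'
#' The proportional attenuation of an association estimate moving from the
#' population to the within-sibship model,
#' `(beta_pop - beta_ws) / beta_pop`, with a first-order delta-method
#' standard error using the two variances and their covariance. The two
#' estimates come from the same individuals, so independence is
#' indefensible: supply the covariance (e.g. from
#' [shrinkage_bootstrap()]), or accept the zero-covariance default with a
#' logged warning.
#'
#' @param pop,ws population and within-sibship `assoc_estimate`s.
#' @param covariance covariance of the two estimates; `NULL` assumes 0
#'   and warns.
#' @return A `shrinkage_result`: `proportion`, `se`, `ci_low`, `ci_high`.
#' @export
shrinkage <- function(pop, ws, covariance = NULL) {
  bp <- .est_val(pop); vp <- .est_se(pop)^2
  bw <- .est_val(ws); vw <- .est_se(ws)^2
  if (!is.finite(bp) || bp == 0) {
    stop_sibmr("population estimate is zero: shrinkage undefined")
  }
  if (is.null(covariance)) {
    warning("no covariance supplied for shrinkage; assuming 0 ",
            "(the two estimates share individuals)", call. = FALSE)
    covariance <- 0
  }
  prop <- (bp - bw) / bp
  # gradient of (bp - bw)/bp = 1 - bw/bp: d/dbp = bw/bp^2, d/dbw = -1/bp
  v <- (bw^2 / bp^4) * vp + vw / bp^2 - 2 * (bw / bp^3) * covariance
  se <- sqrt(max(v, 0))
  structure(list(proportion = prop, se = se,
                 ci_low = prop - 1.96 * se, ci_high = prop + 1.96 * se,
                 beta_pop = bp, beta_ws = bw, covariance = covariance),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("shrinkage: %.1f%% (SE %.1f%%, 95%% CI %.1f%%, %.1f%%)\n",
              100 * x$proportion, 100 * x$se, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

# Fast paired (beta_pop, beta_ws) slopes used inside the bootstrap: same
# estimators as fit_population / fit_within_sibship, without the variance
# machinery.
.paired_slopes <- function(y, x, fid) {
  xc0 <- x - mean(x)
  bp <- sum(xc0 * y) / sum(xc0^2)
  f <- if (is.integer(fid)) fid else match(fid, unique(fid))
  cnt <- tabulate(f)
  xm <- (rowsum(x, f, reorder = TRUE) / cnt)[f]
  xc <- x - xm
  bw <- sum(xc * y) / sum(xc^2)
  c(bp, bw)
}

#' Sibship-level paired bootstrap for the shrinkage statistic
#'
#' Resamples sibships with replacement, refits the population and
#' within-sibship linear models on each replicate, and uses the empirical
#' covariance of the two coefficients in the delta-method standard error
#' of the shrinkage proportion. The bootstrap SD of the proportion itself
#' is kept alongside as a check on the delta approximation.
#'
#' @param cohort a cohort table.
#' @param x exposure column name or vector (standardized).
#' @param outcome outcome column name (linear outcomes only).
#' @param B number of bootstrap replicates.
#' @param seed optional seed for the resampling.
#' @param min_sibship_size minimum sibship size.
#' @return A `shrinkage_result` with extra fields `boot_sd` (bootstrap SD
#'   of the proportion) and `B`.
#' @export
shrinkage_bootstrap <- function(cohort, x, outcome, B = 1000L, seed = NULL,
                                min_sibship_size = 2L) {
  if (!is.null(seed)) set.seed(seed)
  spec <- model_spec(outcome, family = "linear")
  pop <- fit_population(cohort, x, spec, min_sibship_size)
  ws <- fit_within_sibship(cohort, x, spec, min_sibship_size)

  df <- data.frame(fid = cohort$fid, x = .resolve_exposure(cohort, x),
                   y = cohort[[outcome]], stringsAsFactors = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  size <- table(df$fid)
  df <- df[df$fid %in% names(size)[size >= min_sibship_size], , drop = FALSE]
  idx_by_fam <- split(seq_len(nrow(df)), df$fid)
  G <- length(idx_by_fam)

  reps <- matrix(NA_real_, B, 3L)
  for (b in seq_len(B)) {
    fams <- sample.int(G, G, replace = TRUE)
    rows <- unlist(idx_by_fam[fams], use.names = FALSE)
    # each resampled sibship is its own cluster
    fidb <- rep.int(seq_along(fams), lengths(idx_by_fam)[fams])
    sl <- .paired_slopes(df$y[rows], df$x[rows], fidb)
    reps[b, ] <- c(sl, (sl[1] - sl[2]) / sl[1])
  }
  cv <- stats::cov(reps[, 1], reps[, 2])
  out <- shrinkage(pop, ws, covariance = cv)
  out$boot_sd <- stats::sd(reps[, 3])
  out$B <- B
  out
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools estimates with weights `1/se^2`:
#' `pooled = sum(w * b) / sum(w)`, `se = 1/sqrt(sum(w))`. Cochran's Q is
#' reported but never acted on. Estimates must share a scale (pooling a
#' log hazard ratio with an SD-unit effect is an error).
#'
#' @param estimates list of `assoc_estimate` or `mr_result` objects.
#' @return A `meta_result`: `beta`, `se`, `ci_low`, `ci_high`, `q`,
#'   `n_studies`, `scale` and the per-study inputs.
#' @export
meta_fixed <- function(estimates) {
  if (inherits(estimates, c("assoc_estimate", "mr_result"))) {
    estimates <- list(estimates)
  }
  if (!length(estimates)) stop_sibmr("no estimates to meta-analyse")
  scales <- vapply(estimates, .est_scale, character(1))
  if (length(unique(scales)) > 1L) {
    stop_sibmr("cannot pool estimates on different scales: ",
               paste(unique(scales), collapse = ", "))
  }
  b <- vapply(estimates, .est_val, numeric(1))
  s <- vapply(estimates, .est_se, numeric(1))
  w <- 1 / s^2
  pooled <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (b - pooled)^2)
  structure(list(beta = pooled, se = se,
                 ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
                 q = q, n_studies = length(estimates),
                 scale = scales[1], inputs = data.frame(beta = b, se = s)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effects meta (%d studies): %.4f (SE %.4f, 95%% CI %.4f, %.4f), Q = %.2f\n",
              x$n_studies, x$beta, x$se, x$ci_low, x$ci_high, x$q))
  invisible(x)
}
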