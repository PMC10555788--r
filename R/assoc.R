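# Population and within-sibship association models.
#
# The population model regresses the outcome on the exposure. The
# within-sibship model additionally includes the sibship-mean exposure as a
# covariate, with each sibling's exposure centred on that mean; the
# coefficient on the centred term isolates within-family exposure variation
# generated by meiotic segregation. Standard errors are clustered by sibship
# in both models with a plain (CR0) sandwich estimator; Cox models use the
# analogous robust grouped-score variance. Mortality models run on an age
# timescale (origin at birth) with optional delayed entry.

#' Specify an association model
#'
#' @param outcome outcome column name (`"mortality"` or any continuous
#'   outcome column of the cohort table).
#' @param exposure label for the exposure (`"phenotype"` or `"pgs"`);
#'   bookkeeping only.
#' @param family `"linear"` or `"cox"`; `outcome = "mortality"` implies
#'   `"cox"`.
#' @param covariates optional character vector of additional covariate
#'   columns (the standardization pipeline usually leaves none).
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome, exposure = c("phenotype", "pgs"),
                       family = c("linear", "cox"), covariates = NULL) {
  exposure <- match.arg(exposure)
  family <- match.arg(family)
  if (identical(outcome, "mortality")) family <- "cox"
  structure(list(outcome = outcome, exposure = exposure, family = family,
                 covariates = covariates), class = "model_spec")
}

new_assoc_estimate <- function(beta, se, n, n_sibships, model, exposure,
                               outcome, scale = "sd") {
  if (!is.finite(se) || se <= 0) stop_sibmr("estimated standard error is not positive")
  structure(list(beta = as.numeric(beta), se = as.numeric(se),
                 n_individuals = as.integer(n), n_sibships = as.integer(n_sibships),
                 model = model, exposure = exposure, outcome = outcome,
                 scale = scale,
                 ci_low = as.numeric(beta) - 1.96 * as.numeric(se),
                 ci_high = as.numeric(beta) + 1.96 * as.numeric(se)),
            class = "assoc_estimate")
}

#' @export
print.assoc_estimate <- function(x, ...) {
  lab <- if (x$scale == "log_hr") "log-HR" else "beta"
  cat(sprintf("%s model, %s ~ %s: %s = %.4f (SE %.4f, 95%% CI %.4f, %.4f)\n",
              x$model, x$outcome, x$exposure, lab, x$beta, x$se,
              x$ci_low, x$ci_high))
  if (x$scale == "log_hr") {
    cat(sprintf("  HR = %.4f (95%% CI %.4f, %.4f)\n",
                exp(x$beta), exp(x$ci_low), exp(x$ci_high)))
  }
  cat(sprintf("  n = %d individuals in %d sibships\n",
              x$n_individuals, x$n_sibships))
  invisible(x)
}

.resolve_exposure <- function(cohort, x) {
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% names(cohort)) stop_sibmr("exposure column not found: ", x)
    return(cohort[[x]])
  }
  if (length(x) != nrow(cohort)) {
    stop_sibmr("exposure vector length does not match the cohort")
  }
  as.numeric(x)
}

.model_frame <- function(cohort, x, spec, min_sibship_size) {
  df <- data.frame(fid = cohort$fid, x = .resolve_exposure(cohort, x),
                   stringsAsFactors = FALSE)
  if (spec$family == "cox") {
    df$entry_age <- cohort$entry_age
    df$exit_age <- cohort$exit_age
    df$event <- cohort$event
  } else {
    if (!spec$outcome %in% names(cohort)) {
      stop_sibmr("outcome column not found: ", spec$outcome)
    }
    df$y <- cohort[[spec$outcome]]
  }
  for (v in spec$covariates) df[[v]] <- cohort[[v]]
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  size <- table(df$fid)
  df <- df[df$fid %in% names(size)[size >= min_sibship_size], , drop = FALSE]
  sib_log(spec$outcome, " ~ ", spec$exposure, ": ", n0, " -> ", nrow(df),
          " individuals in ", length(unique(df$fid)),
          " sibships after filtering (min size ", min_sibship_size, ")")
  if (length(unique(df$fid)) < 2L) stop_sibmr("need at least 2 sibships")
  df
}

.cov_terms <- function(spec) {
  if (length(spec$covariates)) paste("+", paste(spec$covariates, collapse = " + ")) else ""
}

.fit_linear <- function(df, rhs, term, spec, model, small_sample) {
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
  V <- sandwich::vcovCL(fit, cluster = df$fid, type = "HC0",
                        cadjust = isTRUE(small_sample))
  new_assoc_estimate(stats::coef(fit)[[term]], sqrt(V[term, term]),
                     nrow(df), length(unique(df$fid)), model,
                     spec$exposure, spec$outcome, scale = "sd")
}

.fit_cox <- function(df, rhs, term, spec, model, left_truncate) {
  if (sum(df$event) < 1L) stop_sibmr("no events: cannot fit a Cox model")
  surv <- if (isTRUE(left_truncate) && any(df$entry_age > 0)) {
    "survival::Surv(entry_age, exit_age, event)"
  } else {
    "survival::Surv(exit_age, event)"
  }
  f <- stats::as.formula(paste(surv, "~", rhs, "+ cluster(fid)"))
  fit <- survival::coxph(f, data = df, ties = "efron")
  V <- fit$var  # robust (grouped-score sandwich) when cluster() is present
  k <- match(term, names(stats::coef(fit)))
  new_assoc_estimate(stats::coef(fit)[[term]], sqrt(V[k, k]),
                     nrow(df), length(unique(df$fid)), model,
                     spec$exposure, spec$outcome, scale = "log_hr")
}

#' Fit the population association model
#'
#' Regresses the outcome on the exposure (linear for continuous outcomes,
#' Cox partial likelihood on an age timescale for mortality) with
#' sibship-clustered sandwich standard errors.
#'
#' @param cohort a cohort table.
#' @param x exposure: a column name or a numeric vector aligned with the
#'   cohort rows (typically already residualized and standardized).
#' @param spec a [model_spec()].
#' @param min_sibship_size minimum sibship size after complete-case
#'   filtering (set 1 to keep singletons).
#' @param small_sample apply the G/(G-1) cluster small-sample correction.
#' @param left_truncate for Cox models, honour `entry_age > 0` as delayed
#'   entry.
#' @return An `assoc_estimate`.
#' @export
fit_population <- function(cohort, x, spec, min_sibship_size = 2L,
                           small_sample = FALSE, left_truncate = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  df <- .model_frame(cohort, x, spec, min_sibship_size)
  if (stats::sd(df$x) < 1e-12) stop_sibmr("no variance in the exposure")
  rhs <- paste0("x", .cov_terms(spec))
  if (spec$family == "linear") {
    .fit_linear(df, rhs, "x", spec, "population", small_sample)
  } else {
    .fit_cox(df, rhs, "x", spec, "population", left_truncate)
  }
}

#' Fit the within-sibship association model
#'
#' The exposure is centred on its sibship mean and the sibship mean enters
#' as a covariate; the reported coefficient is the one on the centred
#' term, which is identified by within-family exposure differences only.
#' For two-sibling families this coefficient is algebraically identical to
#' regressing sibling differences of the outcome on sibling differences of
#' the exposure. Standard errors are clustered by sibship; the Cox variant
#' carries both terms in the linear predictor.
#'
#' @inheritParams fit_population
#' @return An `assoc_estimate` with `model = "within_sibship"`.
#' @export
fit_within_sibship <- function(cohort, x, spec, min_sibship_size = 2L,
                               small_sample = FALSE, left_truncate = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  df <- .model_frame(cohort, x, spec, min_sibship_size)
  xm <- stats::ave(df$x, df$fid)
  df$x_cent <- df$x - xm
  df$x_sibmean <- xm
  if (max(abs(df$x_cent)) < 1e-12) {
    stop_sibmr("no within-family variance in the exposure")
  }
  rhs <- paste0("x_cent + x_sibmean", .cov_terms(spec))
  if (spec$family == "linear") {
    .fit_linear(df, rhs, "x_cent", spec, "within_sibship", small_sample)
  } else {
    .fit_cox(df, rhs, "x_cent", spec, "within_sibship", left_truncate)
  }
}

#' Cox model for mortality on an age timescale
#'
#' Convenience wrapper: age is the time axis with origin at date of birth;
#' `entry_age` is honoured as delayed entry when positive. Dispatches to
#' the population or within-sibship linear predictor.
#'
#' @inheritParams fit_population
#' @param model `"population"` or `"within_sibship"`.
#' @return An `assoc_estimate` on the log hazard-ratio scale.
#' @export
fit_cox_mortality <- function(cohort, x, model = c("population", "within_sibship"),
                              min_sibship_size = 2L, left_truncate = TRUE) {
  model <- match.arg(model)
  spec <- model_spec("mortality", family = "cox")
  if (model == "population") {
    fit_population(cohort, x, spec, min_sibship_size, left_truncate = left_truncate)
  } else {
    fit_within_sibship(cohort, x, spec, min_sibship_size, left_truncate = left_truncate)
  }
}

#' Twin-pair-stratified Cox model
#'
#' Restricts to complete same-sex twin pairs of the requested zygosity and
#' fits a Cox model with the baseline hazard stratified by pair, adjusted
#' for smoking; only exposure-discordant pairs carry information, and a
#' data set with none is an error.
#'
#' @param cohort a cohort table with a `zygosity` column.
#' @param x exposure column name or vector.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param adjust_smoking include `packyears` as a covariate.
#' @return An `assoc_estimate` with `model = "twin_stratified"`.
#' @export
fit_twin_stratified_cox <- function(cohort, x, zygosity = c("DZ", "MZ"),
                                    adjust_smoking = TRUE) {
  zygosity <- match.arg(zygosity)
  if (!"zygosity" %in% names(cohort)) stop_sibmr("cohort has no zygosity column")
  df <- data.frame(fid = cohort$fid, x = .resolve_exposure(cohort, x),
                   sex = cohort$sex, packyears = cohort$packyears,
                   entry_age = cohort$entry_age, exit_age = cohort$exit_age,
                   event = cohort$event, zyg = cohort$zygosity,
                   stringsAsFactors = FALSE)
  df <- df[df$zyg == zygosity, , drop = FALSE]
  vars <- c("x", "entry_age", "exit_age", "event",
            if (adjust_smoking) "packyears")
  df <- df[stats::complete.cases(df[vars]), , drop = FALSE]
  # complete same-sex pairs only
  ok_fid <- vapply(split(df$sex, df$fid), function(s) {
    length(s) == 2L && s[1] == s[2]
  }, logical(1))
  df <- df[df$fid %in% names(ok_fid)[ok_fid], , drop = FALSE]
  n0 <- nrow(df)
  sib_log("twin-stratified Cox (", zygosity, "): ", n0 / 2, " complete same-sex pairs")
  if (n0 == 0L) stop_sibmr("no complete same-sex ", zygosity, " pairs")
  disc <- vapply(split(df$x, df$fid), function(v) abs(diff(v)) > 1e-12, logical(1))
  if (!any(disc)) stop_sibmr("no exposure-discordant pairs: zero information")
  if (sum(df$event) < 1L) stop_sibmr("no events: cannot fit a Cox model")
  rhs <- paste0("x", if (adjust_smoking) " + packyears" else "",
                " + strata(fid)")
  surv <- if (any(df$entry_age > 0)) {
    "survival::Surv(entry_age, exit_age, event)"
  } else {
    "survival::Surv(exit_age, event)"
  }
  fit <- survival::coxph(stats::as.formula(paste(surv, "~", rhs)),
                         data = df, ties = "efron")
  V <- stats::vcov(fit)
  spec <- model_spec("mortality", family = "cox")
  new_assoc_estimate(stats::coef(fit)[["x"]], sqrt(V["x", "x"]),
                     nrow(df), length(unique(df$fid)), "twin_stratified",
                     "phenotype", "mortality", scale = "log_hr")
}

#' Per-variant association scan
#'
#' Fits the population or within-sibship linear model for every variant in
#' the dosage matrix, with CR0 sibship-clustered standard errors, using
#' closed-form least squares (the centred within-sibship term is exactly
#' orthogonal to the intercept and the sibship-mean term, so each variant
#' reduces to projections computed by column sums). Numerically identical
#' to calling [fit_population()] / [fit_within_sibship()] per variant, but
#' vectorized across variants.
#'
#' @param cohort a cohort table.
#' @param dosages individuals x variants matrix, rownames matching
#'   `cohort$iid`.
#' @param outcome outcome column name or numeric vector (already
#'   standardized as appropriate).
#' @param model `"within_sibship"` or `"population"`.
#' @param min_sibship_size minimum sibship size (within model only counts
#'   families with 2+ members anyway).
#' @return Data frame: `snp`, `chrom`, `pos`, `ea`, `oa` (when variant
#'   metadata is attached), `beta`, `se`, `p`, `n`, `model`.
#' @export
gwas_scan <- function(cohort, dosages, outcome,
                      model = c("within_sibship", "population"),
                      min_sibship_size = 2L) {
  model <- match.arg(model)
  y <- if (is.character(outcome) && length(outcome) == 1L) {
    cohort[[outcome]]
  } else {
    as.numeric(outcome)
  }
  keep <- !is.na(y)
  cohort_ids <- cohort$iid[keep]
  fid <- cohort$fid[keep]
  y <- y[keep]
  size <- table(fid)
  keep2 <- fid %in% names(size)[size >= min_sibship_size]
  cohort_ids <- cohort_ids[keep2]
  fid <- fid[keep2]
  y <- y[keep2]

  idx <- match(cohort_ids, rownames(dosages))
  if (anyNA(idx)) stop_sibmr("dosage matrix is missing individuals in the cohort")
  X <- dosages[idx, , drop = FALSE]
  n <- length(y)
  yc <- y - mean(y)
  ffac <- factor(fid)
  fsize <- as.vector(table(ffac)[as.integer(ffac)])

  if (model == "within_sibship") {
    Xmf <- rowsum(X, ffac) / as.vector(table(ffac))
    Xm <- Xmf[as.integer(ffac), , drop = FALSE]
    Xc <- X - Xm
    Sxx <- colSums(Xc^2)
    if (any(Sxx < 1e-12)) stop_sibmr("variant(s) with no within-family variance")
    b1 <- colSums(Xc * yc) / Sxx
    Xmc <- sweep(Xm, 2, colMeans(Xm))
    Smm <- colSums(Xmc^2)
    b2 <- colSums(Xmc * yc) / pmax(Smm, 1e-300)
    E <- yc - sweep(Xmc, 2, b2, `*`) - sweep(Xc, 2, b1, `*`)
    U <- rowsum(Xc * E, ffac)
    se <- sqrt(colSums(U^2)) / Sxx
    beta <- b1
  } else {
    Xcen <- sweep(X, 2, colMeans(X))
    Sxx <- colSums(Xcen^2)
    if (any(Sxx < 1e-12)) stop_sibmr("variant(s) with no variance")
    beta <- colSums(Xcen * yc) / Sxx
    E <- yc - sweep(Xcen, 2, beta, `*`)
    U <- rowsum(Xcen * E, ffac)
    se <- sqrt(colSums(U^2)) / Sxx
  }

  out <- data.frame(snp = colnames(X), beta = beta, se = se,
                    p = 2 * stats::pnorm(-abs(beta / se)),
                    n = n, model = model, stringsAsFactors = FALSE)
  vi <- attr(dosages, "variant_info")
  if (!is.null(vi)) {
    j <- match(out$snp, vi$snp)
    out$chrom <- vi$chrom[j]
    out$pos <- vi$pos[j]
    out$ea <- vi$ea[j]
    out$oa <- vi$oa[j]
    out <- out[c("snp", "chrom", "pos", "ea", "oa", "beta", "se", "p", "n", "model")]
  }
  rownames(out) <- NULL
  out
}
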