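#' Parameters for the family-based cohort simulator
#'
#' Defines the generative model for a synthetic multi-sibling cohort with
#' known causal structure. The simulator implements the three mechanisms that
#' bias population-scale genetic association estimates for social phenotypes
#' -- population stratification, assortative mating and indirect parental
#' genetic effects -- together with a family-level environmental confounder
#' and a true causal effect of the exposure liability on each outcome, so
#' that population and within-sibship estimators can be compared against
#' ground truth.
#'
#' The exposure liability of offspring `i` in family `f` is
#' \deqn{L_i = \sum_j b_j x_{ij} + s \sum_j b_j (x^{mat}_{fj} + x^{pat}_{fj})
#'       + a_{k(f)} + c_f + e_i}
#' where `b` are the per-variant direct effects, `s` is `indirect_scale`
#' multiplying the parental genotype sum (transmitted plus non-transmitted
#' alleles, the vehicle of indirect parental effects), `a_k` is the
#' subpopulation phenotype shift, `c_f` the shared family confounder and
#' `e_i` individual noise. With `indirect_scale = 1` the parental-genotype
#' contribution to the population-level covariance between offspring score
#' and liability equals the direct contribution, so the population
#' score-liability slope is twice the within-sibship slope (50\% attenuation).
#'
#' Continuous outcomes are `causal * z(L) + c_f + a_k + noise` (`z()` is
#' cohort standardization), reported on familiar raw scales (BMI-like,
#' pack-years-like, SBP-like) via fixed affine maps. The mortality linear
#' predictor is `causal_log_hr * z(L)` plus an optional confounder term, fed
#' to an exponential survival model with administrative censoring.
#'
#' @param n_families number of independent sibships.
#' @param sibs_per_family siblings per family (constant, >= 2).
#' @param n_variants number of unlinked biallelic variants.
#' @param base_allele_freq per-variant allele frequency in (0.01, 0.99);
#'   scalar or length `n_variants`. Default: evenly spaced on `[0.2, 0.8]`.
#' @param n_subpops number of subpopulations (1 disables stratification).
#' @param freq_divergence per-variant allele-frequency offset magnitude;
#'   subpopulation `k` gets `base + u_k * freq_divergence` with `u_k`
#'   evenly spread over `[-1, 1]`.
#' @param strat_shift subpopulation shift (SD units) applied with the same
#'   `u_k` pattern to the exposure liability and to every outcome, creating
#'   ancestry confounding.
#' @param am_correlation target spousal correlation of the exposure
#'   phenotype in `[0, 1)`, realized by Gaussian-copula rank matching of
#'   spouses within subpopulation. This is the correlation conditional on
#'   subpopulation; with stratification active the marginal spousal
#'   correlation is larger because spouses also share ancestry.
#' @param direct_effects per-variant effect on the exposure liability;
#'   default: alternating-sign, heterogeneous magnitudes scaled so the
#'   direct genetic variance equals `h2_direct`.
#' @param h2_direct direct genetic variance of the liability used to scale
#'   the default `direct_effects` (ignored when `direct_effects` is given).
#' @param indirect_scale multiplier on the parental-genotype-sum
#'   contribution to offspring liability (0 disables indirect effects).
#' @param causal_effects named vector of true effects (SD outcome per SD
#'   liability) for the continuous outcomes.
#' @param causal_log_hr true log hazard ratio per SD of liability.
#' @param family_confounder_sd SD of the shared family confounder affecting
#'   exposure and all outcomes.
#' @param exposure_noise_sd,outcome_noise_sd individual-level noise SDs.
#'   The outcome default (0.85) keeps total outcome variance near 1 under
#'   the default mechanism settings, so `causal_effects` are approximately
#'   on the standardized-outcome scale.
#' @param hazard_confounder weight of the (standardized) family confounder
#'   in the mortality linear predictor.
#' @param baseline_hazard events per person-year at linear predictor 0.
#' @param censor_time administrative censoring horizon, years after entry.
#' @param entry_age age at study entry (delayed entry; exponential event
#'   times make entry conditioning exact).
#' @param education_thresholds strictly increasing liability cut-points for
#'   coarsening into years-of-education categories; default: empirical
#'   quartiles of the realized liability.
#' @param education_years_map years assigned to the categories (length
#'   `length(education_thresholds) + 1`); default `c(10, 12, 13, 16)`,
#'   a four-category national-survey-style scheme.
#' @param birth_year_range inclusive calendar-year range for uniform random
#'   birth years (pure nuisance covariate).
#' @param same_sex_sibs if `TRUE`, siblings share a sex (twin-style data).
#' @param zygosity_label zygosity label written to the cohort table
#'   (`"none"`, `"MZ"` or `"DZ"`); a label only, transmission is always
#'   dizygotic-style independent meiosis.
#' @param seed integer seed; together with the parameters it fully
#'   determines the simulated cohort.
#'
#' @return An object of class `sim_params`.
#' @seealso [simulate_cohort()]
#' @export
sim_params <- function(n_families = 15000L,
                       sibs_per_family = 2L,
                       n_variants = 100L,
                       base_allele_freq = NULL,
                       n_subpops = 2L,
                       freq_divergence = 0.05,
                       strat_shift = 0.3,
                       am_correlation = 0.4,
                       direct_effects = NULL,
                       h2_direct = 0.25,
                       indirect_scale = 1,
                       causal_effects = c(bmi = -0.2, packyears = -0.2, sbp = -0.2),
                       causal_log_hr = log(0.9),
                       family_confounder_sd = 0.5,
                       exposure_noise_sd = 0.7,
                       outcome_noise_sd = 0.85,
                       hazard_confounder = 0,
                       baseline_hazard = 0.02,
                       censor_time = 40,
                       entry_age = 0,
                       education_thresholds = NULL,
                       education_years_map = c(10, 12, 13, 16),
                       birth_year_range = c(1950, 1969),
                       same_sex_sibs = FALSE,
                       zygosity_label = "none",
                       seed = 1L) {
  n_families <- as.integer(n_families)
  sibs_per_family <- as.integer(sibs_per_family)
  n_variants <- as.integer(n_variants)
  n_subpops <- as.integer(n_subpops)
  if (n_families < 1L) stop_sibmr("n_families must be >= 1")
  if (sibs_per_family < 2L) stop_sibmr("sibs_per_family must be >= 2")
  if (n_variants < 1L) stop_sibmr("n_variants must be >= 1")
  if (n_subpops < 1L) stop_sibmr("n_subpops must be >= 1")
  if (am_correlation < 0 || am_correlation >= 1) {
    stop_sibmr("am_correlation must be in [0, 1)")
  }
  if (baseline_hazard <= 0) stop_sibmr("baseline_hazard must be positive")
  if (censor_time < 0) stop_sibmr("censor_time must be non-negative")
  if (entry_age < 0) stop_sibmr("entry_age must be non-negative")
  if (family_confounder_sd < 0 || exposure_noise_sd < 0 || outcome_noise_sd < 0) {
    stop_sibmr("noise SDs must be non-negative")
  }

  p <- base_allele_freq %||% seq(0.2, 0.8, length.out = n_variants)
  p <- rep_len(p, n_variants)
  if (any(p <= 0.01 | p >= 0.99)) {
    stop_sibmr("base_allele_freq must lie in (0.01, 0.99)")
  }

  d <- rep_len(freq_divergence, n_variants)
  u <- if (n_subpops == 1L) 0 else seq(-1, 1, length.out = n_subpops)
  subpop_freqs <- outer(u, d) + rep(p, each = n_subpops)  # K x m
  if (any(subpop_freqs <= 0 | subpop_freqs >= 1)) {
    stop_sibmr("allele frequencies fall outside (0, 1) after subpopulation ",
               "divergence offsets; reduce freq_divergence")
  }

  if (is.null(direct_effects)) {
    if (h2_direct <= 0) stop_sibmr("h2_direct must be positive")
    raw <- rep_len(c(1, -1), n_variants) * seq(0.5, 1.5, length.out = n_variants)
    v <- sum(2 * p * (1 - p) * raw^2)
    direct_effects <- raw * sqrt(h2_direct / v)
  } else {
    direct_effects <- rep_len(direct_effects, n_variants)
  }

  if (is.null(names(causal_effects)) || any(!nzchar(names(causal_effects)))) {
    stop_sibmr("causal_effects must be a named vector")
  }
  if (!is.null(education_thresholds)) {
    if (any(diff(education_thresholds) <= 0)) {
      stop_sibmr("education_thresholds must be strictly increasing")
    }
    if (length(education_years_map) != length(education_thresholds) + 1L) {
      stop_sibmr("education_years_map must have one more entry than ",
                 "education_thresholds")
    }
  }
  if (any(diff(education_years_map) <= 0)) {
    stop_sibmr("education_years_map must be strictly increasing")
  }
  zygosity_label <- match.arg(zygosity_label, c("none", "MZ", "DZ"))

  structure(list(
    n_families = n_families, sibs_per_family = sibs_per_family,
    n_variants = n_variants, base_allele_freq = p, n_subpops = n_subpops,
    freq_divergence = d, subpop_freqs = subpop_freqs,
    strat_shifts = strat_shift * u,
    am_correlation = am_correlation,
    direct_effects = direct_effects, indirect_scale = indirect_scale,
    causal_effects = causal_effects, causal_log_hr = causal_log_hr,
    family_confounder_sd = family_confounder_sd,
    exposure_noise_sd = exposure_noise_sd,
    outcome_noise_sd = outcome_noise_sd,
    hazard_confounder = hazard_confounder,
    baseline_hazard = baseline_hazard, censor_time = censor_time,
    entry_age = entry_age,
    education_thresholds = education_thresholds,
    education_years_map = education_years_map,
    birth_year_range = birth_year_range,
    same_sex_sibs = isTRUE(same_sex_sibs),
    zygosity_label = zygosity_label,
    snp_ids = sprintf("snp%04d", seq_len(n_variants)),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Family cohort simulation parameters\n")
  cat(sprintf("  %d families x %d sibs, %d variants, %d subpopulation(s)\n",
              x$n_families, x$sibs_per_family, x$n_variants, x$n_subpops))
  cat(sprintf("  assortative mating r = %.2f, indirect scale = %.2f, ",
              x$am_correlation, x$indirect_scale))
  cat(sprintf("confounder SD = %.2f\n", x$family_confounder_sd))
  cat(sprintf("  causal effects: %s; log-HR = %.3f\n",
              paste(names(x$causal_effects), round(x$causal_effects, 3),
                    sep = "=", collapse = ", "), x$causal_log_hr))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
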