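options(sibmr.verbose = FALSE)

# Small default scenario used across unit tests; individual tests override
# what they need.
tiny_params <- function(...) {
  defaults <- list(n_families = 400L, sibs_per_family = 2L,
                   n_variants = 12L, seed = 42L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# Scenario with every bias mechanism switched off.
clean_params <- function(...) {
  defaults <- list(n_families = 400L, sibs_per_family = 2L,
                   n_variants = 12L, seed = 42L,
                   n_subpops = 1L, freq_divergence = 0, strat_shift = 0,
                   am_correlation = 0, indirect_scale = 0,
                   family_confounder_sd = 0)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

std_exposure <- function(cohort) {
  residualize_standardize(cohort$edu_cont, cohort$birth_year, cohort$sex)
}

std_outcome <- function(cohort, outcome) {
  residualize_standardize(cohort[[outcome]], cohort$birth_year, cohort$sex)
}
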