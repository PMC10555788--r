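# End-to-end orchestration: simulate (or load) >=1 cohorts, prepare
# phenotypes, build the polygenic score from a discovery GWAS, fit
# population and within-sibship models per outcome, meta-analyse PGS
# associations across cohorts, derive Wald-ratio MR from the meta-analysed
# PGS estimates and summary IVW from per-variant estimates, and compute
# shrinkage for every population/within-sibship pair.

#' Configure an end-to-end run
#'
#' @param cohorts list of [sim_params()] objects (one per cohort to
#'   meta-analyse; two cohorts emulate a two-biobank design). Seeds are
#'   re-derived from `seed` so the run is fully determined by this
#'   configuration.
#' @param outcomes outcomes to analyse; `"mortality"` uses the Cox model,
#'   anything else the linear model.
#' @param exposure_var cohort column used as the continuous exposure
#'   phenotype (`"edu_cont"`, the simulator's continuous liability
#'   readout, or `"edu_years"` for the coarsened years measure).
#' @param boot_B sibship bootstrap replicates for per-cohort shrinkage
#'   covariance (0 disables the bootstrap; zero covariance is then
#'   assumed and logged).
#' @param clump_p,clump_r2,clump_window_kb clumping thresholds for the
#'   discovery summary statistics.
#' @param seed master seed; every stochastic stage derives its stream
#'   from it.
#' @return A `run_config` object.
#' @export
run_config <- function(cohorts = list(sim_params(), sim_params()),
                       outcomes = c("bmi", "packyears", "sbp", "mortality"),
                       exposure_var = "edu_cont",
                       boot_B = 200L,
                       clump_p = 5e-8, clump_r2 = 0.001,
                       clump_window_kb = 10000,
                       seed = 1L) {
  if (!length(cohorts)) stop_sibmr("config needs at least one cohort")
  for (p in cohorts) {
    if (!inherits(p, "sim_params")) stop_sibmr("cohorts must be sim_params objects")
  }
  nm <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  nm[!nzchar(nm)] <- paste0("cohort", which(!nzchar(nm)))
  names(cohorts) <- nm
  structure(list(cohorts = cohorts, outcomes = outcomes,
                 exposure_var = exposure_var, boot_B = as.integer(boot_B),
                 clump_p = clump_p, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 seed = as.integer(seed)),
            class = "run_config")
}

.assoc_row <- function(cohort_name, est) {
  data.frame(cohort = cohort_name, outcome = est$outcome,
             exposure = est$exposure, model = est$model,
             beta = est$beta, se = est$se,
             ci_low = est$ci_low, ci_high = est$ci_high,
             n = est$n_individuals, n_sibships = est$n_sibships,
             scale = est$scale, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Per cohort: simulate, residualize/standardize exposure and continuous
#' outcomes on birth year and sex, run a population discovery GWAS of the
#' exposure in the parental generation (a sample disjoint from the
#' siblings), clump it, score and standardize the PGS, fit population and
#' within-sibship models for each outcome with both the phenotypic
#' exposure and the PGS, and run per-variant within-sibship and population
#' scans. Across cohorts: fixed-effects meta-analysis of the PGS
#' association estimates, Wald-ratio MR from the meta-analysed PGS
#' estimates, per-variant meta then summary IVW, and shrinkage for every
#' population/within-sibship pair.
#'
#' @param config a [run_config()].
#' @return A `results_bundle`: data frames `associations`, `meta`, `mr`,
#'   `shrinkage`, the run `log`, and the `config`. All numbers are pure
#'   functions of the configuration (including its seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    sib_log(line)
  }

  cont_outcomes <- setdiff(config$outcomes, "mortality")
  assoc <- list()
  scans <- list()   # scans[[model]][[outcome]][[cohort]] = per-variant df
  pgs_est <- list() # pgs_est[[model]][[outcome]][[cohort]] = assoc_estimate
  cohort_store <- list()

  for (ci in seq_along(config$cohorts)) {
    cname <- names(config$cohorts)[ci]
    params <- config$cohorts[[ci]]
    params$seed <- derive_seed(config$seed, ci)
    note("cohort ", cname, ": simulating with derived seed ", params$seed)
    sim <- simulate_cohort(params)
    ch <- sim$cohort

    ch$x_pheno <- residualize_standardize(ch[[config$exposure_var]],
                                          ch$birth_year, ch$sex)
    for (o in cont_outcomes) {
      ch[[paste0("z_", o)]] <- residualize_standardize(ch[[o]], ch$birth_year, ch$sex)
    }

    if (ci == 1L) {
      # Discovery GWAS of the exposure phenotype in the parental
      # generation of the first cohort (disjoint from all sibling
      # samples), shared across cohorts as the external weight source.
      par_dos <- rbind(sim$parents$mother, sim$parents$father)
      rownames(par_dos) <- paste0(rep(c("M", "P"), each = params$n_families),
                                  rep(sim$parents$fid, 2))
      attr(par_dos, "variant_info") <- sim$variants
      par_ch <- data.frame(iid = rownames(par_dos),
                           fid = rownames(par_dos),
                           stringsAsFactors = FALSE)
      par_pheno <- c(sim$parents$pheno_mother, sim$parents$pheno_father)
      disc <- gwas_scan(par_ch, par_dos, par_pheno, model = "population",
                        min_sibship_size = 1L)
      retained <- clump(disc, identity_ld(disc$snp), r2_max = config$clump_r2,
                        window_kb = config$clump_window_kb, p_max = config$clump_p)
      note("discovery GWAS on ", nrow(par_dos), " parents; clumping retained ",
           nrow(retained), " of ", nrow(disc), " variants")
      if (nrow(retained) == 0L) stop_sibmr("no genome-wide-significant variants ",
                                           "in the discovery GWAS")
    }

    raw_pgs <- compute_pgs(sim$dosages, retained)
    ch$pgs <- prepare_pgs(raw_pgs, age = max(ch$birth_year) - ch$birth_year,
                          sex = ch$sex)

    exposures <- list(phenotype = "x_pheno", pgs = "pgs")
    for (o in config$outcomes) {
      ycol <- if (o == "mortality") "mortality" else paste0("z_", o)
      for (ex in names(exposures)) {
        spec <- model_spec(ycol, exposure = ex,
                           family = if (o == "mortality") "cox" else "linear")
        spec$outcome <- if (o == "mortality") "mortality" else ycol
        pop <- fit_population(ch, exposures[[ex]], spec)
        ws <- fit_within_sibship(ch, exposures[[ex]], spec)
        pop$outcome <- ws$outcome <- o
        assoc <- c(assoc, list(.assoc_row(cname, pop), .assoc_row(cname, ws)))
        if (ex == "pgs") {
          pgs_est[["population"]][[o]][[cname]] <- pop
          pgs_est[["within_sibship"]][[o]][[cname]] <- ws
        }
      }
    }
    # PGS-exposure associations (the MR denominator)
    for (mdl in c("population", "within_sibship")) {
      fitter <- if (mdl == "population") fit_population else fit_within_sibship
      est <- fitter(ch, "pgs", model_spec("x_pheno", exposure = "pgs"))
      est$outcome <- "exposure"
      pgs_est[[mdl]][["exposure"]][[cname]] <- est
      assoc <- c(assoc, list(.assoc_row(cname, est)))
    }

    # per-variant scans for summary-level MR
    for (mdl in c("population", "within_sibship")) {
      scans[[mdl]][["exposure"]][[cname]] <-
        gwas_scan(ch, sim$dosages, "x_pheno", model = mdl)
      for (o in cont_outcomes) {
        scans[[mdl]][[o]][[cname]] <-
          gwas_scan(ch, sim$dosages, paste0("z_", o), model = mdl)
      }
    }
    cohort_store[[cname]] <- ch
  }

  # fixed-effects meta of PGS association estimates across cohorts
  meta_rows <- list()
  meta_est <- list()
  for (mdl in names(pgs_est)) {
    for (o in names(pgs_est[[mdl]])) {
      mm <- meta_fixed(unname(pgs_est[[mdl]][[o]]))
      meta_est[[mdl]][[o]] <- mm
      meta_rows <- c(meta_rows, list(data.frame(
        outcome = o, exposure = "pgs", model = mdl,
        beta = mm$beta, se = mm$se, ci_low = mm$ci_low, ci_high = mm$ci_high,
        q = mm$q, n_studies = mm$n_studies, scale = mm$scale,
        stringsAsFactors = FALSE)))
    }
  }
  note("meta-analysed PGS associations across ", length(config$cohorts),
       " cohort(s)")

  # Wald MR from meta-analysed PGS estimates; summary IVW from per-variant
  # estimates meta-analysed per variant.
  mr_rows <- list()
  for (mdl in c("population", "within_sibship")) {
    gx <- meta_est[[mdl]][["exposure"]]
    for (o in config$outcomes) {
      gy <- meta_est[[mdl]][[o]]
      wr <- wald_ratio(c(gx, list(model = mdl)), c(gy, list(model = mdl,
                                                            outcome = o)))
      mr_rows <- c(mr_rows, list(data.frame(
        outcome = o, method = "wald_pgs", model = mdl,
        estimate = wr$estimate, se = wr$se,
        ci_low = wr$ci_low, ci_high = wr$ci_high,
        n_variants = nrow(retained), scale = wr$scale,
        stringsAsFactors = FALSE)))
    }
    exp_meta <- .meta_scans(scans[[mdl]][["exposure"]])
    for (o in cont_outcomes) {
      out_meta <- .meta_scans(scans[[mdl]][[o]])
      pair <- harmonize_sumstats(exp_meta, out_meta)
      attr(pair, "model") <- mdl
      iv <- ivw(pair, outcome = o)
      mr_rows <- c(mr_rows, list(data.frame(
        outcome = o, method = "ivw_summary", model = mdl,
        estimate = iv$estimate, se = iv$se,
        ci_low = iv$ci_low, ci_high = iv$ci_high,
        n_variants = iv$n_variants, scale = iv$scale,
        stringsAsFactors = FALSE)))
    }
  }
  note("derived Wald-ratio MR from meta-analysed PGS estimates and ",
       "summary IVW from per-variant estimates")

  # shrinkage: per cohort with bootstrap covariance where affordable,
  # plus meta-level with zero covariance (logged).
  shr_rows <- list()
  for (o in c("exposure", cont_outcomes)) {
    for (ci in names(config$cohorts)) {
      pop <- pgs_est[["population"]][[o]][[ci]]
      ws <- pgs_est[["within_sibship"]][[o]][[ci]]
      ch <- cohort_store[[ci]]
      ycol <- if (o == "exposure") "x_pheno" else paste0("z_", o)
      if (config$boot_B > 0L) {
        sh <- shrinkage_bootstrap(ch, "pgs", ycol, B = config$boot_B,
                                  seed = derive_seed(config$seed, 500 + match(ci, names(config$cohorts))))
      } else {
        note("shrinkage covariance assumed 0 for ", ci, "/", o,
             " (bootstrap disabled)")
        sh <- suppressWarnings(shrinkage(pop, ws, covariance = 0))
      }
      shr_rows <- c(shr_rows, list(data.frame(
        cohort = ci, quantity = paste0("pgs_", o), proportion = sh$proportion,
        se = sh$se, ci_low = sh$ci_low, ci_high = sh$ci_high,
        stringsAsFactors = FALSE)))
    }
    note("meta-level shrinkage for ", o, " uses zero covariance across cohorts")
    shm <- suppressWarnings(shrinkage(meta_est[["population"]][[o]],
                                      meta_est[["within_sibship"]][[o]],
                                      covariance = 0))
    shr_rows <- c(shr_rows, list(data.frame(
      cohort = "meta", quantity = paste0("pgs_", o), proportion = shm$proportion,
      se = shm$se, ci_low = shm$ci_low, ci_high = shm$ci_high,
      stringsAsFactors = FALSE)))
  }

  structure(list(
    associations = do.call(rbind, assoc),
    meta = do.call(rbind, meta_rows),
    mr = do.call(rbind, mr_rows),
    shrinkage = do.call(rbind, shr_rows),
    n_retained_variants = nrow(retained),
    log = log_lines,
    config = config
  ), class = "results_bundle")
}

# per-variant fixed-effects meta across cohorts
.meta_scans <- function(scan_list) {
  if (length(scan_list) == 1L) return(scan_list[[1]])
  base <- scan_list[[1]]
  W <- sapply(scan_list, function(s) 1 / s$se[match(base$snp, s$snp)]^2)
  B <- sapply(scan_list, function(s) s$beta[match(base$snp, s$snp)])
  sw <- rowSums(W)
  base$beta <- rowSums(B * W) / sw
  base$se <- 1 / sqrt(sw)
  base$p <- 2 * stats::pnorm(-abs(base$beta / base$se))
  base$n <- sum(vapply(scan_list, function(s) s$n[1], numeric(1)))
  base
}

#' Summarize a results bundle as one table
#'
#' One row per (outcome, exposure, model, method); hazard-ratio scale
#' estimates are additionally exponentiated.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @return Data frame summary (empty bundle gives an empty table).
#' @export
report_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "results_bundle"))
  rows <- list()
  a <- bundle$associations
  if (!is.null(a) && nrow(a)) {
    rows <- c(rows, list(data.frame(
      source = a$cohort, outcome = a$outcome, exposure = a$exposure,
      model = a$model, method = "association",
      estimate = a$beta, se = a$se, ci_low = a$ci_low, ci_high = a$ci_high,
      scale = a$scale, stringsAsFactors = FALSE)))
  }
  m <- bundle$mr
  if (!is.null(m) && nrow(m)) {
    rows <- c(rows, list(data.frame(
      source = "meta", outcome = m$outcome, exposure = "liability",
      model = m$model, method = m$method,
      estimate = m$estimate, se = m$se, ci_low = m$ci_low, ci_high = m$ci_high,
      scale = m$scale, stringsAsFactors = FALSE)))
  }
  if (!length(rows)) {
    return(data.frame(source = character(0), outcome = character(0),
                      exposure = character(0), model = character(0),
                      method = character(0), estimate = numeric(0),
                      se = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), scale = character(0),
                      hr = numeric(0), hr_low = numeric(0),
                      hr_high = numeric(0)))
  }
  out <- do.call(rbind, rows)
  is_hr <- out$scale == "log_hr"
  out$hr <- ifelse(is_hr, exp(out$estimate), NA_real_)
  out$hr_low <- ifelse(is_hr, exp(out$ci_low), NA_real_)
  out$hr_high <- ifelse(is_hr, exp(out$ci_high), NA_real_)
  rownames(out) <- NULL
  out
}

#' Write a results bundle to disk
#'
#' Emits `associations.tsv`, `meta.tsv`, `mr.tsv`, `shrinkage.tsv`,
#' `report.tsv`, `log.txt` and a YAML snapshot of the configuration. The
#' files are bitwise reproducible from the configuration and seed.
#'
#' @param bundle a `results_bundle`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("associations", "meta", "mr", "shrinkage")) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(bundle[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "report.tsv")
  write_tsv(report_bundle(bundle), p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "log.txt")
  writeLines(bundle$log, p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "config.yaml")
  cfg <- bundle$config
  yaml::write_yaml(list(
    seed = cfg$seed, outcomes = cfg$outcomes, exposure_var = cfg$exposure_var,
    boot_B = cfg$boot_B, clump_p = cfg$clump_p, clump_r2 = cfg$clump_r2,
    clump_window_kb = cfg$clump_window_kb,
    cohorts = lapply(cfg$cohorts, function(pp) {
      pp$subpop_freqs <- NULL
      lapply(unclass(pp), function(v) if (is.numeric(v)) as.numeric(v) else v)
    })
  ), p)
  paths <- c(paths, p)
  invisible(paths)
}
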