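# Family cohort simulator: parents -> meiotic transmission -> phenotypes ->
# survival. All stochastic steps draw from the current RNG stream; pass a
# seed (or use simulate_cohort(), which seeds once from the parameters) for
# reproducibility.

# Raw reporting scales (location, scale) for the standardized outcome
# components; purely cosmetic, analyses re-standardize.
.outcome_raw_scale <- list(bmi = c(27, 4), packyears = c(8, 6), sbp = c(135, 18))

.family_ids <- function(n_families) sprintf("F%05d", seq_len(n_families))

#' Simulate the parental generation with stratification and assortment
#'
#' Draws two parents per family. Each family belongs to one subpopulation;
#' parental genotypes are binomial(2, subpopulation allele frequency) per
#' variant and the parental exposure phenotype is genetic value +
#' subpopulation shift + noise. Spouse pairs are then matched within
#' subpopulation by Gaussian-copula rank matching so that the realized
#' spousal phenotype correlation targets `am_correlation`.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed (set before any draws).
#' @return An object of class `sib_parents`: dosage matrices `mother` and
#'   `father` (families x variants, spouse pairs aligned by row), parental
#'   phenotypes, per-family subpopulation labels and the realized spousal
#'   phenotype correlations (`realized_spousal_r` marginal,
#'   `realized_spousal_r_within` conditional on subpopulation, the
#'   quantity the copula targets).
#' @export
simulate_parents <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  nf <- params$n_families
  m <- params$n_variants
  K <- params$n_subpops

  subpop <- sample.int(K, nf, replace = TRUE)
  pr <- params$subpop_freqs[subpop, , drop = FALSE]
  mother <- matrix(stats::rbinom(nf * m, 2L, pr), nf, m)
  father <- matrix(stats::rbinom(nf * m, 2L, pr), nf, m)
  colnames(mother) <- colnames(father) <- params$snp_ids

  b <- params$direct_effects
  shift <- params$strat_shifts[subpop]
  ph_m <- drop(mother %*% b) + shift +
    stats::rnorm(nf, 0, params$exposure_noise_sd)
  ph_f <- drop(father %*% b) + shift +
    stats::rnorm(nf, 0, params$exposure_noise_sd)

  r <- params$am_correlation
  if (r > 0) {
    # Rank-match spouses through a Gaussian copula: the mother with
    # phenotype rank t is paired with the father whose phenotype rank
    # equals the rank of z2 among pairs ordered by z1, (z1, z2) bivariate
    # normal with correlation r. Near-Gaussian margins make the realized
    # Pearson correlation track the target.
    perm <- seq_len(nf)
    for (k in seq_len(K)) {
      idx <- which(subpop == k)
      ns <- length(idx)
      if (ns < 2L) next
      z1 <- stats::rnorm(ns)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(ns)
      mothers_sorted <- idx[order(ph_m[idx])]
      fathers_sorted <- idx[order(ph_f[idx])]
      partner_rank <- rank(z2, ties.method = "first")[order(z1)]
      perm[mothers_sorted] <- fathers_sorted[partner_rank]
    }
    father <- father[perm, , drop = FALSE]
    ph_f <- ph_f[perm]
  }

  # Marginal spousal correlation includes a component from shared
  # subpopulation membership; the copula targets the within-subpopulation
  # correlation, reported separately.
  dm <- ph_m - stats::ave(ph_m, subpop)
  df_ <- ph_f - stats::ave(ph_f, subpop)
  structure(list(
    mother = mother, father = father,
    pheno_mother = ph_m, pheno_father = ph_f,
    subpop = subpop,
    realized_spousal_r = stats::cor(ph_m, ph_f),
    realized_spousal_r_within = stats::cor(dm, df_),
    fid = .family_ids(nf),
    params = params
  ), class = "sib_parents")
}

.transmit_one <- function(parent) {
  het <- parent == 1L
  trans <- (parent == 2L) + 0L
  trans[het] <- stats::rbinom(sum(het), 1L, 0.5)
  trans
}

#' Transmit parental genotypes to siblings by independent meiosis
#'
#' Per parent and variant, the number of transmitted copies is 0 for dosage
#' 0, 1 for dosage 2 and Bernoulli(1/2) for dosage 1; the offspring dosage
#' is the sum over both parents. Transmissions are independent across
#' siblings and variants, so genetic differences between siblings arise
#' only from random segregation.
#'
#' @param parents a `sib_parents` object with hard-call dosages.
#' @param sibs_per_family siblings per family.
#' @param seed optional integer seed.
#' @return An object of class `sib_offspring`: offspring dosage matrix
#'   (rows `iid`, sorted by family then sibling index), `fid`/`iid`
#'   vectors, and the per-family parental dosage sum `parent_sum`
#'   (transmitted + non-transmitted alleles).
#' @export
transmit_genotypes <- function(parents,
                               sibs_per_family = parents$params$sibs_per_family,
                               seed = NULL) {
  stopifnot(inherits(parents, "sib_parents"))
  if (!is.null(seed)) set.seed(seed)
  M <- parents$mother
  F_ <- parents$father
  if (any(M != floor(M)) || any(F_ != floor(F_)) ||
      any(M < 0 | M > 2) || any(F_ < 0 | F_ > 2)) {
    stop_sibmr("parental dosages must be hard calls in {0, 1, 2}; ",
               "transmission requires integer genotypes")
  }
  S <- as.integer(sibs_per_family)
  if (S < 1L) stop_sibmr("sibs_per_family must be >= 1")
  nf <- nrow(M)

  blocks <- vector("list", S)
  for (s in seq_len(S)) blocks[[s]] <- .transmit_one(M) + .transmit_one(F_)
  dosage <- do.call(rbind, blocks)
  fid <- rep(parents$fid, times = S)
  sib <- rep(seq_len(S), each = nf)
  ord <- order(fid, sib)
  dosage <- dosage[ord, , drop = FALSE]
  fid <- fid[ord]
  sib <- sib[ord]
  iid <- paste0(fid, "_S", sib)
  rownames(dosage) <- iid
  colnames(dosage) <- colnames(M)

  structure(list(
    dosage = dosage, fid = fid, iid = iid, sib_index = sib,
    parent_sum = M + F_
  ), class = "sib_offspring")
}

#' Simulate phenotypes with direct, indirect, confounder and causal paths
#'
#' Builds the exposure liability (direct genetic + indirect parental +
#' subpopulation shift + family confounder + noise), its coarsening into
#' years-of-education categories, the continuous outcomes (true causal
#' effect of standardized liability + the same confounder and shift +
#' noise, reported on familiar raw scales) and the survival triple.
#'
#' @param parents a `sib_parents` object.
#' @param offspring a `sib_offspring` object from [transmit_genotypes()].
#' @param params the [sim_params()] used to generate them.
#' @param seed optional integer seed.
#' @return A list with `cohort` (data frame, one row per offspring: `iid`,
#'   `fid`, `sex`, `birth_year`, `edu_years`, `edu_cont` (the continuous
#'   liability readout), outcomes, survival triple, `zygosity`) and `truth`
#'   (a `truth_ledger`: realized spousal correlation, true effects,
#'   per-individual liability, subpopulation labels, parental and
#'   non-transmitted polygenic scores). The ledger is consumed only by
#'   tests, never by estimators.
#' @export
simulate_phenotypes <- function(parents, offspring, params, seed = NULL) {
  stopifnot(inherits(parents, "sib_parents"), inherits(offspring, "sib_offspring"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(offspring$iid)
  nf <- params$n_families
  b <- params$direct_effects
  fmap <- match(offspring$fid, parents$fid)

  g_direct <- drop(offspring$dosage %*% b)
  g_parent <- drop(offspring$parent_sum %*% b)[fmap]
  confounder_f <- stats::rnorm(nf, 0, params$family_confounder_sd)
  conf <- confounder_f[fmap]
  shift <- params$strat_shifts[parents$subpop][fmap]

  liab <- g_direct + params$indirect_scale * g_parent + shift + conf +
    stats::rnorm(n, 0, params$exposure_noise_sd)
  liab_sd <- stats::sd(liab)
  zliab <- (liab - mean(liab)) / liab_sd

  thr <- params$education_thresholds %||%
    stats::quantile(liab, c(0.25, 0.5, 0.75), names = FALSE)
  if (any(diff(thr) <= 0)) {
    stop_sibmr("education thresholds must be strictly increasing ",
               "(degenerate liability distribution?)")
  }
  edu_years <- params$education_years_map[findInterval(liab, thr) + 1L]

  if (params$same_sex_sibs) {
    sex <- stats::rbinom(nf, 1L, 0.5)[fmap]
  } else {
    sex <- stats::rbinom(n, 1L, 0.5)
  }
  birth_year <- sample(seq(params$birth_year_range[1], params$birth_year_range[2]),
                       n, replace = TRUE)

  outcomes <- list()
  outcome_sd <- numeric(0)
  for (o in names(params$causal_effects)) {
    ce <- params$causal_effects[[o]]
    ystd <- ce * zliab + conf + shift +
      stats::rnorm(n, 0, params$outcome_noise_sd)
    outcome_sd[o] <- stats::sd(ystd)
    sc <- .outcome_raw_scale[[o]] %||% c(0, 1)
    outcomes[[o]] <- sc[1] + sc[2] * ystd
  }

  lp <- params$causal_log_hr * zliab
  if (params$hazard_confounder != 0 && params$family_confounder_sd > 0) {
    lp <- lp + params$hazard_confounder * conf / params$family_confounder_sd
  }
  surv <- simulate_survival(lp, params)

  cohort <- data.frame(
    iid = offspring$iid, fid = offspring$fid,
    sex = sex, birth_year = birth_year,
    edu_years = edu_years, edu_cont = liab,
    outcomes,
    surv,
    zygosity = params$zygosity_label,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort_table", "data.frame")

  truth <- structure(list(
    realized_spousal_r = parents$realized_spousal_r,
    direct_effects = b,
    causal_effects = params$causal_effects,
    causal_log_hr = params$causal_log_hr,
    # SD/SD truth after the outcome's own standardization:
    causal_effects_sd = params$causal_effects / outcome_sd,
    liability = liab,
    liability_sd = liab_sd,
    linear_predictor = lp,
    subpop = parents$subpop[fmap],
    parent_pgs_sum = g_parent,
    nontransmitted_pgs = g_parent - g_direct,
    education_thresholds = thr,
    outcome_sd = outcome_sd
  ), class = "truth_ledger")

  list(cohort = cohort, truth = truth)
}

#' Simulate exponential survival with administrative censoring
#'
#' Event times are exponential with rate `baseline_hazard * exp(lp)`,
#' measured from study entry; exit is the event time or the censoring
#' horizon, whichever comes first. Because the exponential is memoryless,
#' delayed entry at `entry_age` is exact.
#'
#' @param lp per-individual linear predictor (log relative hazard).
#' @param params a [sim_params()] (uses `baseline_hazard`, `censor_time`,
#'   `entry_age`).
#' @param seed optional integer seed.
#' @return Data frame with `entry_age`, `exit_age`, `event` (0/1).
#' @export
simulate_survival <- function(lp, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (params$baseline_hazard <= 0) stop_sibmr("baseline_hazard must be positive")
  n <- length(lp)
  tt <- stats::rexp(n, rate = params$baseline_hazard * exp(lp))
  event <- as.integer(tt < params$censor_time)
  exit <- params$entry_age + pmin(tt, params$censor_time)
  data.frame(entry_age = rep(params$entry_age, n), exit_age = exit,
             event = event)
}

#' Simulate a complete sibling cohort
#'
#' Runs [simulate_parents()], [transmit_genotypes()] and
#' [simulate_phenotypes()] under a single seed taken from the parameters,
#' so identical parameters always reproduce the identical cohort.
#'
#' @param params a [sim_params()] object.
#' @return An object of class `sib_cohort`: `cohort` (phenotype table),
#'   `dosages` (offspring dosage matrix with a `variant_info` attribute),
#'   `variants` (snp, chrom, pos, alleles, base frequency), `parents`,
#'   `truth` and `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  parents <- simulate_parents(params)
  offspring <- transmit_genotypes(parents, params$sibs_per_family)
  ph <- simulate_phenotypes(parents, offspring, params)

  m <- params$n_variants
  j <- seq_len(m)
  variants <- data.frame(
    snp = params$snp_ids,
    chrom = ((j - 1L) %% 22L) + 1L,
    pos = 1e6 * (1L + (j - 1L) %/% 22L),
    ea = "A", oa = "G",
    freq = params$base_allele_freq,
    stringsAsFactors = FALSE
  )
  dosages <- offspring$dosage
  attr(dosages, "variant_info") <- variants

  structure(list(
    cohort = ph$cohort, dosages = dosages, variants = variants,
    parents = parents, offspring = offspring, truth = ph$truth,
    params = params
  ), class = "sib_cohort")
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Emits `phenotypes.tsv`, `dosages.tsv`, `variants.tsv`, a KING-style
#' `kinship.tsv` (true sibling pairs at kinship ~0.25, IBD0 ~0.25,
#' IBD2 ~0.25 plus noise, and an equal number of unrelated cross-family
#' pairs near zero), `truth.json`, optional GWAS summary tables and an
#' optional minimal VCF with hard-call genotypes. All files round-trip
#' through the package readers.
#'
#' @param sim a `sib_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param summary_stats optional named list of summary-statistics data
#'   frames, written as `sumstats_<name>.tsv`.
#' @param vcf also write `dosages.vcf`.
#' @param kinship_noise_sd SD of the noise added to the ideal sibling
#'   kinship/IBD values.
#' @param seed optional seed for the kinship noise.
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(sim, out_dir, summary_stats = NULL, vcf = FALSE,
                          kinship_noise_sd = 0.01, seed = NULL) {
  stopifnot(inherits(sim, "sib_cohort"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- sim$cohort
  if (nrow(cohort) == 0L) stop_sibmr("empty cohort: nothing to write")
  if (anyDuplicated(cohort$iid)) {
    stop_sibmr("duplicate individual ids in cohort; refusing to write fixture")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  p <- file.path(out_dir, "phenotypes.tsv")
  write_tsv(cohort, p)
  paths <- c(paths, p)

  dos <- data.frame(iid = rownames(sim$dosages),
                    sim$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  p <- file.path(out_dir, "dosages.tsv")
  write_tsv(dos, p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "variants.tsv")
  write_tsv(sim$variants, p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "kinship.tsv")
  write_tsv(.kinship_table(cohort, kinship_noise_sd), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "truth.json")
  tr <- sim$truth
  jsonlite::write_json(list(
    realized_spousal_r = tr$realized_spousal_r,
    direct_effects = tr$direct_effects,
    causal_effects = as.list(tr$causal_effects),
    causal_effects_sd = as.list(tr$causal_effects_sd),
    causal_log_hr = tr$causal_log_hr,
    liability_sd = tr$liability_sd,
    education_thresholds = tr$education_thresholds
  ), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  for (nm in names(summary_stats)) {
    p <- file.path(out_dir, paste0("sumstats_", nm, ".tsv"))
    write_tsv(summary_stats[[nm]], p)
    paths <- c(paths, p)
  }

  if (isTRUE(vcf)) {
    p <- file.path(out_dir, "dosages.vcf")
    .write_vcf(sim$dosages, sim$variants, p)
    paths <- c(paths, p)
  }

  sib_log("wrote fixture: ", nrow(cohort), " individuals, ",
          ncol(sim$dosages), " variants -> ", out_dir)
  invisible(paths)
}

# True sibling pairs plus an equal number of unrelated cross-family pairs.
.kinship_table <- function(cohort, noise_sd) {
  fam <- split(cohort$iid, cohort$fid)
  sib_pairs <- do.call(rbind, lapply(fam, function(ids) {
    if (length(ids) < 2L) return(NULL)
    t(utils::combn(ids, 2L))
  }))
  ns <- nrow(sib_pairs)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  kin <- data.frame(
    id1 = sib_pairs[, 1], id2 = sib_pairs[, 2],
    kinship = clamp(0.25 + stats::rnorm(ns, 0, noise_sd), 0.18, 0.35),
    ibd0 = clamp(0.25 + stats::rnorm(ns, 0, noise_sd), 0.05, 0.95),
    ibd2 = clamp(0.25 + stats::rnorm(ns, 0, noise_sd), 0.09, 0.95),
    stringsAsFactors = FALSE
  )
  # background pairs across different families
  ids <- cohort$iid
  fidv <- cohort$fid
  nb <- min(ns, length(ids))
  i1 <- sample.int(length(ids), nb, replace = TRUE)
  i2 <- sample.int(length(ids), nb, replace = TRUE)
  keep <- fidv[i1] != fidv[i2]
  if (any(keep)) {
    bg <- data.frame(
      id1 = ids[i1[keep]], id2 = ids[i2[keep]],
      kinship = stats::rnorm(sum(keep), 0, noise_sd),
      ibd0 = clamp(0.96 + stats::rnorm(sum(keep), 0, noise_sd), 0, 1),
      ibd2 = clamp(abs(stats::rnorm(sum(keep), 0, noise_sd / 2)), 0, 1),
      stringsAsFactors = FALSE
    )
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    bg <- bg[!duplicated(key(bg$id1, bg$id2)), ]
    kin <- rbind(kin, bg)
  }
  rownames(kin) <- NULL
  kin
}

.write_vcf <- function(dosages, variants, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(dosages))) {
    row <- c(variants$chrom[j], format(variants$pos[j], scientific = FALSE),
             variants$snp[j], variants$oa[j], variants$ea[j], ".", "PASS",
             ".", "GT", gt_codes[dosages[, j] + 1L])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
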