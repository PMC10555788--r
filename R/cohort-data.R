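# Cohort data model and preprocessing: file readers, education-years coding,
# kinship-based sibship inference, residualization/standardization and the
# sibship-size restriction applied before any model fit.

.pheno_required <- c("iid", "fid", "sex", "birth_year", "edu_years",
                     "bmi", "packyears", "sbp",
                     "entry_age", "exit_age", "event")

#' Read a phenotype table
#'
#' Expects a tab-delimited file with columns `iid`, `fid`, `sex`,
#' `birth_year`, `edu_years`, `bmi`, `packyears`, `sbp`, `entry_age`,
#' `exit_age`, `event` (optional: `edu_cont`, `zygosity`). Malformed rows
#' are reported with their line number; duplicate individual ids are an
#' error.
#'
#' @param path path to the TSV file.
#' @return A `cohort_table` data frame.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, required = .pheno_required, what = "phenotype")
  df$iid <- as.character(df$iid)
  df$fid <- as.character(df$fid)
  dup <- df$iid[duplicated(df$iid)]
  if (length(dup)) {
    stop_sibmr("duplicate iid in phenotype file: ",
               paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(df$exit_age < df$entry_age, na.rm = TRUE)) {
    stop_sibmr("exit_age must be >= entry_age")
  }
  sib_log("read ", nrow(df), " individuals in ",
          length(unique(df$fid)), " sibships from ", basename(path))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a dosage matrix from TSV or minimal VCF
#'
#' TSV layout: first column `iid`, remaining columns one variant each with
#' dosages in `[0, 2]`. A VCF (extension `.vcf`) is read through the
#' `vcfR` package; GT fields are converted to counts of the ALT allele
#' (`0/1` -> 1), with missing genotypes becoming `NA`. Variant metadata
#' (snp, chrom, pos, effect/other allele) is attached as the
#' `variant_info` attribute, from the VCF itself or from an optional
#' sidecar table.
#'
#' @param path dosage TSV or VCF file.
#' @param variants optional path to a `variants.tsv` sidecar
#'   (snp, chrom, pos, ea, oa).
#' @return Numeric matrix, individuals x variants, rownames `iid`.
#' @export
read_dosages <- function(path, variants = NULL) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    mat <- .read_vcf_dosages(path)
  } else {
    df <- read_tsv_checked(path, required = "iid", what = "dosage")
    iid <- as.character(df$iid)
    if (anyDuplicated(iid)) stop_sibmr("duplicate iid in dosage file")
    mat <- as.matrix(df[setdiff(names(df), "iid")])
    if (!is.numeric(mat)) stop_sibmr("non-numeric dosage values in ", basename(path))
    rownames(mat) <- iid
    if (any(mat < 0 | mat > 2, na.rm = TRUE)) {
      stop_sibmr("dosages must lie in [0, 2]")
    }
  }
  if (!is.null(variants)) {
    vi <- read_tsv_checked(variants, required = c("snp", "chrom", "pos", "ea", "oa"),
                           what = "variant")
    attr(mat, "variant_info") <- vi
  }
  sib_log("read dosages: ", nrow(mat), " individuals x ", ncol(mat), " variants")
  mat
}

.read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  dos <- matrix(a1 + a2, nrow = nrow(gt), dimnames = dimnames(gt))
  mat <- t(dos)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  colnames(mat) <- fix$ID
  # ALT is the counted (effect) allele under the GT -> dosage conversion
  attr(mat, "variant_info") <- data.frame(
    snp = fix$ID, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ea = fix$ALT, oa = fix$REF, stringsAsFactors = FALSE
  )
  mat
}

#' Read a KING-style pairwise kinship table
#'
#' Columns: `id1`, `id2`, `kinship`, `ibd0`, `ibd2`. Unordered duplicate
#' pairs and out-of-range coefficients are errors.
#'
#' @param path path to the TSV file.
#' @return Data frame of kinship records.
#' @export
read_kinship <- function(path) {
  df <- read_tsv_checked(path, required = c("id1", "id2", "kinship", "ibd0", "ibd2"),
                         what = "kinship")
  df$id1 <- as.character(df$id1)
  df$id2 <- as.character(df$id2)
  if (any(df$kinship < -0.5 | df$kinship > 0.5)) {
    stop_sibmr("kinship coefficients must lie in [-0.5, 0.5]")
  }
  if (any(df$ibd0 < 0 | df$ibd0 > 1 | df$ibd2 < 0 | df$ibd2 > 1)) {
    stop_sibmr("IBD proportions must lie in [0, 1]")
  }
  key <- paste(pmin(df$id1, df$id2), pmax(df$id1, df$id2))
  if (anyDuplicated(key)) stop_sibmr("duplicate unordered pair in kinship file")
  sib_log("read ", nrow(df), " kinship pairs from ", basename(path))
  df
}

#' Education coding schemes
#'
#' Maps self-reported qualification labels to years of full-time
#' education. Built-in schemes:
#' \describe{
#'   \item{UKB}{questionnaire qualifications; a college or university
#'     degree counts 17 years, A levels/AS levels 14 years, with the
#'     remaining categories given conventional values.}
#'   \item{HUNT}{five survey categories: primary school 10, high school
#'     for 1 or 2 years 12, complete high school 13, college or
#'     university (either duration) 16 years.}
#'   \item{FINNTWIN}{eight categories from less than primary school
#'     (4 years) to university education (17 years); `other` is coded
#'     missing.}
#' }
#' Unknown labels map to missing, never to an error.
#'
#' @param name one of `"UKB"`, `"HUNT"`, `"FINNTWIN"` or `"custom"`.
#' @param mapping named numeric vector (label -> years) for a custom
#'   scheme; `NA` values mark labels deliberately coded as missing.
#' @param file optional two-column TSV (`label`, `years`) defining the
#'   scheme.
#' @return An `edu_scheme` object.
#' @export
edu_scheme <- function(name = c("UKB", "HUNT", "FINNTWIN", "custom"),
                       mapping = NULL, file = NULL) {
  name <- match.arg(name)
  if (!is.null(file)) {
    df <- read_tsv_checked(file, required = c("label", "years"), what = "education scheme")
    mapping <- stats::setNames(as.numeric(df$years), df$label)
    name <- "custom"
  }
  if (is.null(mapping)) {
    mapping <- switch(name,
      UKB = c(
        "College or University degree" = 17,
        "A levels/AS levels or equivalent" = 14,
        "NVQ or HND or HNC or equivalent" = 16,
        "Other professional qualifications eg: nursing, teaching" = 15,
        "O levels/GCSEs or equivalent" = 11,
        "CSEs or equivalent" = 10,
        "None of the above" = 7,
        "Prefer not to answer" = NA
      ),
      HUNT = c(
        "primary school" = 10,
        "high school for 1 or 2 years" = 12,
        "complete high school" = 13,
        "college or university for <4 years" = 16,
        "college or university for 4 or more years" = 16
      ),
      FINNTWIN = c(
        "less than primary school" = 4,
        "primary school" = 6,
        "junior high school" = 8,
        "vocational school" = 9,
        "senior high school" = 12,
        "vocational college" = 14,
        "lower university degree" = 15,
        "university education" = 17,
        "other" = NA
      ),
      custom = stop_sibmr("a custom scheme needs an explicit mapping")
    )
  }
  if (any(!is.na(mapping) & mapping <= 0)) stop_sibmr("years must be positive")
  structure(list(name = name, mapping = mapping), class = "edu_scheme")
}

#' Years of education from reported qualifications
#'
#' When an individual reports several qualifications, the highest
#' qualification in terms of years of education is used. Labels unknown
#' to the scheme (or mapped to `NA`) are ignored; if nothing maps, the
#' result is missing.
#'
#' @param qualifications a character vector (one individual) or a list of
#'   character vectors (one element per individual).
#' @param scheme an [edu_scheme()].
#' @return Numeric vector of years, `NA` where nothing maps.
#' @export
education_years <- function(qualifications, scheme) {
  stopifnot(inherits(scheme, "edu_scheme"))
  if (is.character(qualifications)) qualifications <- list(qualifications)
  vapply(qualifications, function(labs) {
    yrs <- scheme$mapping[labs]
    yrs <- yrs[!is.na(yrs)]
    if (length(yrs)) max(yrs) else NA_real_
  }, numeric(1))
}

#' Infer sibships from pairwise kinship estimates
#'
#' A pair is called full siblings when the kinship coefficient lies within
#' `kinship_range` and both IBD-sharing proportions exceed their
#' thresholds (the IBD0 criterion separates full siblings from
#' parent-offspring pairs, which share one allele everywhere). Sibships
#' are the connected components of the sibling-pair graph; singletons do
#' not appear in the output. The defaults are standard KING full-sibling
#' criteria.
#'
#' @param records data frame with `id1`, `id2`, `kinship`, `ibd0`, `ibd2`.
#' @param kinship_range inclusive kinship window for full siblings.
#' @param ibd2_min minimum proportion of the genome sharing two alleles IBD.
#' @param ibd0_min minimum proportion sharing zero alleles IBD.
#' @return Named list of character vectors, one per sibship, each sorted;
#'   the list is ordered by first member, making the partition canonical
#'   (order-invariant and idempotent).
#' @export
infer_sibships <- function(records, kinship_range = c(0.177, 0.355),
                           ibd2_min = 0.08, ibd0_min = 0.04) {
  if (is.null(records) || nrow(records) == 0L) return(list())
  ok <- records$kinship >= kinship_range[1] & records$kinship <= kinship_range[2] &
    records$ibd2 > ibd2_min & records$ibd0 > ibd0_min
  pairs <- records[ok, c("id1", "id2"), drop = FALSE]
  sib_log("sibling-pair criteria passed by ", nrow(pairs), " of ",
          nrow(records), " kinship pairs")
  if (nrow(pairs) == 0L) return(list())
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
  comp <- igraph::components(g)
  out <- split(names(comp$membership), comp$membership)
  out <- lapply(out, function(x) sort(unname(x)))
  out <- out[order(vapply(out, `[`, character(1), 1L))]
  names(out) <- sprintf("sibship%04d", seq_along(out))
  out
}

#' Residualize on birth year and sex, then standardize
#'
#' Computes OLS residuals of the values on an intercept, birth year and
#' sex, and scales them to mean 0, SD 1 (denominator `n - 1`). Missing
#' values (in the values or covariates) propagate to the output. This is
#' the standardization applied to the exposure, the continuous outcomes
#' and the polygenic score before any model fit.
#'
#' @param values numeric vector.
#' @param birth_year,sex optional covariates; `NULL` reduces to a plain
#'   z-score. Constant covariates are dropped automatically.
#' @return Numeric vector of z-scores with the same length as `values`.
#' @export
residualize_standardize <- function(values, birth_year = NULL, sex = NULL) {
  n <- length(values)
  df <- data.frame(.y = values)
  if (!is.null(birth_year)) df$.by <- birth_year
  if (!is.null(sex)) df$.sex <- sex
  ok <- stats::complete.cases(df)
  if (sum(ok) < 3L) stop_sibmr("need at least 3 complete observations")
  if (ncol(df) > 1L) {
    fit <- stats::lm(.y ~ ., data = df, na.action = stats::na.exclude)
    r <- stats::residuals(fit)
  } else {
    r <- values
    r[!ok] <- NA_real_
  }
  s <- stats::sd(r, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-12) {
    stop_sibmr("zero residual variance: cannot standardize")
  }
  as.numeric((r - mean(r, na.rm = TRUE)) / s)
}

#' Restrict to complete cases within sibships of a minimum size
#'
#' Applies per-analysis missingness filtering on the given variables, then
#' keeps only sibships that still have at least `min_size` members (a
#' within-sibship model needs two or more informative siblings). Counts
#' before and after are logged.
#'
#' @param cohort a cohort table.
#' @param vars character vector of columns that must be non-missing.
#' @param min_size minimum post-filter sibship size.
#' @return The filtered cohort table.
#' @export
filter_complete_sibships <- function(cohort, vars = character(0), min_size = 2L) {
  n0 <- nrow(cohort)
  keep <- rep(TRUE, n0)
  for (v in vars) keep <- keep & !is.na(cohort[[v]])
  out <- cohort[keep, , drop = FALSE]
  size <- table(out$fid)
  out <- out[out$fid %in% names(size)[size >= min_size], , drop = FALSE]
  sib_log("complete-case + sibship-size filter: ", n0, " -> ", nrow(out),
          " individuals in ", length(unique(out$fid)), " sibships")
  out
}
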