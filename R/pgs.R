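# Polygenic score construction: greedy LD clumping of GWAS summary
# statistics, weighted allele-count scoring with allele harmonization, and
# the residualize-on-age-and-sex standardization applied before analysis.

.sumstats_required <- c("snp", "chrom", "pos", "ea", "oa", "beta", "se", "p")

#' Read a GWAS summary-statistics table
#'
#' Columns: `snp`, `chrom`, `pos`, `ea` (effect allele), `oa` (other
#' allele), `beta`, `se`, `p`; an optional `model` column distinguishes
#' population from within-sibship estimates.
#'
#' @param path path to the TSV file.
#' @return Data frame of variant records.
#' @export
read_sumstats <- function(path) {
  df <- read_tsv_checked(path, required = .sumstats_required, what = "summary statistics")
  if (any(df$p <= 0 | df$p > 1, na.rm = TRUE)) stop_sibmr("p-values must lie in (0, 1]")
  if (any(df$ea == df$oa)) stop_sibmr("effect and other allele must differ")
  if (anyDuplicated(df[c("chrom", "pos")])) stop_sibmr("duplicate (chrom, pos) in sumstats")
  sib_log("read ", nrow(df), " variants from ", basename(path))
  df
}

#' Read a pairwise LD (r-squared) matrix
#'
#' Accepts either a square TSV (first column variant id, remaining columns
#' one variant each) or a long-form table with columns `id1`, `id2`, `r2`.
#' The result is symmetrized with a unit diagonal; pairs absent from a
#' long-form table are `NA` (unknown), which [clump()] treats as an error
#' when it needs them.
#'
#' @param path path to the TSV file.
#' @return Symmetric numeric matrix with variant-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  head1 <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (all(c("id1", "id2", "r2") %in% head1)) {
    df <- read_tsv_checked(path, required = c("id1", "id2", "r2"), what = "LD")
    ids <- sort(unique(c(df$id1, df$id2)))
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    m[cbind(df$id1, df$id2)] <- df$r2
    m[cbind(df$id2, df$id1)] <- df$r2
    return(m)
  }
  df <- read_tsv_checked(path, what = "LD")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  dimnames(m) <- list(ids, colnames(m))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) stop_sibmr("LD matrix must be symmetric")
  m
}

#' Identity LD matrix for unlinked variants
#'
#' @param snps variant ids.
#' @return Diagonal matrix (r-squared 1 on the diagonal, 0 elsewhere).
#' @export
identity_ld <- function(snps) {
  m <- diag(length(snps))
  dimnames(m) <- list(snps, snps)
  m
}

#' Greedy LD clumping of GWAS summary statistics
#'
#' Standard PLINK-style index-variant clumping: variants with
#' `p >= p_max` are dropped; then, repeatedly, the smallest-p remaining
#' variant becomes an index and every remaining variant on the same
#' chromosome within `window_kb` kilobases with `r2 >= r2_max` against it
#' is removed. Ties in p are broken by (chrom, pos) so the result is
#' invariant to input order. The defaults reproduce the conventional
#' genome-wide clumping thresholds (r2 < 0.001, 10 000 kb, p < 5e-8).
#'
#' @param variants data frame of variant records (see [read_sumstats()]).
#' @param ld symmetric r-squared matrix with variant-id dimnames; required
#'   whenever two surviving variants fall in the same window. Use
#'   [identity_ld()] for variants known to be unlinked.
#' @param r2_max r-squared at or above which a nearby variant is removed
#'   (strict `r2 < r2_max` survives).
#' @param window_kb physical distance threshold in kilobases.
#' @param p_max significance threshold (strict `p < p_max` retained).
#' @return The retained variant records, in p order.
#' @export
clump <- function(variants, ld = NULL, r2_max = 0.001, window_kb = 10000,
                  p_max = 5e-8) {
  if (r2_max <= 0 || window_kb <= 0 || p_max <= 0) {
    stop_sibmr("clumping parameters must be positive")
  }
  miss <- setdiff(c("snp", "chrom", "pos", "p"), names(variants))
  if (length(miss)) stop_sibmr("variants table missing column(s): ",
                               paste(miss, collapse = ", "))
  v <- variants[variants$p < p_max, , drop = FALSE]
  if (nrow(v) == 0L) return(v)
  v <- v[order(v$p, v$chrom, v$pos), , drop = FALSE]

  alive <- rep(TRUE, nrow(v))
  retained <- integer(0)
  for (i in seq_len(nrow(v))) {
    if (!alive[i]) next
    retained <- c(retained, i)
    alive[i] <- FALSE
    near <- which(alive & v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= window_kb * 1000)
    if (!length(near)) next
    if (is.null(ld)) {
      stop_sibmr("variants within the clumping window but no LD matrix supplied")
    }
    r2 <- rep(NA_real_, length(near))
    if (v$snp[i] %in% rownames(ld)) {
      idx <- match(v$snp[near], colnames(ld))
      r2[!is.na(idx)] <- ld[v$snp[i], idx[!is.na(idx)]]
    }
    if (anyNA(r2)) {
      stop_sibmr("LD unknown for pair(s) within the clumping window: ",
                 v$snp[i], " vs ",
                 paste(utils::head(v$snp[near][is.na(r2)], 5), collapse = ", "))
    }
    alive[near[r2 >= r2_max]] <- FALSE
  }
  out <- v[retained, , drop = FALSE]
  rownames(out) <- NULL
  sib_log("clumping retained ", nrow(out), " of ", nrow(variants), " variants")
  out
}

#' Compute a raw polygenic score
#'
#' `score_i = sum_k beta_k * dosage_ik` over the retained variants.
#' When allele metadata is available for the dosage matrix, variants whose
#' effect/other alleles are swapped relative to the counted allele are
#' harmonized by flipping the dosage (`2 - d`); irreconcilable allele
#' pairs are an error listing the offending variants.
#'
#' @param dosages individuals x variants matrix (columns named by snp id),
#'   optionally carrying a `variant_info` attribute with `ea`/`oa`.
#' @param variants variant records with `snp`, `beta`, `ea`, `oa`.
#' @param dosage_alleles optional data frame (`snp`, `ea`, `oa`) describing
#'   the counted allele of each dosage column; defaults to the
#'   `variant_info` attribute; `NULL` skips harmonization.
#' @return Named numeric vector of raw scores (one per individual).
#' @export
compute_pgs <- function(dosages, variants,
                        dosage_alleles = attr(dosages, "variant_info")) {
  idx <- match(variants$snp, colnames(dosages))
  if (anyNA(idx)) {
    stop_sibmr("variants absent from dosage matrix: ",
               paste(utils::head(variants$snp[is.na(idx)], 5), collapse = ", "))
  }
  D <- dosages[, idx, drop = FALSE]
  if (!is.null(dosage_alleles) && all(c("ea", "oa") %in% names(variants))) {
    j <- match(variants$snp, dosage_alleles$snp)
    if (anyNA(j)) {
      stop_sibmr("no allele metadata for variant(s): ",
                 paste(utils::head(variants$snp[is.na(j)], 5), collapse = ", "))
    }
    same <- variants$ea == dosage_alleles$ea[j] & variants$oa == dosage_alleles$oa[j]
    swap <- variants$ea == dosage_alleles$oa[j] & variants$oa == dosage_alleles$ea[j]
    bad <- !(same | swap)
    if (any(bad)) {
      stop_sibmr("unresolvable allele mismatch for variant(s): ",
                 paste(utils::head(variants$snp[bad], 5), collapse = ", "))
    }
    if (any(swap)) D[, swap] <- 2 - D[, swap, drop = FALSE]
  }
  drop(D %*% variants$beta)
}

#' Standardize a polygenic score for analysis
#'
#' Regresses the raw score on age and sex and returns the standardized
#' residuals (mean 0, SD 1); delegates to [residualize_standardize()].
#'
#' @param score raw polygenic score.
#' @param age,sex optional covariates.
#' @return Numeric vector of standardized residuals.
#' @export
prepare_pgs <- function(score, age = NULL, sex = NULL) {
  residualize_standardize(score, birth_year = age, sex = sex)
}
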