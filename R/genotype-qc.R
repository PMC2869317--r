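# Genotype quality control: sample call rate, genotypic sex check, and
# per-SNP filters (call rate, HWE exact p, minor-homozygote count, and
# imputation-quality metrics for imputed SNPs). All quoted exclusions are
# strict ("less than"), so equality at a threshold passes.

# Genotype class counts from dosages rounded to the nearest integer
# (round half to even), over non-missing entries.
dosage_counts <- function(d) {
  g <- round(d[!is.na(d)])
  c(n_AA = sum(g == 0), n_AB = sum(g == 1), n_BB = sum(g == 2))
}

#' Per-SNP quality metrics
#'
#' @param genotypes a `geno_matrix`.
#' @return data.frame with one row per SNP: call rate, MAF, exact HWE p,
#'   minor-homozygote count and the imputation metrics carried in `snp_info`.
#'   For X-chromosome SNPs the HWE test and homozygote counts use female
#'   samples only (males are hemizygous) when reported gender is available.
#' @export
snp_qc_metrics <- function(genotypes) {
  dos <- genotypes$dosages
  n <- nrow(dos)
  call_rate <- colMeans(!is.na(dos))
  female_rows <- NULL
  cv <- genotypes$covariates
  if (!is.null(cv) && !is.null(cv$gender))
    female_rows <- rownames(dos) %in% cv$sample[cv$gender == "F"]
  out <- data.frame(snp = colnames(dos), call_rate = call_rate,
                    maf = NA_real_, hwe_p = NA_real_,
                    n_minor_homozygotes = NA_integer_,
                    stringsAsFactors = FALSE, row.names = NULL)
  on_x <- genotypes$snp_info$chr %in% c("chrX", "X")
  for (j in seq_len(ncol(dos))) {
    dj <- if (on_x[j] && !is.null(female_rows)) dos[female_rows, j] else dos[, j]
    cts <- dosage_counts(dj)
    tot <- sum(cts)
    if (tot == 0) next
    p_b <- (2 * cts[["n_BB"]] + cts[["n_AB"]]) / (2 * tot)
    out$maf[j] <- min(p_b, 1 - p_b)
    out$hwe_p[j] <- hwe_exact_test(cts[["n_AA"]], cts[["n_AB"]], cts[["n_BB"]])
    out$n_minor_homozygotes[j] <- if (p_b < 0.5) cts[["n_BB"]]
      else if (p_b > 0.5) cts[["n_AA"]] else min(cts[["n_AA"]], cts[["n_BB"]])
  }
  cbind(out, genotypes$snp_info[, c("imputed", "imputation_r2", "posterior_avg")])
}

#' Apply the standard SNP filters
#'
#' Retains SNPs with call rate >= 0.95, exact HWE p >= 0.001, at least 3
#' minor homozygotes, and — for imputed SNPs — imputation r2 >= 0.3 and
#' posterior-probability average >= 0.8. Exclusions are strict inequalities
#' on the quoted thresholds, so values exactly at a threshold are retained.
#'
#' @param genotypes a `geno_matrix`.
#' @param call_rate_min,hwe_p_min,min_minor_hom,imputation_r2_min,posterior_avg_min
#'   filter thresholds.
#' @return list with `genotypes` (filtered) and `report` (per-SNP metrics,
#'   per-filter pass flags and a comma-separated `exclusion_reasons` column).
#' @export
apply_snp_filters <- function(genotypes, call_rate_min = 0.95,
                              hwe_p_min = 0.001, min_minor_hom = 3,
                              imputation_r2_min = 0.3,
                              posterior_avg_min = 0.8) {
  thr <- c(call_rate_min, hwe_p_min, imputation_r2_min, posterior_avg_min)
  if (any(thr < 0 | thr > 1)) stop2("filter thresholds must lie in [0, 1]")
  rep <- snp_qc_metrics(genotypes)
  rep$pass_call_rate <- rep$call_rate >= call_rate_min
  rep$pass_hwe <- is.na(rep$hwe_p) | rep$hwe_p >= hwe_p_min
  rep$pass_minor_hom <- !is.na(rep$n_minor_homozygotes) &
    rep$n_minor_homozygotes >= min_minor_hom
  rep$pass_imputation <- !rep$imputed |
    (rep$imputation_r2 >= imputation_r2_min & rep$posterior_avg >= posterior_avg_min)
  pass <- rep$pass_call_rate & rep$pass_hwe & rep$pass_minor_hom & rep$pass_imputation
  reasons <- character(nrow(rep))
  add <- function(reasons, bad, label) {
    reasons[bad] <- ifelse(reasons[bad] == "", label, paste(reasons[bad], label, sep = ","))
    reasons
  }
  reasons <- add(reasons, !rep$pass_call_rate, "call_rate")
  reasons <- add(reasons, !rep$pass_hwe, "hwe")
  reasons <- add(reasons, !rep$pass_minor_hom, "minor_homozygotes")
  reasons <- add(reasons, !rep$pass_imputation, "imputation_quality")
  rep$pass <- pass
  rep$exclusion_reasons <- reasons
  out <- genotypes
  out$dosages <- genotypes$dosages[, pass, drop = FALSE]
  out$truth_dosages <- genotypes$truth_dosages[, pass, drop = FALSE]
  out$snp_info <- genotypes$snp_info[pass, , drop = FALSE]
  out$maf_target <- genotypes$maf_target[pass]
  list(genotypes = out, report = rep)
}

#' Filter samples by call rate
#'
#' Works on a `geno_matrix` or a `trait_matrix` (for methylation the
#' "call" is a detection p-value at or below `det_p`). Samples with a
#' non-missing/detected fraction at or above `threshold` are retained.
#'
#' @param x a `geno_matrix` or `trait_matrix`.
#' @param threshold minimum call rate for inclusion (default 0.95).
#' @param det_p detection p-value cutoff defining a methylation "call".
#' @return character vector of retained sample IDs, with the per-sample call
#'   rates as attribute `call_rate`.
#' @export
sample_call_rate_filter <- function(x, threshold = 0.95, det_p = 0.01) {
  if (inherits(x, "geno_matrix")) {
    cr <- rowMeans(!is.na(x$dosages))
  } else if (inherits(x, "trait_matrix")) {
    cr <- rowMeans(x$detection <= det_p & !is.na(x$values))
  } else stop2("x must be a geno_matrix or trait_matrix")
  keep <- names(cr)[cr >= threshold]
  attr(keep, "call_rate") <- cr
  keep
}

#' Infer genotypic sex from X-chromosome heterozygosity
#'
#' Heterozygosity is the fraction of X SNPs with a rounded dosage of 1.
#' Samples below `male_max` are called male, above `female_min` female,
#' and in between undetermined. The cutoffs are conventional defaults,
#' tunable rather than fixed constants.
#'
#' @param genotypes a `geno_matrix` containing X-chromosome SNPs.
#' @param reported optional character vector (`"M"`/`"F"`, named by sample or
#'   in sample order) of reported sex to compare against.
#' @param male_max,female_min X-heterozygosity cutoffs.
#' @return data.frame with per-sample `x_heterozygosity`, `inferred`,
#'   `reported` and `mismatch`.
#' @export
infer_genotypic_sex <- function(genotypes, reported = NULL,
                                male_max = 0.02, female_min = 0.20) {
  x_snps <- genotypes$snp_info$chr %in% c("chrX", "X")
  if (sum(x_snps) < 10) stop2("need at least 10 X-chromosome SNPs")
  dx <- genotypes$dosages[, x_snps, drop = FALSE]
  het <- rowMeans(round(dx) == 1, na.rm = TRUE)
  inferred <- ifelse(het < male_max, "M", ifelse(het > female_min, "F", NA))
  out <- data.frame(sample = rownames(dx), x_heterozygosity = het,
                    inferred = inferred, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(reported)) {
    rep_v <- if (!is.null(names(reported))) reported[out$sample] else reported
    out$reported <- unname(rep_v)
    out$mismatch <- !is.na(out$inferred) & out$inferred != out$reported
  }
  out
}
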