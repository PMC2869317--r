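# Genome-wide allele-dosage regression with maxT label-swapping permutation
# empirical p-values. The per-trait scan is one matrix product between the
# (centered) dosage matrix and the observed-plus-permuted trait matrix, so a
# 2,000-SNP x 1,000-permutation scan is a single BLAS call. Missing dosages
# are handled pairwise-complete through indicator-matrix algebra.

#' Permutation plan for the maxT procedure
#'
#' @param n_perm number of label-swapping permutations (default 1000).
#' @param seed integer seed; the same seed reproduces the same permutations.
#' @return a `perm_plan` list.
#' @export
perm_plan <- function(n_perm = 1000, seed) {
  if (n_perm < 1) stop2("n_perm must be >= 1")
  if (missing(seed)) stop2("perm_plan() requires an explicit seed")
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 scheme = "label_swap"),
            class = "perm_plan")
}

#' Regress one trait on one SNP's allele dosage
#'
#' Ordinary least squares `trait = mu + beta * dosage` on pairwise-complete
#' observations; two-sided t-test p-value; `r2` is the squared Pearson
#' correlation; genotype counts come from dosages rounded to the nearest
#' integer (half to even).
#'
#' @param trait_values,dosages numeric vectors of equal length.
#' @return list with `beta`, `se`, `t`, `p`, `r2`, `n`, `counts`
#'   (`n_AA`,`n_AB`,`n_BB`) and `reason` (`NA` unless the pair was skipped
#'   for insufficient or degenerate data).
#' @export
regress_trait_on_dosage <- function(trait_values, dosages) {
  stopifnot(length(trait_values) == length(dosages))
  ok <- stats::complete.cases(trait_values, dosages)
  y <- trait_values[ok]; x <- dosages[ok]
  skip <- function(reason) list(beta = NA_real_, se = NA_real_, t = NA_real_,
                                p = NA_real_, r2 = NA_real_, n = sum(ok),
                                counts = dosage_counts(x), reason = reason)
  if (sum(ok) < 3) return(skip("fewer than 3 complete pairs"))
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  if (sxx == 0) return(skip("zero dosage variance"))
  if (syy == 0) return(skip("zero trait variance"))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  n <- length(x); df <- n - 2L
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  se <- sqrt(max(rss, 0) / df / sxx)
  tval <- if (se == 0) sign(beta) * Inf else beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), r2 = (sxy^2) / (sxx * syy),
       n = n, counts = dosage_counts(x), reason = NA_character_)
}

#' Squared-correlation linkage disequilibrium between two dosage vectors
#'
#' @param dosages_a,dosages_b allele-dosage vectors of equal length.
#' @return squared Pearson correlation on pairwise-complete entries, or `NA`
#'   when fewer than 3 complete pairs remain or a vector has zero variance.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  r2_of(dosages_a, dosages_b)
}

# Draw the n x n_perm matrix of permutation indices for one trait.
perm_indices <- function(n, plan) {
  with_seed(plan$seed, {
    matrix(unlist(lapply(seq_len(plan$n_perm), function(i) sample.int(n))),
           nrow = n, ncol = plan$n_perm)
  })
}

#' Genome-wide maxT scan of one trait
#'
#' Computes the dosage-regression t statistic of the trait against every SNP,
#' then the genome-wide maximum |t| under each of `n_perm` label-swapping
#' permutations of the trait vector (shared across SNPs, as maxT requires).
#' The empirical p-value of a SNP is
#' `(1 + #\{permutation maxima >= observed |t|\}) / (n_perm + 1)`.
#'
#' @param trait_values named numeric vector (names = sample IDs). Samples
#'   with a missing trait value are dropped before permutation.
#' @param genotypes a `geno_matrix`; dosages may contain missing entries
#'   (handled pairwise-complete per SNP).
#' @param plan a [perm_plan()].
#' @return data.frame with one row per SNP: `snp`, `beta`, `r2`, `t`,
#'   `pvalue` (asymptotic), `empP`, `n_AA`, `n_AB`, `n_BB`,
#'   `fraction_samples_used`, `skip_reason`.
#' @export
scan_trait <- function(trait_values, genotypes, plan) {
  stopifnot(inherits(plan, "perm_plan"))
  dos <- genotypes$dosages
  samples <- intersect(rownames(dos), names(trait_values))
  if (length(samples) == 0) stop2("no shared samples between trait and genotypes")
  y_full <- trait_values[samples]
  n_total <- length(y_full)
  ok <- !is.na(y_full)
  y <- y_full[ok]
  G <- dos[samples[ok], , drop = FALSE]
  m <- ncol(G); n <- length(y)
  K <- plan$n_perm + 1L

  empty <- function(reason) data.frame(
    snp = colnames(dos), beta = NA_real_, r2 = NA_real_, t = NA_real_,
    pvalue = NA_real_, empP = NA_real_, n_AA = NA_integer_,
    n_AB = NA_integer_, n_BB = NA_integer_,
    fraction_samples_used = NA_real_, skip_reason = reason,
    stringsAsFactors = FALSE)
  if (n < 3) return(empty("fewer than 3 complete trait values"))
  if (stats::sd(y) == 0) return(empty("zero trait variance"))

  idx <- perm_indices(n, plan)
  P <- cbind(y, matrix(y[idx], nrow = n, ncol = plan$n_perm))

  if (!anyNA(G)) {
    nj <- rep(n, m)
    Gc <- sweep(G, 2, colMeans(G))
    Pc <- sweep(P, 2, colMeans(P))
    sg2 <- colSums(Gc^2)
    sp2 <- colSums(Pc^2)
    num <- crossprod(Gc, Pc)                       # m x K
    den <- outer(sg2, sp2)
    r_all <- num / sqrt(pmax(den, .Machine$double.xmin))
    beta <- num[, 1] / sg2
    var_ok <- sg2 > n * .Machine$double.eps
  } else {
    Mna <- is.na(G)
    G0 <- G; G0[Mna] <- 0
    nj <- n - colSums(Mna)
    Sx <- colSums(G0); Sxx <- colSums(G0^2)
    Msp <- methods::as(Matrix::Matrix(Mna * 1, sparse = TRUE), "CsparseMatrix")
    Sxy <- crossprod(G0, P)                        # m x K
    Sy <- matrix(colSums(P), m, K, byrow = TRUE) -
      as.matrix(Matrix::crossprod(Msp, P))
    Syy <- matrix(colSums(P^2), m, K, byrow = TRUE) -
      as.matrix(Matrix::crossprod(Msp, P^2))
    num <- nj * Sxy - Sx * Sy
    denx <- nj * Sxx - Sx^2
    deny <- nj * Syy - Sy^2
    den <- denx * deny
    r_all <- num / sqrt(pmax(den, .Machine$double.xmin))
    beta <- ifelse(denx > 0, num[, 1] / denx, NA_real_)
    var_ok <- denx > nj * nj * .Machine$double.eps & nj >= 3L
  }
  r_all[r_all > 1] <- 1; r_all[r_all < -1] <- -1
  df <- pmax(nj - 2L, 1L)
  t_all <- r_all * sqrt(df / pmax(1 - r_all^2, 1e-300))
  t_all[!var_ok, ] <- NA_real_

  t_obs <- t_all[, 1]
  perm_max <- suppressWarnings(apply(abs(t_all[, -1, drop = FALSE]), 2, max, na.rm = TRUE))
  perm_max[!is.finite(perm_max)] <- NA_real_
  empP <- vapply(abs(t_obs), function(to) {
    if (is.na(to)) return(NA_real_)
    (1 + sum(perm_max >= to, na.rm = TRUE)) / (plan$n_perm + 1)
  }, numeric(1))

  Gr <- round(G)
  res <- data.frame(
    snp = colnames(G),
    beta = beta,
    r2 = r_all[, 1]^2,
    t = t_obs,
    pvalue = 2 * stats::pt(-abs(t_obs), df),
    empP = empP,
    n_AA = colSums(Gr == 0, na.rm = TRUE),
    n_AB = colSums(Gr == 1, na.rm = TRUE),
    n_BB = colSums(Gr == 2, na.rm = TRUE),
    fraction_samples_used = nj / n_total,
    skip_reason = ifelse(var_ok, NA_character_,
                         ifelse(nj < 3, "fewer than 3 complete pairs",
                                "zero dosage variance")),
    stringsAsFactors = FALSE, row.names = NULL)
  res$beta[!var_ok] <- NA_real_
  res$r2[!var_ok] <- NA_real_
  res$pvalue[!var_ok] <- NA_real_
  res$empP[!var_ok] <- NA_real_
  res
}

#' Scan every trait of a residualized matrix against all SNPs
#'
#' Runs [scan_trait()] for each probe. Permutations are drawn independently
#' per trait from seeds derived from `plan$seed` and the probe index, and are
#' shared across SNPs within the trait (the maxT requirement).
#'
#' @param resid a `residual_traits` object (or `trait_matrix`).
#' @param genotypes a `geno_matrix` (QC-filtered).
#' @param plan a [perm_plan()].
#' @param probes optional character vector restricting the probes scanned.
#' @return data.frame of QTL records: probe and SNP identities and
#'   coordinates, `beta`, `r2`, asymptotic `pvalue`, `empP`, genotype counts,
#'   `fraction_samples_used`, `cis_trans`/`distance` columns left for the
#'   annotation step.
#' @export
scan_tissue <- function(resid, genotypes, plan, probes = NULL) {
  vals <- resid$values
  pr <- resid$probes
  probes <- probes %||% colnames(vals)
  probes <- intersect(probes, colnames(vals))
  si <- genotypes$snp_info
  out <- vector("list", length(probes))
  for (i in seq_along(probes)) {
    p <- probes[i]
    # per-trait permutation stream keyed on the probe name, so traits of
    # different kinds or tissues never share permutations
    key <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) %% 1000003L
    tp <- perm_plan(plan$n_perm, derive_seed(plan$seed, key))
    rec <- scan_trait(vals[, p], genotypes, tp)
    meta <- pr[match(p, pr$probe), ]
    out[[i]] <- data.table::data.table(
      tissue = resid$tissue %||% NA_character_,
      probe = p, kind = resid$kind %||% meta$kind,
      probe_chr = meta$chr, probe_start = meta$start, probe_end = meta$end,
      probe_strand = meta$strand, probe_tss = meta$tss,
      probe_anchor = meta$anchor,
      snp = rec$snp, snp_chr = si$chr[match(rec$snp, si$snp)],
      snp_pos = si$pos[match(rec$snp, si$snp)],
      beta = rec$beta, r2 = rec$r2, t = rec$t, pvalue = rec$pvalue,
      empP = rec$empP, n_AA = rec$n_AA, n_AB = rec$n_AB, n_BB = rec$n_BB,
      fraction_samples_used = rec$fraction_samples_used,
      skip_reason = rec$skip_reason)
  }
  as.data.frame(data.table::rbindlist(out), stringsAsFactors = FALSE)
}
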