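# Trait preparation: detection filtering, rank-invariant normalization of
# mRNA intensities, outlier-sample exclusion, covariate residualization,
# methylation-based sex inference and clustering QC.

#' Select probes by detection rate
#'
#' A probe is kept in a tissue iff the fraction of that tissue's samples with
#' detection p-value at or below `det_p` is at least `min_frac` (both
#' boundaries inclusive).
#'
#' @param traits a [trait_matrix][simulate_traits] or named list of them (one
#'   per tissue, same probe panel).
#' @param det_p detection p-value cutoff (default 0.01).
#' @param min_frac minimum detected-sample fraction (default 0.95).
#' @return list with `retained` (per-tissue character vectors of probe IDs),
#'   `common` (probes detected in every tissue) and `overlap` (count of
#'   probes detected in exactly k tissues, k = 0..n_tissues).
#' @export
detection_filter <- function(traits, det_p = 0.01, min_frac = 0.95) {
  if (inherits(traits, "trait_matrix")) traits <- list(traits)
  if (is.null(names(traits)))
    names(traits) <- vapply(traits, function(t) t$tissue %||% "tissue", character(1))
  retained <- lapply(traits, function(tm) {
    dp <- tm$detection
    if (anyNA(dp)) {
      bad <- colnames(dp)[colSums(is.na(dp)) > 0]
      stop2("missing detection p-values for probe(s): ",
            paste(utils::head(bad, 5), collapse = ", "))
    }
    frac <- colMeans(dp <= det_p)
    colnames(dp)[frac >= min_frac]
  })
  all_probes <- colnames(traits[[1]]$detection)
  k <- rowSums(vapply(retained, function(r) all_probes %in% r,
                      logical(length(all_probes))))
  overlap <- table(factor(k, levels = 0:length(traits)))
  list(retained = retained,
       common = all_probes[k == length(traits)],
       overlap = overlap)
}

#' Rank-invariant normalization of mRNA intensities
#'
#' Each sample is scaled onto a reference pseudo-sample (the per-probe median
#' across samples). The rank-invariant probe set is selected as probes whose
#' rank in the sample differs from their rank in the reference by at most
#' `rank_tolerance * n_probes`; selection is iterated until the set is stable
#' (at most `max_iter` rounds). A linear scaling through the origin is fitted
#' on that set and applied to all probes, then values are log2 transformed.
#'
#' @param traits a `trait_matrix` of strictly positive raw intensities.
#' @param rank_tolerance rank-difference tolerance as a fraction of the probe
#'   count (default 0.05).
#' @param max_iter iteration cap for the invariant-set selection.
#' @return the `trait_matrix` with log2-normalized values; per-sample scale
#'   factors in attribute `scale_factors`.
#' @export
rank_invariant_normalize <- function(traits, rank_tolerance = 0.05,
                                     max_iter = 10) {
  stopifnot(inherits(traits, "trait_matrix"))
  x <- traits$values
  if (any(is.na(x)) || any(x <= 0))
    stop2("rank-invariant normalization requires strictly positive intensities")
  np <- ncol(x)
  ref <- apply(x, 2, stats::median)
  rref <- rank(ref, ties.method = "average")
  tol <- rank_tolerance * np
  scales <- numeric(nrow(x))
  out <- x
  for (i in seq_len(nrow(x))) {
    s <- x[i, ]
    set <- rep(TRUE, np)
    for (iter in seq_len(max_iter)) {
      new_set <- abs(rank(s, ties.method = "average") - rref) <= tol
      if (!any(new_set))
        stop2("empty rank-invariant set for sample ", rownames(x)[i],
              "; increase rank_tolerance")
      if (identical(new_set, set) && iter > 1) break
      set <- new_set
      # scaling preserves ranks, so the set is stable after one refit
      s <- x[i, ] * sum(ref[set] * x[i, set]) / sum(x[i, set]^2)
    }
    scales[i] <- sum(ref[set] * x[i, set]) / sum(x[i, set]^2)
    out[i, ] <- log2(x[i, ] * scales[i])
  }
  traits$values <- out
  attr(traits, "scale_factors") <- stats::setNames(scales, rownames(x))
  traits
}

#' Exclude outlier samples on detection rate or mean trait level
#'
#' A sample is excluded when its overall probe detection rate or its mean
#' trait value lies more than `k_sd` standard deviations from the tissue
#' mean. Both metrics are returned for reporting.
#'
#' @param traits a `trait_matrix` (>= 5 samples).
#' @param k_sd exclusion cutoff in standard deviations (default 3).
#' @param det_p detection p-value defining a detected probe.
#' @return character vector of retained samples; data.frame of per-sample
#'   metrics and flags in attribute `metrics`.
#' @export
exclude_outlier_samples <- function(traits, k_sd = 3, det_p = 0.01) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (nrow(traits$values) < 5) stop2("need at least 5 samples")
  det_rate <- rowMeans(traits$detection <= det_p)
  mean_val <- rowMeans(traits$values, na.rm = TRUE)
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  z_det <- zs(det_rate); z_mean <- zs(mean_val)
  out_flag <- abs(z_det) > k_sd | abs(z_mean) > k_sd
  metrics <- data.frame(sample = rownames(traits$values),
                        detection_rate = det_rate, mean_value = mean_val,
                        z_detection = z_det, z_mean = z_mean,
                        excluded = out_flag, row.names = NULL,
                        stringsAsFactors = FALSE)
  keep <- metrics$sample[!out_flag]
  attr(keep, "metrics") <- metrics
  keep
}

# Build the covariate design matrix: age and PMI numeric, gender/bank/batch
# dummy-coded. Rank-deficient columns (after pivoted QR) are dropped with a
# warning, e.g. a batch level carried by a single already-spanned sample.
covariate_design <- function(covariates, samples) {
  idx <- match(samples, covariates$sample)
  if (anyNA(idx)) stop2("covariates missing for sample(s): ",
                        paste(samples[is.na(idx)], collapse = ", "))
  cv <- covariates[idx, , drop = FALSE]
  for (col in c("gender", "bank", "batch"))
    if (col %in% names(cv)) cv[[col]] <- factor(cv[[col]])
  terms <- intersect(c("age", "pmi", "gender", "bank", "batch"), names(cv))
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, data = cv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    warning("dropping rank-deficient covariate column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "), call. = FALSE)
    X <- X[, -drop_cols, drop = FALSE]
  }
  X
}

#' Residualize traits on known covariates
#'
#' Per probe, ordinary least squares of the trait on age and post-mortem
#' interval (numeric) plus gender, tissue bank and batch (dummy-coded). The
#' residuals replace the trait in all downstream analyses; the covariate
#' model R-squared is recorded per probe. Probes with missing values are fit
#' on their complete cases, leaving `NA` residuals elsewhere.
#'
#' @param traits a `trait_matrix` (CpG values raw, mRNA values log2).
#' @param covariates data.frame with columns `sample`, `age`, `gender`,
#'   `pmi`, `bank`, `batch`.
#' @return a `residual_traits` object: `values` (residual matrix with input
#'   dimnames), `covariate_r2` per probe, `probes`, `kind`, `tissue`, and the
#'   design column names used in `model`.
#' @export
residualize <- function(traits, covariates) {
  stopifnot(inherits(traits, "trait_matrix"))
  Y <- traits$values
  X <- covariate_design(covariates, rownames(Y))
  qrX <- qr(X)
  res <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  r2 <- stats::setNames(rep(NA_real_, ncol(Y)), colnames(Y))
  complete_rows <- !apply(is.na(Y), 2, any)
  if (any(complete_rows)) {
    Yc <- Y[, complete_rows, drop = FALSE]
    R <- qr.resid(qrX, Yc)
    res[, complete_rows] <- R
    tot <- colSums(scale(Yc, scale = FALSE)^2)
    r2[complete_rows] <- ifelse(tot == 0, 0, 1 - colSums(R^2) / tot)
  }
  for (j in which(!complete_rows)) {
    ok <- !is.na(Y[, j])
    if (sum(ok) <= ncol(X)) next
    Xj <- X[ok, , drop = FALSE]
    qj <- qr(Xj)
    rj <- qr.resid(qj, Y[ok, j])
    res[ok, j] <- rj
    tot <- sum((Y[ok, j] - mean(Y[ok, j]))^2)
    r2[j] <- if (tot == 0) 0 else 1 - sum(rj^2) / tot
  }
  structure(list(values = res, covariate_r2 = r2, probes = traits$probes,
                 kind = traits$kind, tissue = traits$tissue,
                 model = colnames(X)),
            class = "residual_traits")
}

#' Infer sex from X-chromosome CpG methylation
#'
#' Two-group clustering of samples on their X-chromosome CpG profiles, with
#' deterministic centre initialization at the samples with the lowest and
#' highest mean X methylation. The higher-methylation group is labelled
#' female (mosaic X inactivation leaves female X CpGs partially methylated).
#'
#' @param traits a CpG `trait_matrix` whose probe table includes chrX probes.
#' @param reported optional reported sex (`"M"`/`"F"`) to compare against.
#' @param min_probes minimum number of X probes required (default 10).
#' @return data.frame with per-sample `mean_x_methylation`, `inferred`, and
#'   (when `reported` is given) `reported` and `mismatch`.
#' @export
infer_methylation_sex <- function(traits, reported = NULL, min_probes = 10) {
  stopifnot(inherits(traits, "trait_matrix"))
  xp <- traits$probes$probe[traits$probes$chr %in% c("chrX", "X")]
  xp <- intersect(xp, colnames(traits$values))
  if (length(xp) < min_probes)
    stop2("need at least ", min_probes, " X-chromosome CpG probes")
  M <- traits$values[, xp, drop = FALSE]
  if (nrow(M) < 2) stop2("need at least 2 samples")
  mm <- rowMeans(M, na.rm = TRUE)
  centers <- M[c(which.min(mm), which.max(mm)), , drop = FALSE]
  assign_prev <- rep(0L, nrow(M))
  for (iter in 1:100) {
    d1 <- rowSums((M - matrix(centers[1, ], nrow(M), ncol(M), byrow = TRUE))^2)
    d2 <- rowSums((M - matrix(centers[2, ], nrow(M), ncol(M), byrow = TRUE))^2)
    grp <- ifelse(d1 <= d2, 1L, 2L)
    if (identical(grp, assign_prev)) break
    assign_prev <- grp
    for (g in 1:2) if (any(grp == g)) centers[g, ] <- colMeans(M[grp == g, , drop = FALSE])
  }
  means <- tapply(mm, grp, mean)
  female_grp <- as.integer(names(means)[which.max(means)])
  inferred <- ifelse(grp == female_grp, "F", "M")
  out <- data.frame(sample = rownames(M), mean_x_methylation = mm,
                    inferred = inferred, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(reported)) {
    rep_v <- if (!is.null(names(reported))) reported[out$sample] else reported
    out$reported <- unname(rep_v)
    out$mismatch <- out$inferred != out$reported
  }
  out
}

#' Average-linkage clustering of samples
#'
#' Agglomerative average-linkage (UPGMA) clustering on Euclidean distances
#' between sample trait profiles, serialized as a Newick tree. For CpG data,
#' `autosomes_only` restricts to autosomal probes (X probes otherwise induce
#' gender sub-clusters).
#'
#' @param traits a `trait_matrix`, or a numeric matrix (samples x probes).
#' @param autosomes_only drop chrX/chrY probes before clustering.
#' @return Newick string (length-1 character); the `hclust` object is
#'   attached as attribute `hclust`.
#' @export
cluster_samples <- function(traits, autosomes_only = FALSE) {
  if (inherits(traits, "trait_matrix")) {
    M <- traits$values
    if (autosomes_only) {
      auto <- !(traits$probes$chr %in% c("chrX", "X", "chrY", "Y"))
      M <- M[, traits$probes$probe[auto][traits$probes$probe[auto] %in% colnames(M)],
             drop = FALSE]
    }
  } else M <- as.matrix(traits)
  if (nrow(M) < 2) stop2("need at least 2 samples")
  if (anyNA(M) || any(!is.finite(M))) stop2("clustering input contains NA/NaN")
  hc <- stats::hclust(stats::dist(M, method = "euclidean"), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  attr(nwk, "hclust") <- hc
  nwk
}
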