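# Downstream integration: cis/trans enrichment and its distance-threshold
# scan, cross-tissue comparison, ternary coordinates, SNP-CpG-mRNA triplets
# and the subsampling analysis. The enrichment universe is always the full
# set of tested SNP-probe pairs, significant or not.

enrichment_counts <- function(is_cis, is_sig) {
  c(n_sig_cis = sum(is_cis & is_sig), n_sig_trans = sum(!is_cis & is_sig),
    n_possible_cis = sum(is_cis), n_possible_trans = sum(!is_cis))
}

fold_from_counts <- function(cts) {
  if (cts[["n_possible_cis"]] == 0 || cts[["n_possible_trans"]] == 0)
    return(NA_real_)
  prop_cis <- cts[["n_sig_cis"]] / cts[["n_possible_cis"]]
  prop_trans <- cts[["n_sig_trans"]] / cts[["n_possible_trans"]]
  if (prop_trans == 0) {
    if (prop_cis == 0) return(NA_real_)
    return(Inf)
  }
  prop_cis / prop_trans
}

#' Cis versus trans enrichment of significant QTLs
#'
#' The fold is the ratio of the significant fraction among possible cis
#' pairs to the significant fraction among possible trans pairs, where the
#' universe of possible pairs is every tested SNP-probe combination
#' (significant or not) at the given window.
#'
#' @param records annotated, significance-called QTL records for the full
#'   tested universe (must carry `class_distance`, `snp_chr`, `probe_chr`
#'   and `significant` columns).
#' @param window cis window in bp (default 1e6).
#' @return list with the four counts, `fold`, and `infinite` flag (no
#'   significant trans pair).
#' @export
enrichment_fold <- function(records, window = 1e6) {
  same <- records$snp_chr == records$probe_chr
  is_cis <- same & !is.na(records$class_distance) &
    records$class_distance <= window
  cts <- enrichment_counts(is_cis, records$significant)
  if (cts[["n_possible_cis"]] == 0) stop2("no possible cis pairs in universe")
  if (cts[["n_possible_trans"]] == 0) stop2("no possible trans pairs in universe")
  fold <- fold_from_counts(cts)
  c(as.list(cts), list(fold = fold, infinite = is.infinite(fold),
                       window = window))
}

#' Enrichment scan over geometrically shrinking cis windows
#'
#' Thresholds are `max_window * ratio^k` for `k = 0 .. n_thresholds - 1`
#' (each distance four-fifths the size of the next larger one at the
#' default). At each threshold, pairs are re-classified cis/trans and the
#' enrichment fold recomputed from the proportions of significant pairs
#' among possible pairs. The peak is the threshold maximizing the fold;
#' infinite folds outrank finite ones and ties go to the smallest threshold.
#'
#' @param records as for [enrichment_fold()].
#' @param n_thresholds number of thresholds (default 50).
#' @param ratio geometric ratio in (0,1) (default 4/5).
#' @param max_window largest threshold in bp (default 1e6).
#' @return list with `scan` (data.frame threshold, counts, fold, infinite)
#'   and `peak_threshold`.
#' @export
enrichment_distance_scan <- function(records, n_thresholds = 50, ratio = 4 / 5,
                                     max_window = 1e6) {
  if (ratio <= 0 || ratio >= 1) stop2("ratio must be in (0, 1)")
  thresholds <- max_window * ratio^(seq_len(n_thresholds) - 1)
  same <- records$snp_chr == records$probe_chr
  d <- records$class_distance
  rows <- lapply(thresholds, function(th) {
    is_cis <- same & !is.na(d) & d <= th
    cts <- enrichment_counts(is_cis, records$significant)
    fold <- fold_from_counts(cts)
    data.frame(threshold = th, t(cts), fold = fold,
               infinite = is.infinite(fold))
  })
  scan <- do.call(rbind, rows)
  rank_key <- ifelse(is.na(scan$fold), -Inf, scan$fold)
  best <- which(rank_key == max(rank_key))
  peak <- min(scan$threshold[best])    # ties: smallest threshold wins
  list(scan = scan, peak_threshold = peak)
}

#' Cross-tissue table of QTL pairs significant in at least one tissue
#'
#' Takes the union over tissues of significant SNP-probe pairs and reports,
#' for every such pair, the regression r-squared and significance flag in
#' every tissue (including tissues where the pair is non-significant), plus
#' counts of pairs significant in exactly k tissues.
#'
#' @param records_list named list of annotated, significance-called record
#'   data.frames, one per tissue (same trait kind).
#' @return list with `pairs` (one row per union pair, per-tissue `r2_*` and
#'   `sig_*` columns, `n_tissues_significant`), `by_k` (pair counts by
#'   number of significant tissues) and `all_tissues` (probe/SNP/pair counts
#'   significant in every tissue).
#' @export
cross_tissue_table <- function(records_list) {
  if (length(records_list) < 2) stop2("need at least 2 tissues")
  empty <- vapply(records_list, function(r) nrow(r) == 0, logical(1))
  if (any(empty)) {
    warning("excluding tissue(s) with no records: ",
            paste(names(records_list)[empty], collapse = ", "), call. = FALSE)
    records_list <- records_list[!empty]
  }
  tissues <- names(records_list)
  key <- function(r) paste(r$probe, r$snp, sep = "|")
  sig_keys <- unique(unlist(lapply(records_list, function(r) key(r)[r$significant])))
  if (length(sig_keys) == 0) {
    warning("no significant pairs in any tissue", call. = FALSE)
    return(list(pairs = data.frame(), by_k = table(integer(0)),
                all_tissues = c(pairs = 0, probes = 0, snps = 0)))
  }
  parts <- do.call(rbind, strsplit(sig_keys, "|", fixed = TRUE))
  pairs <- data.frame(probe = parts[, 1], snp = parts[, 2],
                      stringsAsFactors = FALSE)
  for (t in tissues) {
    r <- records_list[[t]]
    i <- match(sig_keys, key(r))
    pairs[[paste0("r2_", t)]] <- r$r2[i]
    pairs[[paste0("sig_", t)]] <- !is.na(i) & r$significant[i]
  }
  sig_cols <- paste0("sig_", tissues)
  pairs$n_tissues_significant <- rowSums(as.matrix(pairs[sig_cols]))
  by_k <- table(factor(pairs$n_tissues_significant, levels = seq_along(tissues)))
  all_t <- pairs$n_tissues_significant == length(tissues)
  list(pairs = pairs, by_k = by_k,
       all_tissues = c(pairs = sum(all_t),
                       probes = length(unique(pairs$probe[all_t])),
                       snps = length(unique(pairs$snp[all_t]))))
}

#' Barycentric (ternary) coordinates of per-tissue effect sizes
#'
#' Each triple of non-negative r-squared values is normalized by its sum;
#' points near the centre indicate equal effects across the three tissues,
#' and the cumulative value (the sum) carries the overall effect size.
#'
#' @param r2 numeric matrix (or vector) with 3 columns of non-negative
#'   values.
#' @return list with `coords` (rows summing to 1; all-zero rows dropped),
#'   `cumulative`, and `skipped` (row indices of all-zero triples).
#' @export
ternary_coordinates <- function(r2) {
  if (is.null(dim(r2))) r2 <- matrix(r2, nrow = 1)
  if (ncol(r2) != 3) stop2("need exactly 3 columns")
  if (any(r2 < 0, na.rm = TRUE)) stop2("values must be non-negative")
  s <- rowSums(r2)
  skipped <- which(is.na(s) | s == 0)
  keep <- setdiff(seq_len(nrow(r2)), skipped)
  list(coords = r2[keep, , drop = FALSE] / s[keep],
       cumulative = s[keep], skipped = skipped)
}

#' Build SNP-CpG-mRNA triplets around shared cis QTLs
#'
#' CpG-mRNA pairs with the CpG within `window` of the mRNA TSS, where at
#' least one member has a significant cis QTL, are expanded by every SNP
#' significantly cis-associated with either member. Each triplet records
#' both effects (the non-significant side contributes its observed,
#' unthresholded beta and r-squared when the pair was tested, else 0), the
#' squared CpG-mRNA trait correlation, and the effect-sign quadrant
#' (`sign(methqtl_beta)` then `sign(eqtl_beta)`; "+-" is the
#' methylation-positive / expression-negative quadrant).
#'
#' @param meth_records,eqtl_records annotated, significance-called records.
#' @param cpg_values,mrna_values trait matrices (samples x probes) used for
#'   the CpG-mRNA correlation (CpG raw/residual, mRNA residual/log2).
#' @param window CpG-to-TSS window in bp (default 1e6).
#' @param islands optional island membership data.frame (`probe`,
#'   `in_island`) for the island summary.
#' @return list with `triplets` (one row per SNP-CpG-mRNA combination,
#'   `shared` flag, `quadrant`) and `summary` (fraction shared, mean
#'   |CpG-TSS| distance and mean CpG-mRNA r2 for shared vs all considered,
#'   and fraction of in-island shared triplets with opposite-sign effects).
#' @export
build_triplets <- function(meth_records, eqtl_records, cpg_values,
                           mrna_values, window = 1e6, islands = NULL) {
  mr <- meth_records; er <- eqtl_records
  if (!is.null(rownames(cpg_values)) && !is.null(rownames(mrna_values))) {
    shared_samples <- intersect(rownames(cpg_values), rownames(mrna_values))
    if (length(shared_samples) < 3)
      stop2("fewer than 3 samples shared between the CpG and mRNA matrices")
    cpg_values <- cpg_values[shared_samples, , drop = FALSE]
    mrna_values <- mrna_values[shared_samples, , drop = FALSE]
  }
  cpg_anno <- unique(mr[, c("probe", "probe_chr", "probe_anchor")])
  mrna_anno <- unique(er[, c("probe", "probe_chr", "probe_tss")])
  if (anyNA(mrna_anno$probe_tss))
    stop2("mRNA probes without TSS: ",
          paste(mrna_anno$probe[is.na(mrna_anno$probe_tss)], collapse = ", "))
  sig_m <- mr[mr$significant & mr$cis_trans == "cis", , drop = FALSE]
  sig_e <- er[er$significant & er$cis_trans == "cis", , drop = FALSE]

  trip <- list()
  for (ci in seq_len(nrow(cpg_anno))) {
    cp <- cpg_anno$probe[ci]
    near <- mrna_anno[mrna_anno$probe_chr == cpg_anno$probe_chr[ci] &
                        abs(mrna_anno$probe_tss - cpg_anno$probe_anchor[ci]) <= window, ,
                      drop = FALSE]
    if (nrow(near) == 0) next
    for (mi in seq_len(nrow(near))) {
      mp <- near$probe[mi]
      snps_m <- sig_m$snp[sig_m$probe == cp]
      snps_e <- sig_e$snp[sig_e$probe == mp]
      snps <- union(snps_m, snps_e)
      if (length(snps) == 0) next
      cmr2 <- r2_of(cpg_values[, cp], mrna_values[, mp])
      cm_sign <- sign(stats::cor(cpg_values[, cp], mrna_values[, mp],
                                 use = "pairwise.complete.obs"))
      for (s in snps) {
        m_row <- mr[mr$probe == cp & mr$snp == s, , drop = FALSE]
        e_row <- er[er$probe == mp & er$snp == s, , drop = FALSE]
        m_sig <- s %in% snps_m
        e_sig <- s %in% snps_e
        m_beta <- if (nrow(m_row) && !is.na(m_row$beta[1])) m_row$beta[1] else 0
        e_beta <- if (nrow(e_row) && !is.na(e_row$beta[1])) e_row$beta[1] else 0
        quadrant <- paste0(ifelse(m_beta >= 0, "+", "-"),
                           ifelse(e_beta >= 0, "+", "-"))
        trip[[length(trip) + 1L]] <- data.frame(
          snp = s, cpg_probe = cp, mrna_probe = mp,
          methqtl_beta = m_beta,
          methqtl_r2 = if (nrow(m_row) && !is.na(m_row$r2[1])) m_row$r2[1] else 0,
          methqtl_significant = m_sig,
          eqtl_beta = e_beta,
          eqtl_r2 = if (nrow(e_row) && !is.na(e_row$r2[1])) e_row$r2[1] else 0,
          eqtl_significant = e_sig,
          cpg_mrna_r2 = cmr2, cpg_mrna_sign = cm_sign,
          cpg_tss_distance = cpg_anno$probe_anchor[ci] - near$probe_tss[mi],
          shared = m_sig && e_sig, quadrant = quadrant,
          stringsAsFactors = FALSE)
      }
    }
  }
  triplets <- if (length(trip)) do.call(rbind, trip) else
    data.frame(snp = character(), cpg_probe = character(),
               mrna_probe = character(), methqtl_beta = numeric(),
               methqtl_r2 = numeric(), methqtl_significant = logical(),
               eqtl_beta = numeric(), eqtl_r2 = numeric(),
               eqtl_significant = logical(), cpg_mrna_r2 = numeric(),
               cpg_mrna_sign = numeric(), cpg_tss_distance = numeric(),
               shared = logical(), quadrant = character(),
               stringsAsFactors = FALSE)
  sh <- triplets$shared
  opp_frac <- NA_real_
  if (!is.null(islands) && any(sh)) {
    in_isl <- islands$in_island[match(triplets$cpg_probe, islands$probe)]
    sel <- sh & !is.na(in_isl) & in_isl
    if (any(sel))
      opp_frac <- mean(sign(triplets$methqtl_beta[sel]) !=
                         sign(triplets$eqtl_beta[sel]))
  }
  summary <- list(
    n_triplets = nrow(triplets), n_shared = sum(sh),
    fraction_shared = if (nrow(triplets)) mean(sh) else NA_real_,
    mean_abs_tss_distance_shared = if (any(sh)) mean(abs(triplets$cpg_tss_distance[sh])) else NA_real_,
    mean_abs_tss_distance_all = if (nrow(triplets)) mean(abs(triplets$cpg_tss_distance)) else NA_real_,
    mean_cpg_mrna_r2_shared = if (any(sh)) mean(triplets$cpg_mrna_r2[sh], na.rm = TRUE) else NA_real_,
    mean_cpg_mrna_r2_all = if (nrow(triplets)) mean(triplets$cpg_mrna_r2, na.rm = TRUE) else NA_real_,
    fraction_island_shared_opposite_sign = opp_frac)
  list(triplets = triplets, summary = summary)
}

#' Subsampling analysis of QTL detection rates
#'
#' Repeatedly draws sample subsets from a core set (without replacement),
#' reruns the scan and significance call on each subset, and records three
#' metrics per iteration: the percentage of probes with at least one
#' significant QTL, the mean number of significant SNPs per such probe, and
#' the mean r-squared of significant pairs.
#'
#' @param resid a `residual_traits` object.
#' @param genotypes a `geno_matrix`.
#' @param core_samples character vector of core sample IDs.
#' @param n_iter number of iterations (>= 1).
#' @param subset_size samples drawn per iteration (default core size - 10).
#' @param seed integer seed.
#' @param n_perm permutations per scan (default 200).
#' @param q FDR level (default 0.05).
#' @return data.frame with one row per iteration: `pct_probes_with_qtl`,
#'   `mean_snps_per_probe`, `mean_r2`.
#' @export
subsample_qtl_rates <- function(resid, genotypes, core_samples, n_iter,
                                subset_size = length(core_samples) - 10,
                                seed, n_perm = 200, q = 0.05) {
  if (n_iter < 1) stop2("n_iter must be >= 1")
  if (subset_size > length(core_samples))
    stop2("subset_size exceeds core sample count")
  subsets <- with_seed(derive_seed(seed, 11L), {
    lapply(seq_len(n_iter), function(i) sample(core_samples, subset_size))
  })
  rows <- lapply(seq_len(n_iter), function(i) {
    ss <- subsets[[i]]
    r_sub <- resid
    r_sub$values <- resid$values[ss, , drop = FALSE]
    g_sub <- subset_samples(genotypes, ss)
    plan <- perm_plan(n_perm, derive_seed(seed, 100L + i))
    rec <- scan_tissue(r_sub, g_sub, plan)
    rec <- call_significant(rec, g_sub, q = q)
    sig <- rec[rec$significant, , drop = FALSE]
    n_probes <- length(unique(rec$probe))
    hit_probes <- unique(sig$probe)
    data.frame(
      pct_probes_with_qtl = 100 * length(hit_probes) / n_probes,
      mean_snps_per_probe = if (length(hit_probes))
        nrow(sig) / length(hit_probes) else 0,
      mean_r2 = if (nrow(sig)) mean(sig$r2) else NA_real_)
  })
  do.call(rbind, rows)
}
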