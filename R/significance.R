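# Trait-level significance: Benjamini-Hochberg FDR across per-trait best
# empirical p-values fixes an empirical-p threshold; SNP-trait pairs at or
# below the threshold are significant, and SNPs in strong LD (r2 >= 0.7)
# with a significant SNP for the same trait are rescued.

# BH step-up threshold: the largest p among rejected hypotheses, or -Inf
# when nothing is rejected.
bh_threshold <- function(p, q) {
  p <- p[!is.na(p)]
  m <- length(p)
  if (m == 0) return(-Inf)
  ps <- sort(p)
  ok <- ps <= q * seq_len(m) / m
  if (!any(ok)) return(-Inf)
  ps[max(which(ok))]
}

#' Call significant QTLs with FDR thresholding and LD rescue
#'
#' Within each tissue-by-trait-kind group, each trait is represented by its
#' best (minimum) empirical p-value; Benjamini-Hochberg at level `q` across
#' traits fixes an empirical-p threshold, and every SNP-trait pair at or
#' below that threshold is significant. Additionally, for each trait, any SNP
#' whose dosage r-squared with one of that trait's significant SNPs is at
#' least `ld_r2_rescue` is marked significant with `rescue = TRUE`.
#'
#' @param records QTL record data.frame from [scan_tissue()] (may combine
#'   tissues/kinds; grouping is by `tissue` and `kind` columns).
#' @param genotypes the `geno_matrix` the records were scanned against
#'   (needed for LD rescue); `NULL` disables rescue.
#' @param q FDR level across traits (default 0.05).
#' @param ld_r2_rescue LD r-squared rescue threshold (default 0.7).
#' @return `records` with logical columns `significant` and `rescue`; the
#'   per-group empirical-p thresholds are attached as attribute
#'   `fdr_thresholds` (data.frame tissue, kind, threshold, n_traits).
#' @export
call_significant <- function(records, genotypes = NULL, q = 0.05,
                             ld_r2_rescue = 0.7) {
  if (nrow(records) == 0) {
    records$significant <- logical(0)
    records$rescue <- logical(0)
    return(records)
  }
  records$significant <- FALSE
  records$rescue <- FALSE
  grp <- interaction(records$tissue, records$kind, drop = TRUE)
  thr_rows <- list()
  for (g in levels(grp)) {
    sel <- which(grp == g)
    sub <- records[sel, ]
    best <- tapply(sub$empP, sub$probe, function(p)
      if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE))
    thr <- bh_threshold(as.numeric(best), q)
    sig <- !is.na(sub$empP) & sub$empP <= thr
    records$significant[sel] <- sig
    thr_rows[[g]] <- data.frame(tissue = sub$tissue[1], kind = sub$kind[1],
                                threshold = thr, n_traits = length(best),
                                stringsAsFactors = FALSE)
    if (!is.null(genotypes) && any(sig)) {
      dos <- genotypes$dosages
      for (p in unique(sub$probe[sig])) {
        prow <- sel[records$probe[sel] == p]
        sig_snps <- records$snp[prow][records$significant[prow]]
        cand <- prow[!records$significant[prow] & is.na(records$skip_reason[prow])]
        if (length(cand) == 0) next
        cand_snps <- records$snp[cand]
        R <- suppressWarnings(stats::cor(dos[, cand_snps, drop = FALSE],
                                         dos[, sig_snps, drop = FALSE],
                                         use = "pairwise.complete.obs"))^2
        hit <- apply(R, 1, function(v) any(!is.na(v) & v >= ld_r2_rescue))
        records$significant[cand[hit]] <- TRUE
        records$rescue[cand[hit]] <- TRUE
      }
    }
  }
  attr(records, "fdr_thresholds") <- do.call(rbind, thr_rows)
  records
}

#' Remove QTLs whose assay probe contains a known polymorphism
#'
#' A record is dropped when its probe's genomic interval (0-based, half-open)
#' contains at least one known variant position. Probes without an interval
#' are retained with a warning.
#'
#' @param records QTL record data.frame.
#' @param probe_intervals data.frame with columns `probe`, `chr`, `start`,
#'   `end` (0-based half-open).
#' @param known_variant_positions data.frame with columns `chr`, `pos`.
#' @return list with `records` (retained) and `removed` (dropped rows plus a
#'   `n_variants_in_probe` column).
#' @export
filter_probe_polymorphisms <- function(records, probe_intervals,
                                       known_variant_positions) {
  if (nrow(records) == 0 || nrow(known_variant_positions) == 0)
    return(list(records = records, removed = records[integer(0), ]))
  iv <- probe_intervals[match(unique(records$probe), probe_intervals$probe), ]
  missing_iv <- unique(records$probe)[is.na(iv$probe)]
  if (length(missing_iv))
    warning("no interval for probe(s): ",
            paste(utils::head(missing_iv, 5), collapse = ", "),
            "; records retained", call. = FALSE)
  n_hits <- stats::setNames(integer(nrow(iv)), iv$probe)
  for (ch in unique(iv$chr[!is.na(iv$chr)])) {
    v <- sort(known_variant_positions$pos[known_variant_positions$chr == ch])
    if (length(v) == 0) next
    sel <- which(!is.na(iv$chr) & iv$chr == ch)
    n_hits[sel] <- findInterval(iv$end[sel] - 0.5, v) -
      findInterval(iv$start[sel] - 0.5, v)
  }
  bad_probes <- names(n_hits)[n_hits > 0]
  drop <- records$probe %in% bad_probes
  removed <- records[drop, , drop = FALSE]
  if (nrow(removed))
    removed$n_variants_in_probe <- n_hits[removed$probe]
  list(records = records[!drop, , drop = FALSE], removed = removed)
}
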