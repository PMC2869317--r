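# Evaluation of significance calls against the generator's planted truth.
# Because a causal SNP drags its LD partners along (exactly as the method
# intends), recovery and false discoveries are judged at the trait level,
# with linkage to the planted SNP deciding whether a significant SNP counts
# as hitting the planted locus.

#' Score significance calls against planted truth
#'
#' A planted effect counts as recovered when its probe has at least one
#' significant SNP that is linked to the planted SNP: in the same LD block,
#' or with dosage LD r-squared at least `ld_true`. The empirical trait-level
#' false discovery rate is the fraction of probes carrying a significant
#' QTL that have no planted effect.
#'
#' @param records significance-called QTL records.
#' @param truth planted-truth data.frame from [simulate_traits()].
#' @param genotypes the `geno_matrix` scanned (pre-QC object is fine; used
#'   for LD and block lookup).
#' @param ld_true LD r-squared above which a significant SNP counts as the
#'   planted locus (default 0.5).
#' @return list with `sensitivity`, `trait_fdr`, `n_recovered`, `n_planted`,
#'   `n_false_traits`, `n_called_traits` and the per-effect `recovered`
#'   logical vector.
#' @export
evaluate_recovery <- function(records, truth, genotypes, ld_true = 0.5) {
  sig <- records[records$significant, , drop = FALSE]
  blocks <- genotypes$snp_info$block
  names(blocks) <- genotypes$snp_info$snp
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    snps <- sig$snp[sig$probe == truth$probe[i]]
    if (length(snps) == 0) return(FALSE)
    pb <- blocks[[truth$snp[i]]]
    if (!is.na(pb) && any(!is.na(blocks[snps]) & blocks[snps] == pb))
      return(TRUE)
    any(vapply(snps, function(s) {
      v <- ld_r2(genotypes$dosages[, s], genotypes$dosages[, truth$snp[i]])
      !is.na(v) && v >= ld_true
    }, logical(1)))
  }, logical(1))
  called <- unique(sig$probe)
  false_traits <- setdiff(called, truth$probe)
  list(sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
       trait_fdr = if (length(called)) length(false_traits) / length(called)
                   else NA_real_,
       n_recovered = sum(recovered), n_planted = nrow(truth),
       n_false_traits = length(false_traits),
       n_called_traits = length(called), recovered = recovered)
}
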