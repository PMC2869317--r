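#' Describe one planted QTL effect
#'
#' A planted effect ties one SNP to one probe with a target fraction of trait
#' variance explained. Cis effects place the probe anchor within 1 Mb of the
#' SNP (at `distance` base pairs, default drawn in \[1 kb, 500 kb\]); trans
#' effects place the probe on a different chromosome.
#'
#' @param snp_index 1-based index of the driving SNP (autosomal SNPs only).
#' @param probe_index 1-based index of the target probe within its kind.
#' @param trait_kind `"cpg"` or `"mrna"`.
#' @param target_r2 fraction of trait variance explained by the SNP, in \[0,1).
#' @param mode `"cis"` or `"trans"`.
#' @param distance signed base-pair offset of the probe anchor from the SNP
#'   (cis mode only); `NULL` to draw one at simulation time.
#' @param sign effect direction, `+1` or `-1`; `NULL` to draw at random.
#' @param tissue_mask character vector of tissues carrying the effect;
#'   `NULL` means all tissues.
#' @return a `planted_qtl` list.
#' @export
planted_qtl <- function(snp_index, probe_index, trait_kind = c("cpg", "mrna"),
                        target_r2 = 0.4, mode = c("cis", "trans"),
                        distance = NULL, sign = NULL, tissue_mask = NULL) {
  trait_kind <- match.arg(trait_kind)
  mode <- match.arg(mode)
  if (target_r2 < 0 || target_r2 >= 1)
    stop2("target_r2 must be in [0, 1)")
  if (!is.null(sign) && !sign %in% c(-1, 1))
    stop2("sign must be +1 or -1")
  if (!is.null(distance) && mode == "cis" && abs(distance) > 1e6)
    stop2("a cis planted effect must place the probe within 1 Mb of the SNP")
  structure(list(snp_index = as.integer(snp_index),
                 probe_index = as.integer(probe_index),
                 trait_kind = trait_kind, target_r2 = target_r2,
                 mode = mode, distance = distance, sign = sign,
                 tissue_mask = tissue_mask),
            class = "planted_qtl")
}

#' Simulation configuration
#'
#' Defaults emulate the design of a four-brain-region cohort of 150 subjects:
#' LD-block-structured dosages, beta-like CpG methylation values, log2-scale
#' expression, age/gender/PMI/bank/batch confounding and sparse missingness.
#'
#' @param n_samples number of subjects (>= 3).
#' @param n_snps number of autosomal SNPs.
#' @param ld_block_size SNPs per LD block.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param n_cpg_probes,n_mrna_probes probe counts per trait kind.
#' @param planted_qtls list of [planted_qtl()] effects.
#' @param covariate_effect_sizes named numeric vector of per-covariate trait
#'   variance fractions (names among age, gender, pmi, bank, batch).
#' @param missing_rate genotype missingness fraction in \[0, 1).
#' @param tissues character vector of tissue labels.
#' @param tissue_cor correlation of residual trait noise between tissues of
#'   the same subject, in \[0, 1\].
#' @param tissue_shift_sd standard deviation of the per-probe tissue mean
#'   shift (liability scale). A constant offset within each tissue, it
#'   separates tissues in clustering while leaving within-tissue variances
#'   and planted effect sizes untouched.
#' @param dosage_mode `"hard"` for calls in \{0,1,2\}, `"imputed"` to add
#'   dosage noise on SNPs flagged as imputed.
#' @param imputed_fraction fraction of SNPs flagged imputed (with emitted
#'   imputation-quality metrics).
#' @param n_x_snps,n_x_cpgs X-chromosome SNP and CpG-probe counts appended for
#'   sex-inference checks (planted indices never refer to these).
#' @param ld_rho latent AR(1) correlation of the per-block Gaussian copula.
#' @param planted_maf_min minimum allele frequency for SNPs carrying a
#'   planted effect (default 0.25), so planted effects sit at analyzable
#'   frequencies rather than at rare SNPs the minor-homozygote QC filter
#'   removes by design.
#' @param undetected_frac fraction of unplanted probes simulated as poorly
#'   detected (failing the detection filter).
#' @param seed master seed; with the config it fully determines all output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 150, n_snps = 2000, ld_block_size = 10,
                       maf_range = c(0.05, 0.5), n_cpg_probes = 100,
                       n_mrna_probes = 100, planted_qtls = list(),
                       covariate_effect_sizes = c(age = 0.05, gender = 0.02,
                                                  pmi = 0.03, bank = 0.02,
                                                  batch = 0.03),
                       missing_rate = 0.01,
                       tissues = c("CRBLM", "FCTX", "PONS", "TCTX"),
                       tissue_cor = 0.3, tissue_shift_sd = 1,
                       dosage_mode = c("imputed", "hard"),
                       imputed_fraction = 0.3, n_x_snps = 25, n_x_cpgs = 15,
                       ld_rho = 0.95, planted_maf_min = 0.25,
                       undetected_frac = 0.02, seed) {
  dosage_mode <- match.arg(dosage_mode)
  if (missing(seed)) stop2("sim_config() requires an explicit seed")
  if (n_samples < 3) stop2("n_samples must be >= 3")
  if (n_snps < 1 || n_cpg_probes < 0 || n_mrna_probes < 0 || ld_block_size < 1)
    stop2("dimensions must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop2("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop2("missing_rate must be in [0, 1)")
  if (tissue_cor < 0 || tissue_cor > 1) stop2("tissue_cor must be in [0, 1]")
  covsum <- sum(covariate_effect_sizes)
  for (pq in planted_qtls) {
    if (!inherits(pq, "planted_qtl")) stop2("planted_qtls must be planted_qtl objects")
    if (pq$target_r2 + covsum >= 1)
      stop2("target_r2 + covariate variance fractions must be < 1")
    if (pq$snp_index > n_snps) stop2("planted snp_index out of range")
    n_probes <- if (pq$trait_kind == "cpg") n_cpg_probes else n_mrna_probes
    if (pq$probe_index > n_probes) stop2("planted probe_index out of range")
    if (!is.null(pq$tissue_mask) && !all(pq$tissue_mask %in% tissues))
      stop2("tissue_mask names unknown tissues")
  }
  idx <- vapply(planted_qtls, function(p) paste(p$trait_kind, p$probe_index),
                character(1))
  if (anyDuplicated(idx))
    stop2("at most one planted effect per probe is supported")
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 ld_block_size = as.integer(ld_block_size),
                 maf_range = maf_range, n_cpg_probes = as.integer(n_cpg_probes),
                 n_mrna_probes = as.integer(n_mrna_probes),
                 planted_qtls = planted_qtls,
                 covariate_effect_sizes = covariate_effect_sizes,
                 missing_rate = missing_rate, tissues = tissues,
                 tissue_cor = tissue_cor, tissue_shift_sd = tissue_shift_sd,
                 dosage_mode = dosage_mode,
                 imputed_fraction = imputed_fraction,
                 n_x_snps = as.integer(n_x_snps),
                 n_x_cpgs = as.integer(n_x_cpgs), ld_rho = ld_rho,
                 planted_maf_min = planted_maf_min,
                 undetected_frac = undetected_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}
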