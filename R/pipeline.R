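# End-to-end pipeline: QC -> trait preparation -> scan -> significance ->
# annotation -> integration, driven by a single declarative config (YAML
# file or list). Stage order is fixed; QC can only be skipped through an
# explicit override flag. A JSON manifest records the config snapshot,
# seeds, input digests, per-stage counts and package version.

default_thresholds <- function() {
  list(call_rate_min = 0.95, hwe_p_min = 0.001, min_minor_hom = 3,
       imputation_r2_min = 0.3, posterior_avg_min = 0.8,
       det_p = 0.01, det_min_frac = 0.95, outlier_k_sd = 3,
       n_perm = 1000, fdr_q = 0.05, ld_r2_rescue = 0.7, cis_window = 1e6)
}

#' Run the full QTL-mapping pipeline from a config
#'
#' The config (YAML path or list) names either a `simulation` block (a
#' [sim_config()] argument list; fully self-contained run) or an `inputs`
#' block with file paths (`dosages`, `snps`, `covariates`, and per-tissue
#' trait files). All thresholds default to the conventional values (0.95 call
#' rates, HWE p 0.001, 3 minor homozygotes, imputation r2 0.3 / posterior
#' 0.8, detection p 0.01 in 95% of samples, 1,000 permutations, FDR 0.05,
#' LD rescue 0.7, 1 Mb cis window) and can be overridden under `thresholds`.
#'
#' Stages, in enforced order: genotype sample call rate, genotypic sex
#' check, SNP filters; per-tissue trait detection filter, outlier-sample
#' exclusion, optional mRNA rank-invariant normalization, covariate
#' residualization; per-trait maxT permutation scan; FDR + LD-rescue
#' significance; cis/trans annotation; enrichment and (multi-tissue)
#' cross-tissue integration. Writes results TSVs, an enrichment scan TSV
#' and a `manifest.json` under `out_dir`.
#'
#' @param config YAML file path or list.
#' @return invisibly, a list with `records` (per tissue/kind), `enrichment`,
#'   `manifest` and output `paths`.
#' @export
run_pipeline <- function(config) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% stop2("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  counts <- list()
  digests <- list()

  # ---- stage 0: load or simulate -------------------------------------------
  if (!is.null(config$simulation)) {
    simargs <- config$simulation
    if (!is.null(simargs$planted_qtls))
      simargs$planted_qtls <- lapply(simargs$planted_qtls,
                                     function(a) do.call(planted_qtl, a))
    if (!is.null(simargs$maf_range)) simargs$maf_range <- as.numeric(simargs$maf_range)
    if (!is.null(simargs$covariate_effect_sizes))
      simargs$covariate_effect_sizes <- unlist(simargs$covariate_effect_sizes)
    scfg <- do.call(sim_config, simargs)
    genotypes <- simulate_genotypes(scfg)
    sim <- simulate_traits(genotypes, scfg)
    traits <- sim$traits
    covariates <- sim$covariates
    say("simulated ", scfg$n_samples, " samples, ", ncol(genotypes$dosages),
        " SNPs, ", length(scfg$tissues), " tissue(s)")
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in c(inp$dosages, inp$snps, inp$covariates))
      if (!file.exists(f)) stop2("missing input file: ", f)
    genotypes <- read_genotypes(inp$dosages, inp$snps)
    covariates <- read_covariates(inp$covariates)
    genotypes$covariates <- covariates
    traits <- list()
    for (t in names(inp$traits)) {
      traits[[t]] <- list()
      for (kind in names(inp$traits[[t]])) {
        ti <- inp$traits[[t]][[kind]]
        for (f in c(ti$values, ti$detection, ti$bed))
          if (!file.exists(f)) stop2("missing input file: ", f)
        traits[[t]][[kind]] <- read_traits(ti$values, ti$detection, ti$bed,
                                           kind = kind, tissue = t)
      }
    }
    digests <- as.list(tools::md5sum(unlist(inp[c("dosages", "snps", "covariates")])))
    say("loaded ", nrow(genotypes$dosages), " samples x ",
        ncol(genotypes$dosages), " SNPs from files")
  } else stop2("config needs a simulation or inputs block")
  counts$input <- list(samples = nrow(genotypes$dosages),
                       snps = ncol(genotypes$dosages))

  # ---- stage 1: genotype QC ------------------------------------------------
  if (isTRUE(config$skip_qc)) {
    warning("QC skipped by explicit config override", call. = FALSE)
    qc_report <- NULL
  } else {
    keep <- sample_call_rate_filter(genotypes, thr$call_rate_min)
    say("genotype sample call rate: ", nrow(genotypes$dosages) - length(keep),
        " sample(s) excluded")
    genotypes <- subset_samples(genotypes, keep)
    if (sum(genotypes$snp_info$chr %in% c("chrX", "X")) >= 10 &&
        !is.null(covariates$gender)) {
      sex <- infer_genotypic_sex(genotypes,
                                 stats::setNames(covariates$gender, covariates$sample))
      bad <- sex$sample[sex$mismatch]
      if (length(bad)) {
        say("genotypic sex mismatch: excluding ", paste(bad, collapse = ", "))
        genotypes <- subset_samples(genotypes, setdiff(rownames(genotypes$dosages), bad))
      } else say("genotypic sex check: no mismatches")
    }
    fl <- apply_snp_filters(genotypes, thr$call_rate_min, thr$hwe_p_min,
                            thr$min_minor_hom, thr$imputation_r2_min,
                            thr$posterior_avg_min)
    say("SNP filters: ", sum(!fl$report$pass), " of ", nrow(fl$report),
        " SNP(s) excluded")
    genotypes <- fl$genotypes
    qc_report <- fl$report
  }
  counts$post_qc <- list(samples = nrow(genotypes$dosages),
                         snps = ncol(genotypes$dosages))

  # ---- stage 2: trait preparation ------------------------------------------
  resid <- list()
  for (t in names(traits)) {
    resid[[t]] <- list()
    for (kind in names(traits[[t]])) {
      tm <- traits[[t]][[kind]]
      keep <- intersect(rownames(genotypes$dosages), rownames(tm$values))
      tm <- subset_samples(tm, keep)
      keep <- sample_call_rate_filter(tm, thr$call_rate_min, thr$det_p)
      tm <- subset_samples(tm, keep)
      if (kind == "mrna") {
        keep <- exclude_outlier_samples(tm, thr$outlier_k_sd, thr$det_p)
        tm <- subset_samples(tm, keep)
        if (isTRUE(config$normalize_mrna))
          tm <- rank_invariant_normalize(tm)
      }
      det <- detection_filter(tm, thr$det_p, thr$det_min_frac)
      probes_keep <- det$retained[[1]]
      auto <- tm$probes$probe[!(tm$probes$chr %in% c("chrX", "X", "chrY", "Y"))]
      probes_keep <- intersect(probes_keep, auto)
      tm$values <- tm$values[, probes_keep, drop = FALSE]
      tm$detection <- tm$detection[, probes_keep, drop = FALSE]
      say(t, "/", kind, ": ", nrow(tm$values), " samples, ",
          length(probes_keep), " detected autosomal probes")
      resid[[t]][[kind]] <- residualize(tm, covariates)
      counts[[paste0("prep_", t, "_", kind)]] <-
        list(samples = nrow(tm$values), probes = length(probes_keep))
    }
  }

  # ---- stage 3-5: scan, significance, annotation ---------------------------
  auto_snps <- genotypes$snp_info$snp[!(genotypes$snp_info$chr %in% c("chrX", "X"))]
  g_auto <- genotypes
  g_auto$dosages <- genotypes$dosages[, auto_snps, drop = FALSE]
  if (!is.null(g_auto$truth_dosages))
    g_auto$truth_dosages <- genotypes$truth_dosages[, auto_snps, drop = FALSE]
  g_auto$snp_info <- genotypes$snp_info[match(auto_snps, genotypes$snp_info$snp), ]

  seed <- config$seed %||% config$simulation$seed %||% 1L
  records <- list()
  for (t in names(resid)) {
    for (kind in names(resid[[t]])) {
      plan <- perm_plan(thr$n_perm,
                        derive_seed(seed, 1000L + match(t, names(resid)) * 10L +
                                      match(kind, names(resid[[t]]))))
      rec <- scan_tissue(resid[[t]][[kind]], g_auto, plan)
      rec <- call_significant(rec, g_auto, thr$fdr_q, thr$ld_r2_rescue)
      rec <- classify_cis_trans(rec, thr$cis_window)
      records[[paste0(t, ".", kind)]] <- rec
      say(t, "/", kind, ": ", sum(rec$significant), " significant pair(s), ",
          length(unique(rec$probe[rec$significant])), " probe(s) with a QTL")
    }
  }

  # optional probe-polymorphism filter
  if (!is.null(config$known_variants)) {
    kv <- as.data.frame(data.table::fread(config$known_variants))
    for (nm in names(records)) {
      iv <- records[[nm]][!duplicated(records[[nm]]$probe),
                          c("probe", "probe_chr", "probe_start", "probe_end")]
      names(iv) <- c("probe", "chr", "start", "end")
      fp <- filter_probe_polymorphisms(records[[nm]], iv, kv)
      say(nm, ": ", nrow(fp$removed), " record(s) removed for probe polymorphisms")
      records[[nm]] <- fp$records
    }
  }

  # ---- stage 6: integration ------------------------------------------------
  enrichment <- list()
  for (kind in unique(sub("^.*\\.", "", names(records)))) {
    rk <- do.call(rbind, records[grep(paste0("\\.", kind, "$"), names(records))])
    if (nrow(rk) && sum(!is.na(rk$class_distance)) > 0) {
      ef <- tryCatch(enrichment_fold(rk, thr$cis_window), error = function(e) NULL)
      sc <- enrichment_distance_scan(rk, max_window = thr$cis_window)
      enrichment[[kind]] <- list(fold = ef, scan = sc)
      fwrite_tsv(sc$scan, file.path(out_dir, paste0("enrichment_", kind, ".tsv")))
    }
  }

  paths <- c()
  for (nm in names(records)) {
    p <- file.path(out_dir, paste0("qtl_", sub("\\.", "_", nm), ".tsv"))
    write_results_tsv(records[[nm]], p, qc_report)
    paths[nm] <- p
  }

  manifest <- list(
    package = "permqtl",
    version = as.character(utils::packageVersion("permqtl")),
    config = config, config_path = config_path, seed = seed,
    thresholds = thr, input_digests = digests, counts = counts,
    fdr_thresholds = lapply(records, function(r) attr(r, "fdr_thresholds")))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(records = records, enrichment = enrichment,
                 manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}
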