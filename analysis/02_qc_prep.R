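#!/usr/bin/env Rscript
# 02 -- Quality control and trait preparation.
#
# Reads the fixture files back through the package readers (so the round
# trip is part of the workflow), then applies the QC chain: sample call
# rates (genotype and methylation, both at 95%), genotypic and
# methylation-based sex checks, SNP filters (call rate / exact HWE /
# minor-homozygote count / imputation quality), detection filtering
# (p <= 0.01 in >= 95% of samples), average-linkage clustering QC, and
# covariate residualization. Residual matrices go to scratch/ for stage 03.

suppressMessages(library(permqtl))

fx <- "results/fixtures"
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

genotypes <- read_genotypes(file.path(fx, "dosages.tsv"),
                            file.path(fx, "snps.tsv"))
covariates <- read_covariates(file.path(fx, "covariates.tsv"))
genotypes$covariates <- covariates
tissues <- c("CRBLM", "FCTX", "PONS", "TCTX")

# genotype-side sample QC
keep <- sample_call_rate_filter(genotypes, 0.95)
message("genotype call rate >= 95%: ", length(keep), " of ",
        nrow(genotypes$dosages), " samples retained")
genotypes <- subset_samples(genotypes, keep)

sex_g <- infer_genotypic_sex(genotypes,
                             setNames(covariates$gender, covariates$sample))
message("genotypic sex check: ", sum(sex_g$mismatch), " mismatch(es)")
genotypes <- subset_samples(genotypes,
                            setdiff(rownames(genotypes$dosages),
                                    sex_g$sample[sex_g$mismatch]))

fl <- apply_snp_filters(genotypes)
data.table::fwrite(fl$report, "results/qc/snp_qc_report.tsv", sep = "\t")
message("SNP filters: ", sum(fl$report$pass), " of ", nrow(fl$report),
        " SNPs pass (exclusions: ",
        paste(names(table(fl$report$exclusion_reasons[!fl$report$pass])),
              table(fl$report$exclusion_reasons[!fl$report$pass]),
              collapse = ", "), ")")
genotypes <- fl$genotypes

resid <- list()
raw <- list()
for (t in tissues) {
  for (kind in c("cpg", "mrna")) {
    tm <- read_traits(file.path(fx, paste0(t, "_", kind, "_values.tsv")),
                      file.path(fx, paste0(t, "_", kind, "_detection.tsv")),
                      file.path(fx, paste0(kind, "_probes.bed")),
                      kind = kind, tissue = t)
    tm <- subset_samples(tm, intersect(rownames(genotypes$dosages),
                                       rownames(tm$values)))
    if (kind == "cpg") {
      keep <- sample_call_rate_filter(tm, 0.95)
      n_drop <- nrow(tm$values) - length(keep)
      tm <- subset_samples(tm, keep)
      sex_m <- infer_methylation_sex(tm, setNames(covariates$gender,
                                                  covariates$sample)[keep])
      message(t, "/cpg: ", n_drop,
              " low-call-rate sample(s); methylation sex mismatches: ",
              sum(sex_m$mismatch))
    } else {
      keep <- exclude_outlier_samples(tm)
      message(t, "/mrna: ", nrow(tm$values) - length(keep),
              " outlier sample(s) excluded")
      tm <- subset_samples(tm, keep)
    }
    det <- detection_filter(tm)
    auto <- tm$probes$probe[!(tm$probes$chr %in% c("chrX", "chrY"))]
    keep_p <- intersect(det$retained[[1]], auto)
    tm$values <- tm$values[, keep_p, drop = FALSE]
    tm$detection <- tm$detection[, keep_p, drop = FALSE]
    message(t, "/", kind, ": ", length(keep_p), " detected autosomal probes")
    raw[[paste0(t, ".", kind)]] <- tm
    resid[[paste0(t, ".", kind)]] <- residualize(tm, covariates)
  }
}

# clustering QC on the raw (pre-residualization) profiles: tissues separate
# on their mean methylation shifts; autosomal CpGs only, otherwise gender
# sub-clusters appear
shared <- Reduce(intersect, lapply(raw[paste0(tissues, ".cpg")],
                                   function(r) rownames(r$values)))
probes <- Reduce(intersect, lapply(raw[paste0(tissues, ".cpg")],
                                   function(r) colnames(r$values)))
prof <- do.call(rbind, lapply(tissues, function(t) {
  m <- raw[[paste0(t, ".cpg")]]$values[shared[1:20], probes]
  rownames(m) <- paste0(t, "_", shared[1:20])
  m
}))
nwk <- cluster_samples(prof)
writeLines(nwk, "results/qc/cluster_cpg.nwk")
hc <- attr(nwk, "hclust")
grp <- cutree(hc, k = 4)
purity <- mean(sapply(split(sub("_.*", "", names(grp)), grp),
                      function(g) max(table(g)) / length(g)))
message("clustering QC: 4-way cut purity by tissue = ", round(purity, 2),
        " (tree in results/qc/cluster_cpg.nwk)")

cov_r2 <- sapply(resid, function(r) mean(r$covariate_r2, na.rm = TRUE))
write.table(data.frame(group = names(cov_r2), mean_covariate_r2 = cov_r2),
            "results/qc/covariate_r2.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message("mean covariate-model R2 by tissue/kind: ",
        paste(names(cov_r2), round(cov_r2, 3), collapse = ", "))

saveRDS(list(genotypes = genotypes, resid = resid, qc_report = fl$report),
        "scratch/02_prepared.rds")
message("prepared objects saved for stage 03")
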