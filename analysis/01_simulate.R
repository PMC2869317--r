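#!/usr/bin/env Rscript
# 01 -- Simulate a four-brain-region cohort with planted QTLs.
#
# Builds the synthetic study: 150 subjects genotyped at 1,000 LD-blocked
# autosomal SNPs (plus chrX SNPs/CpGs for the sex checks), 60 CpG and 60
# mRNA probes per tissue across CRBLM/FCTX/PONS/TCTX, with 16 cis and 4
# trans planted effects (target R2 0.3-0.6), one of them a shared SNP
# driving a CpG and an mRNA 10 kb apart, and one cis methQTL restricted to
# the cerebellum. Writes the fixture files every later stage reads.

suppressMessages(library(permqtl))

out_dir <- "results/fixtures"
master_seed <- 20260
set.seed(master_seed)

planted <- c(
  # cis methQTLs
  lapply(1:6, function(i)
    planted_qtl(sample(950, 1), i, "cpg", runif(1, 0.3, 0.6), "cis")),
  # cis eQTLs
  lapply(1:6, function(i)
    planted_qtl(sample(950, 1), i, "mrna", runif(1, 0.3, 0.6), "cis")),
  # a shared SNP driving CpG 10 and mRNA 10, anchors 10 kb apart
  list(planted_qtl(500, 10, "cpg", 0.5, "cis", distance = 5000, sign = 1),
       planted_qtl(500, 10, "mrna", 0.5, "cis", distance = -5000, sign = -1)),
  # tissue-specific cis methQTL (cerebellum only)
  list(planted_qtl(700, 11, "cpg", 0.55, "cis", tissue_mask = "CRBLM")),
  # an extra cis pair
  list(planted_qtl(820, 12, "cpg", 0.45, "cis"),
       planted_qtl(860, 12, "mrna", 0.4, "cis")),
  # trans effects
  list(planted_qtl(150, 20, "cpg", 0.5, "trans"),
       planted_qtl(250, 20, "mrna", 0.45, "trans"),
       planted_qtl(350, 21, "cpg", 0.4, "trans"),
       planted_qtl(450, 21, "mrna", 0.5, "trans")))

cfg <- sim_config(n_samples = 150, n_snps = 1000, n_cpg_probes = 60,
                  n_mrna_probes = 60, planted_qtls = planted,
                  seed = master_seed)
genotypes <- simulate_genotypes(cfg)
sim <- simulate_traits(genotypes, cfg)
paths <- write_fixture_set(genotypes, sim, cfg, out_dir)

message("wrote ", length(paths), " fixture files to ", out_dir)
message("cohort: ", nrow(genotypes$dosages), " samples x ",
        ncol(genotypes$dosages), " SNPs (",
        sum(genotypes$snp_info$chr == "chrX"), " on chrX), ",
        length(cfg$tissues), " tissues, ",
        nrow(sim$truth), " planted effects (",
        sum(sim$truth$mode == "cis"), " cis / ",
        sum(sim$truth$mode == "trans"), " trans)")
saveRDS(list(cfg = cfg, seed = master_seed), "scratch/01_config.rds")
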