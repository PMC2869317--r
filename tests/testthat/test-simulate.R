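test_that("same seed and config reproduce identical cohorts", {
  cfg <- sim_config(n_samples = 30, n_snps = 40, n_cpg_probes = 5,
                    n_mrna_probes = 5, tissues = "FCTX", seed = 11)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  s1 <- simulate_traits(g1, cfg); s2 <- simulate_traits(g2, cfg)
  expect_identical(s1, s2)
})

test_that("hard-call mode without missingness gives complete {0,1,2} dosages", {
  cfg <- sim_config(n_samples = 50, n_snps = 30, missing_rate = 0,
                    dosage_mode = "hard", n_x_snps = 0, tissues = "FCTX",
                    seed = 3)
  g <- simulate_genotypes(cfg)
  expect_false(anyNA(g$dosages))
  expect_true(all(g$dosages %in% c(0, 1, 2)))
  cfg2 <- sim_config(n_samples = 50, n_snps = 200, missing_rate = 0.05,
                     tissues = "FCTX", seed = 3)
  g2 <- simulate_genotypes(cfg2)
  expect_gt(mean(is.na(g2$dosages)), 0.03)
  expect_true(all(g2$dosages >= 0 & g2$dosages <= 2, na.rm = TRUE))
})

test_that("adjacent SNPs within an LD block are correlated in expectation", {
  # Monte-Carlo estimate over replicate seeds of the generator's own copula
  mean_adj_r2 <- mean(sapply(1:100, function(sd) {
    cfg <- sim_config(n_samples = 100, n_snps = 10, ld_block_size = 10,
                      maf_range = c(0.5, 0.5), missing_rate = 0,
                      dosage_mode = "hard", n_x_snps = 0, n_x_cpgs = 0,
                      n_cpg_probes = 0, n_mrna_probes = 0,
                      tissues = "FCTX", seed = sd)
    g <- simulate_genotypes(cfg)
    mean(sapply(1:9, function(j) cor(g$dosages[, j], g$dosages[, j + 1])^2))
  }))
  expect_gt(mean_adj_r2, 0.5)
  # SNPs in different blocks are essentially uncorrelated
  cfg <- sim_config(n_samples = 2000, n_snps = 40, ld_block_size = 10,
                    missing_rate = 0, dosage_mode = "hard", n_x_snps = 0,
                    n_x_cpgs = 0, n_cpg_probes = 0, n_mrna_probes = 0,
                    tissues = "FCTX", seed = 1)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(cor(g$dosages[, 10], g$dosages[, 11])), 0.08)
})

test_that("planted effects explain the target trait variance at large n", {
  r2s <- sapply(1:50, function(sd) {
    cfg <- sim_config(n_samples = 10000, n_snps = 5, ld_block_size = 5,
                      n_cpg_probes = 2, n_mrna_probes = 2,
                      planted_qtls = list(
                        planted_qtl(2, 1, "cpg", 0.5, "cis", sign = 1),
                        planted_qtl(4, 2, "mrna", 0.5, "cis", sign = -1)),
                      tissues = "FCTX", n_x_snps = 0, n_x_cpgs = 0,
                      missing_rate = 0, dosage_mode = "hard", seed = sd)
    g <- simulate_genotypes(cfg)
    s <- simulate_traits(g, cfg)
    c(cor(s$traits$FCTX$cpg$values[, 1], g$truth_dosages[, 2])^2,
      cor(s$traits$FCTX$mrna$values[, 2], g$truth_dosages[, 4])^2)
  })
  means <- rowMeans(r2s)
  expect_true(all(means >= 0.45 & means <= 0.55))
})

test_that("without planted effects trait-dosage R2 follows the null", {
  # E[r^2] = 1/(n-1) for independent Gaussian pairs
  cfg <- sim_config(n_samples = 200, n_snps = 50, n_cpg_probes = 0,
                    n_mrna_probes = 30,
                    covariate_effect_sizes = c(age = 0),
                    missing_rate = 0, dosage_mode = "hard", n_x_snps = 0,
                    n_x_cpgs = 0, tissues = "FCTX", seed = 5)
  g <- simulate_genotypes(cfg)
  s <- simulate_traits(g, cfg)
  r2 <- cor(s$traits$FCTX$mrna$values, g$dosages)^2
  expect_equal(mean(r2), 1 / 199, tolerance = 0.4)
})

test_that("CpG values stay in [0,1] and X probes separate the sexes", {
  sim <- small_sim(seed = 21)
  for (t in names(sim$s$traits)) {
    v <- sim$s$traits[[t]]$cpg$values
    expect_true(all(v >= 0 & v <= 1))
  }
  cpg <- sim$s$traits$FCTX$cpg
  xmeans <- rowMeans(cpg$values[, grep("^cgX", colnames(cpg$values))])
  f <- sim$s$covariates$gender == "F"
  expect_gt(min(xmeans[f]) - max(xmeans[!f]), 0)
})

test_that("tissue_mask restricts a planted effect to the named tissues", {
  pq <- planted_qtl(10, 3, "mrna", 0.5, "cis", sign = 1,
                    tissue_mask = "FCTX")
  cfg <- sim_config(n_samples = 3000, n_snps = 50, n_cpg_probes = 0,
                    n_mrna_probes = 5, planted_qtls = list(pq),
                    tissues = c("FCTX", "PONS"), missing_rate = 0,
                    dosage_mode = "hard", n_x_snps = 0, n_x_cpgs = 0,
                    seed = 9)
  g <- simulate_genotypes(cfg)
  s <- simulate_traits(g, cfg)
  r2_in <- cor(s$traits$FCTX$mrna$values[, 3], g$dosages[, 10])^2
  r2_out <- cor(s$traits$PONS$mrna$values[, 3], g$dosages[, 10])^2
  expect_gt(r2_in, 0.4)
  expect_lt(r2_out, 0.05)
})

test_that("configuration errors are rejected", {
  expect_error(sim_config(n_samples = 2, seed = 1), "n_samples")
  expect_error(sim_config(n_samples = 10, n_snps = 0, seed = 1), "positive")
  expect_error(sim_config(n_samples = 10, maf_range = c(0, 0.6), seed = 1),
               "maf_range")
  expect_error(sim_config(n_samples = 10, missing_rate = 1, seed = 1),
               "missing_rate")
  expect_error(sim_config(n_samples = 10, seed = 1,
                          planted_qtls = list(planted_qtl(5000, 1, "cpg", 0.4))),
               "out of range")
  expect_error(sim_config(n_samples = 10, seed = 1, n_cpg_probes = 2,
                          planted_qtls = list(planted_qtl(1, 99, "cpg", 0.4))),
               "out of range")
  expect_error(planted_qtl(1, 1, "cpg", target_r2 = 1.2), "target_r2")
  expect_error(sim_config(n_samples = 10, seed = 1,
                          covariate_effect_sizes = c(age = 0.7),
                          planted_qtls = list(planted_qtl(1, 1, "cpg", 0.4))),
               "< 1")
})
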