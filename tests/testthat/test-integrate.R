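mk_universe <- function(n_cis, n_trans, sig_cis, sig_trans,
                        cis_dist = 1e5, kind = "cpg") {
  data.frame(
    tissue = "T", kind = kind,
    probe = paste0("p", seq_len(n_cis + n_trans)),
    snp = paste0("s", seq_len(n_cis + n_trans)),
    snp_chr = c(rep("chr1", n_cis), rep("chr2", n_trans)),
    probe_chr = "chr1",
    class_distance = c(rep(cis_dist, n_cis), rep(NA, n_trans)),
    significant = c(seq_len(n_cis) <= sig_cis, seq_len(n_trans) <= sig_trans))
}

test_that("enrichment fold follows the proportion-of-possible formula", {
  u <- mk_universe(10, 990, sig_cis = 5, sig_trans = 1)
  ef <- enrichment_fold(u)
  expect_equal(ef$fold, (5 / 10) / (1 / 990))     # = 495
  expect_false(ef$infinite)
  # no significant trans: infinite fold with flag
  u2 <- mk_universe(10, 990, 5, 0)
  ef2 <- enrichment_fold(u2)
  expect_true(is.infinite(ef2$fold)); expect_true(ef2$infinite)
  # an empty possible class is an error naming the class
  expect_error(enrichment_fold(mk_universe(0, 10, 0, 1)), "cis")
  expect_error(enrichment_fold(mk_universe(10, 0, 1, 0)), "trans")
})

test_that("distance-scan thresholds form the four-fifths geometric grid", {
  u <- mk_universe(10, 90, 5, 1)
  sc <- enrichment_distance_scan(u)
  expect_equal(sc$scan$threshold[1:3], c(1e6, 8e5, 6.4e5))
  expect_equal(length(sc$scan$threshold), 50)
  # smallest threshold ~ 1e6 * 0.8^49 ~ 17.8 bp
  expect_equal(min(sc$scan$threshold), 1e6 * 0.8^49, tolerance = 1e-12)
  expect_lt(min(sc$scan$threshold), 45)   # grid brackets sub-45 bp scales
  # the 1 Mb entry reproduces enrichment_fold exactly
  ef <- enrichment_fold(u)
  expect_equal(sc$scan$fold[1], ef$fold)
  expect_equal(sc$scan$n_sig_cis[1], ef$n_sig_cis)
  expect_error(enrichment_distance_scan(u, ratio = 1.2), "ratio")
})

test_that("the scan peaks at the planted distance scale", {
  # all significant pairs planted at <= 100 bp; universe spans all distances
  with_seed_test(33, {
    n <- 400
    u <- data.frame(tissue = "T", kind = "cpg",
                    probe = paste0("p", 1:n), snp = paste0("s", 1:n),
                    snp_chr = "chr1", probe_chr = "chr1",
                    class_distance = round(10^runif(n, 0.5, 6.9)),
                    significant = FALSE)
    sig <- data.frame(tissue = "T", kind = "cpg",
                      probe = paste0("q", 1:12), snp = paste0("t", 1:12),
                      snp_chr = "chr1", probe_chr = "chr1",
                      class_distance = sample(30:100, 12, TRUE),
                      significant = TRUE)
    sc <- enrichment_distance_scan(rbind(u, sig))
    expect_lte(sc$peak_threshold, 140)
    expect_gt(sc$scan$fold[1], 1)
  })
})

test_that("cross-tissue table takes the union of significant pairs", {
  r1 <- mk_universe(5, 5, 3, 0); r1$tissue <- "A"
  r2 <- mk_universe(5, 5, 2, 1); r2$tissue <- "B"
  r1$r2 <- seq(0.1, 1, length.out = 10)
  r2$r2 <- seq(0.9, 0.1, length.out = 10)
  ct <- cross_tissue_table(list(A = r1, B = r2))
  # union: pairs significant in >= 1 tissue
  expect_equal(nrow(ct$pairs), length(union(
    paste(r1$probe, r1$snp)[r1$significant],
    paste(r2$probe, r2$snp)[r2$significant])))
  expect_gte(nrow(ct$pairs), sum(r1$significant))
  expect_gte(nrow(ct$pairs), sum(r2$significant))
  # r2 reported in every tissue, including where non-significant
  expect_true(all(!is.na(ct$pairs$r2_A)))
  expect_true(all(!is.na(ct$pairs$r2_B)))
  shared <- ct$pairs$n_tissues_significant == 2
  expect_equal(sum(shared), unname(ct$all_tissues["pairs"]))
  expect_warning(cross_tissue_table(list(A = r1, B = r2[integer(0), ])),
                 "no records")
})

test_that("ternary coordinates normalize and stay scale invariant", {
  tc <- ternary_coordinates(c(0.3, 0.3, 0.3))
  expect_equal(as.numeric(tc$coords), rep(1 / 3, 3))
  expect_equal(tc$cumulative, 0.9)
  expect_equal(as.numeric(ternary_coordinates(c(0.9, 0, 0))$coords),
               c(1, 0, 0))
  with_seed_test(5, {
    m <- matrix(runif(30), 10, 3)
    a <- ternary_coordinates(m); b <- ternary_coordinates(7 * m)
    expect_equal(a$coords, b$coords, tolerance = 1e-12)
    expect_true(all(abs(rowSums(a$coords) - 1) < 1e-12))
  })
  z <- ternary_coordinates(rbind(c(0, 0, 0), c(1, 2, 3)))
  expect_equal(z$skipped, 1)
  expect_equal(nrow(z$coords), 1)
})

trip_fixture <- function(m_beta, e_beta, sig_m = TRUE, sig_e = TRUE) {
  mr <- data.frame(tissue = "T", kind = "cpg", probe = "cg1", snp = "s1",
                   probe_chr = "chr1", probe_anchor = 500000L,
                   probe_tss = NA_integer_, beta = m_beta, r2 = 0.4,
                   empP = 0.001, significant = sig_m, cis_trans = "cis",
                   skip_reason = NA_character_)
  er <- data.frame(tissue = "T", kind = "mrna", probe = "tx1", snp = "s1",
                   probe_chr = "chr1", probe_anchor = 510000L,
                   probe_tss = 510000L, beta = e_beta, r2 = 0.3,
                   empP = 0.001, significant = sig_e, cis_trans = "cis",
                   skip_reason = NA_character_)
  list(mr = mr, er = er)
}

test_that("triplets pair CpG and mRNA QTLs with the documented quadrants", {
  with_seed_test(6, {
    cpg_vals <- matrix(runif(30), 30, 1, dimnames = list(NULL, "cg1"))
    mrna_vals <- matrix(8 - 2 * cpg_vals + rnorm(30, 0, 0.1),
                        dimnames = list(NULL, "tx1"))
    fx <- trip_fixture(m_beta = 0.2, e_beta = -0.5)
    tr <- build_triplets(fx$mr, fx$er, cpg_vals, mrna_vals)
    expect_equal(nrow(tr$triplets), 1)
    expect_true(tr$triplets$shared)
    # methylation-positive / expression-negative: the "top-left" quadrant
    expect_identical(tr$triplets$quadrant, "+-")
    expect_equal(tr$summary$fraction_shared, 1)
    # flipping the coded allele flips both betas and maps +- to -+
    fx2 <- trip_fixture(m_beta = -0.2, e_beta = 0.5)
    tr2 <- build_triplets(fx2$mr, fx2$er, cpg_vals, mrna_vals)
    expect_identical(tr2$triplets$quadrant, "-+")
    # CpG 1.5 Mb from the TSS is excluded
    fx3 <- trip_fixture(0.2, -0.5)
    fx3$mr$probe_anchor <- fx3$er$probe_tss - 1500000L
    tr3 <- build_triplets(fx3$mr, fx3$er, cpg_vals, mrna_vals)
    expect_equal(nrow(tr3$triplets), 0)
    # one-sided significance still forms a (non-shared) triplet
    fx4 <- trip_fixture(0.2, -0.5, sig_e = FALSE)
    tr4 <- build_triplets(fx4$mr, fx4$er, cpg_vals, mrna_vals)
    expect_equal(nrow(tr4$triplets), 1)
    expect_false(tr4$triplets$shared)
    expect_equal(tr4$triplets$eqtl_beta, -0.5)   # observed, unthresholded
  })
})

test_that("subsampling returns deterministic per-iteration QTL metrics", {
  sim <- small_sim(seed = 37,
                   planted = list(planted_qtl(30, 4, "cpg", 0.6, "cis")))
  res <- residualize(sim$s$traits$FCTX$cpg, sim$s$covariates)
  core <- rownames(res$values)
  one <- subsample_qtl_rates(res, sim$g, core, n_iter = 1,
                             subset_size = 70, seed = 2, n_perm = 50)
  expect_equal(nrow(one), 1)
  expect_true(all(c("pct_probes_with_qtl", "mean_snps_per_probe",
                    "mean_r2") %in% names(one)))
  again <- subsample_qtl_rates(res, sim$g, core, n_iter = 1,
                               subset_size = 70, seed = 2, n_perm = 50)
  expect_identical(one, again)
  expect_error(subsample_qtl_rates(res, sim$g, core, n_iter = 0, seed = 1),
               "n_iter")
  expect_error(subsample_qtl_rates(res, sim$g, core, n_iter = 1,
                                   subset_size = 1000, seed = 1),
               "subset_size")
})
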