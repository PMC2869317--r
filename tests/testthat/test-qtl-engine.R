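test_that("dosage regression matches closed-form least squares", {
  # identity: trait == dosage
  r <- regress_trait_on_dosage(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2))
  expect_equal(r$beta, 1); expect_equal(r$r2, 1)
  # exact linear relation
  r2 <- regress_trait_on_dosage(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3),
                                c(0, 1, 2, 0, 1, 2))
  expect_equal(r2$beta, 0.1, tolerance = 1e-12)
  expect_equal(r2$r2, 1, tolerance = 1e-12)
  # noisy 6-sample example against the normal equations
  x <- c(0, 0, 1, 1, 2, 2); y <- c(1.0, 1.2, 1.9, 2.1, 3.0, 3.2)
  X <- cbind(1, x)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  r3 <- regress_trait_on_dosage(y, x)
  expect_equal(r3$beta, beta_hat[2], tolerance = 1e-12)
  expect_equal(r3$r2, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(unname(r3$counts), c(2L, 2L, 2L))
  fit <- summary(lm(y ~ x))
  expect_equal(r3$p, fit$coefficients[2, 4], tolerance = 1e-10)
  # degenerate inputs are skipped with a reason, not an error
  expect_match(regress_trait_on_dosage(c(1, 2, 3), c(1, 1, 1))$reason,
               "zero dosage variance")
  expect_match(regress_trait_on_dosage(c(1, 1, 1), c(0, 1, 2))$reason,
               "zero trait variance")
  expect_match(regress_trait_on_dosage(c(1, NA, 3), c(0, NA, 2))$reason,
               "fewer than 3")
})

test_that("LD r2 is the squared Pearson correlation of dosages", {
  a <- c(0, 1, 2, 0, 1, 2)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(c(-1, 1, -1, 1), c(1, 1, -1, -1)), 0)
  with_seed_test(3, {
    x <- sample(0:2, 6, TRUE); y <- sample(0:2, 6, TRUE)
    manual <- (sum((x - mean(x)) * (y - mean(y))))^2 /
      (sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(ld_r2(x, y), manual, tolerance = 1e-12)
  })
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.na(ld_r2(c(1, NA, NA, 2), c(0, 1, 2, NA))))
})

test_that("maxT empirical p-values follow the plus-one arithmetic", {
  with_seed_test(11, {
    n <- 100
    dos <- matrix(sample(0:2, n * 20, TRUE, c(0.25, 0.5, 0.25)), n, 20)
    g <- make_geno(dos)
    # a trait equal to one SNP's dosage plus tiny noise beats every maximum
    y <- dos[, 7] + rnorm(n, 0, 0.01)
    names(y) <- rownames(g$dosages)
    rec <- scan_trait(y, g, perm_plan(1000, seed = 2))
    expect_equal(rec$empP[7], 1 / 1001, tolerance = 1e-12)
    # pure-noise trait: the observed |t| of most SNPs sits inside the
    # permutation distribution; the weakest SNP must reach empP near 1
    y0 <- rnorm(n); names(y0) <- rownames(g$dosages)
    rec0 <- scan_trait(y0, g, perm_plan(500, seed = 3))
    expect_gte(max(rec0$empP, na.rm = TRUE), 0.99)
    expect_true(all(rec0$empP >= 1 / 501, na.rm = TRUE))
  })
})

test_that("empirical p is monotone in |t| and bounded below within a scan", {
  sim <- small_sim(seed = 23,
                   planted = list(planted_qtl(10, 2, "cpg", 0.5, "cis")))
  res <- residualize(sim$s$traits$FCTX$cpg, sim$s$covariates)
  rec <- scan_tissue(res, sim$g, perm_plan(200, seed = 5))
  for (p in unique(rec$probe)[1:5]) {
    sub <- rec[rec$probe == p & is.na(rec$skip_reason), ]
    o <- order(abs(sub$t))
    expect_true(all(diff(sub$empP[o]) <= 1e-12))
    expect_true(all(sub$empP >= 1 / 201))
  }
})

test_that("label-swapping permutations preserve the trait distribution", {
  y <- rnorm(40)
  idx <- permqtl:::perm_indices(40, perm_plan(50, seed = 1))
  for (k in c(1, 25, 50))
    expect_identical(sort(y[idx[, k]]), sort(y))
  # same seed gives the same permutations
  expect_identical(idx, permqtl:::perm_indices(40, perm_plan(50, seed = 1)))
})

test_that("scans agree between complete-data and pairwise-missing code paths", {
  with_seed_test(9, {
    n <- 60
    dos <- matrix(sample(0:2, n * 12, TRUE, c(0.3, 0.4, 0.3)), n, 12)
    y <- 0.4 * dos[, 3] + rnorm(n)
    g_complete <- make_geno(dos)
    dos_na <- dos; dos_na[5, 1] <- NA   # one missing dosage forces NA path
    g_na <- make_geno(dos_na)
    names(y) <- rownames(g_complete$dosages)
    plan <- perm_plan(100, seed = 4)
    rc <- scan_trait(y, g_complete, plan)
    rn <- scan_trait(y, g_na, plan)
    # untouched SNPs must agree to machine precision
    expect_equal(rc$t[-1], rn$t[-1], tolerance = 1e-10)
    expect_equal(rc$beta[-1], rn$beta[-1], tolerance = 1e-10)
    # the touched SNP agrees with the scalar regression on complete pairs
    ref <- regress_trait_on_dosage(y, dos_na[, 1])
    expect_equal(rn$beta[1], ref$beta, tolerance = 1e-10)
    expect_equal(rn$t[1], ref$t, tolerance = 1e-10)
    expect_equal(rn$fraction_samples_used[1], (n - 1) / n)
  })
})

test_that("BH across per-trait best empirical p fixes the threshold", {
  # 5-value worked example: p = (.001, .01, .03, .04, .8) at q = .05
  # BH by hand: 0.001<=0.01, 0.01<=0.02, 0.03<=0.03, 0.04<=0.04, 0.8>0.05
  expect_equal(permqtl:::bh_threshold(c(.001, .01, .03, .04, .8), 0.05), 0.04)
  rec <- data.frame(tissue = "T", kind = "cpg",
                    probe = paste0("p", 1:5), snp = paste0("s", 1:5),
                    empP = c(.001, .01, .03, .04, .8),
                    skip_reason = NA_character_)
  out <- call_significant(rec, genotypes = NULL, q = 0.05)
  expect_identical(out$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # all traits at the permutation floor: everything significant
  rec2 <- data.frame(tissue = "T", kind = "cpg",
                     probe = paste0("p", 1:100), snp = "s1",
                     empP = 0.000999, skip_reason = NA_character_)
  out2 <- call_significant(rec2, genotypes = NULL, q = 0.05)
  expect_true(all(out2$significant))
  # empty input passes through
  expect_equal(nrow(call_significant(rec[integer(0), ])), 0)
})

test_that("LD rescue requires r2 at or above the 0.7 boundary", {
  with_seed_test(14, {
    n <- 400
    base <- sample(0:2, n, TRUE, c(0.25, 0.5, 0.25))
    make_ld <- function(target) {
      # flip entries until the dosage correlation drops to ~target
      repeat {
        cand <- base
        flip <- sample(n, round(n * (1 - sqrt(target)) * 0.55))
        cand[flip] <- sample(0:2, length(flip), TRUE, c(0.25, 0.5, 0.25))
        if (abs(cor(base, cand)^2 - target) < 0.02) return(cand)
      }
    }
    hi <- make_ld(0.75); lo <- make_ld(0.40)
    dos <- cbind(s_sig = base, s_hi = hi, s_lo = lo)
    g <- make_geno(dos)
    rec <- data.frame(tissue = "T", kind = "cpg", probe = "p1",
                      snp = c("s_sig", "s_hi", "s_lo"),
                      empP = c(0.000999, 0.5, 0.5),
                      skip_reason = NA_character_)
    out <- call_significant(rec, g, q = 0.05)
    expect_true(out$significant[out$snp == "s_sig"])
    expect_true(out$significant[out$snp == "s_hi"])
    expect_true(out$rescue[out$snp == "s_hi"])
    expect_false(out$significant[out$snp == "s_lo"])
  })
})

test_that("probe-polymorphism filtering removes QTLs on compromised probes", {
  rec <- data.frame(tissue = "T", kind = "cpg",
                    probe = c("p1", "p1", "p2", "p3"),
                    snp = paste0("s", 1:4))
  iv <- data.frame(probe = c("p1", "p2"), chr = "chr1",
                   start = c(100L, 500L), end = c(150L, 550L))
  # variant inside p1; variant exactly at p2's end (half-open: outside)
  kv <- data.frame(chr = "chr1", pos = c(120L, 550L))
  expect_warning(out <- filter_probe_polymorphisms(rec, iv, kv), "p3")
  expect_identical(sort(unique(out$records$probe)), c("p2", "p3"))
  expect_equal(nrow(out$removed), 2)
  # variant 1 bp before a start is outside too
  kv2 <- data.frame(chr = "chr1", pos = 99L)
  out2 <- suppressWarnings(filter_probe_polymorphisms(rec, iv, kv2))
  expect_equal(nrow(out2$removed), 0)
  # empty variant list is the identity
  out3 <- filter_probe_polymorphisms(rec, iv, kv[integer(0), ])
  expect_identical(out3$records, rec)
})
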