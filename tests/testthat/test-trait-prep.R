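test_that("detection filter applies inclusive boundaries per tissue", {
  n <- 100
  det <- matrix(0, n, 3, dimnames = list(sprintf("S%03d", 1:n),
                                         c("pA", "pB", "pC")))
  det[1:5, "pB"] <- 0.5        # detected in exactly 95 of 100
  det[1:6, "pC"] <- 0.5        # detected in 94 of 100
  vals <- matrix(0.5, n, 3, dimnames = dimnames(det))
  tm <- make_traits(vals, det)
  res <- detection_filter(tm)
  expect_identical(res$retained[[1]], c("pA", "pB"))
  # detection p exactly at 0.01 counts as detected
  det2 <- det; det2[, "pA"] <- 0.01
  res2 <- detection_filter(make_traits(vals, det2))
  expect_true("pA" %in% res2$retained[[1]])
  # monotone: lowering min_frac never drops a previously kept probe
  res3 <- detection_filter(tm, min_frac = 0.90)
  expect_true(all(res$retained[[1]] %in% res3$retained[[1]]))
  # cross-tissue overlap counts
  tm2 <- make_traits(vals, det, tissue = "T2")
  both <- detection_filter(list(T1 = tm, T2 = tm2))
  expect_identical(both$common, c("pA", "pB"))
  expect_equal(unname(both$overlap[["2"]]), 2)
})

test_that("rank-invariant normalization recovers known scalings", {
  with_seed_test(4, {
    np <- 200
    ref_like <- exp(rnorm(np, 6, 1))
    vals <- rbind(a = ref_like, b = 2 * ref_like, c = ref_like)
    tm <- make_traits(vals, kind = "mrna")
    out <- rank_invariant_normalize(tm)
    # sample b is exactly twice the pseudo-reference shape: halved before log2
    expect_equal(unname(attr(out, "scale_factors")["b"]), 0.5, tolerance = 1e-6)
    # ranks preserved (monotone map)
    expect_equal(cor(rank(vals["a", ]), rank(out$values["a", ])), 1)
    # sample identical to the reference passes through as log2(input)
    tm_id <- make_traits(rbind(a = ref_like, b = ref_like), kind = "mrna")
    out_id <- rank_invariant_normalize(tm_id)
    expect_equal(out_id$values["a", ], log2(ref_like), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_error(rank_invariant_normalize(make_traits(rbind(a = c(1, -2, 3))),
                                          ), "positive")
  })
})

test_that("outlier samples beyond k SD on either metric are excluded", {
  with_seed_test(5, {
    vals <- matrix(rnorm(20 * 50, 8), 20, 50)
    rownames(vals) <- sprintf("S%03d", 1:20)
    vals["S007", ] <- vals["S007", ] + 10   # mean shifted by ~10 SD
    tm <- make_traits(vals, kind = "mrna")
    keep <- exclude_outlier_samples(tm)
    expect_false("S007" %in% keep)
    expect_length(keep, 19)
    # identical samples: none excluded
    tm_id <- make_traits(matrix(1, 6, 10))
    expect_length(exclude_outlier_samples(tm_id), 6)
  })
})

test_that("residualization matches the normal-equations solution", {
  # 6-sample worked example with one binary covariate, solved by hand:
  # X = [1, g], beta = (X'X)^-1 X'y
  y <- c(1.0, 2.0, 1.5, 3.0, 2.5, 4.0)
  gender <- c("M", "M", "M", "F", "F", "F")
  cov6 <- data.frame(sample = sprintf("S%03d", 1:6), gender = gender)
  X <- cbind(1, gender == "F")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expected <- as.numeric(y - X %*% beta)
  tm <- make_traits(matrix(y, 6, 1, dimnames = list(cov6$sample, "p1")))
  res <- residualize(tm, cov6)
  expect_equal(unname(res$values[, 1]), expected, tolerance = 1e-12)
})

test_that("residuals are orthogonal to covariates and idempotent", {
  sim <- small_sim(seed = 13)
  tm <- sim$s$traits$FCTX$cpg
  res <- residualize(tm, sim$s$covariates)
  X <- model.matrix(~ age + pmi + gender + bank + batch,
                    sim$s$covariates)[, -1]
  cors <- abs(cor(res$values, X))
  expect_lt(max(cors), 1e-10)
  # trait proportional to a covariate residualizes to ~0
  tm2 <- make_traits(matrix(2 * sim$s$covariates$age, ncol = 1,
                            dimnames = list(sim$s$covariates$sample, "p1")))
  res2 <- residualize(tm2, sim$s$covariates)
  expect_lt(max(abs(res2$values)), 1e-10)
  expect_equal(unname(res2$covariate_r2["p1"]), 1, tolerance = 1e-10)
  # idempotence
  tm3 <- tm; tm3$values <- res$values
  res3 <- residualize(tm3, sim$s$covariates)
  expect_equal(res3$values, res$values, tolerance = 1e-10)
  # trait uncorrelated with covariates: residual = centered trait
  with_seed_test(6, {
    v <- rnorm(80)
    tm4 <- make_traits(matrix(v, ncol = 1,
                              dimnames = list(sim$s$covariates$sample, "p1")))
    res4 <- residualize(tm4, sim$s$covariates)
    expect_equal(mean(res4$values), 0, tolerance = 1e-12)
    expect_lt(max(abs(res4$values - (v - mean(v)))), 0.8)
  })
})

test_that("methylation-based sex inference separates simulated sexes", {
  sim <- small_sim(seed = 17)
  cpg <- sim$s$traits$FCTX$cpg
  sex <- infer_methylation_sex(cpg, sim$s$covariates$gender)
  expect_identical(sex$inferred, sim$s$covariates$gender)
  expect_false(any(sex$mismatch))
  one <- cpg; one$values <- one$values[1, , drop = FALSE]
  one$detection <- one$detection[1, , drop = FALSE]
  expect_error(infer_methylation_sex(one), "2 samples")
})

test_that("average-linkage clustering matches structure and the O(n^3) oracle", {
  with_seed_test(8, {
    # two planted groups with distinct means bipartition the tree
    v <- rbind(matrix(rnorm(5 * 20, 0), 5, 20), matrix(rnorm(5 * 20, 6), 5, 20))
    rownames(v) <- c(paste0("a", 1:5), paste0("b", 1:5))
    nwk <- cluster_samples(v)
    tree <- ape::read.tree(text = nwk)
    splits <- ape::prop.part(tree)
    grp_a <- sort(paste0("a", 1:5))
    found <- any(vapply(splits, function(s)
      identical(sort(attr(splits, "labels")[s]), grp_a), logical(1)))
    expect_true(found)
    # two samples: a single join at their Euclidean distance
    v2 <- rbind(x = c(0, 0), y = c(3, 4))
    nwk2 <- cluster_samples(v2)
    hc2 <- attr(nwk2, "hclust")
    expect_equal(hc2$height, 5)
    # cophenetic distances agree with the brute-force UPGMA oracle
    for (rep in 1:3) {
      n <- sample(8:20, 1)
      M <- matrix(rnorm(n * 6), n, 6)
      rownames(M) <- sprintf("S%02d", 1:n)
      hc <- attr(cluster_samples(M), "hclust")
      coph <- as.matrix(stats::cophenetic(hc))
      oracle <- upgma_cophenetic_oracle(dist(M))
      dimnames(oracle) <- list(rownames(M), rownames(M))
      expect_equal(coph[rownames(M), rownames(M)], oracle, tolerance = 1e-9)
    }
    expect_error(cluster_samples(rbind(c(1, NA), c(2, 3))), "NA")
  })
})
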