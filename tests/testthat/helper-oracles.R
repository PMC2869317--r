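# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately use different arithmetic routes from the package
# implementations they check.

# --- Hardy-Weinberg exact test by direct log-factorial enumeration ---------
hwe_enumeration_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n - nA
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((nB - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_AB, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# --- CpG island caller by brute-force window scan --------------------------
island_window_stats <- function(v, s, e) {           # 1-based inclusive
  w <- v[s:e]
  L <- e - s + 1
  nC <- sum(w == "C"); nG <- sum(w == "G")
  ncpg <- sum(w[-L] == "C" & w[-1] == "G")
  gc <- (nC + nG) / L
  oe <- if (nC * nG > 0) ncpg * L / (nC * nG) else 0
  c(gc = gc, oe = oe)
}

island_bruteforce_oracle <- function(seq_char, min_len = 200, gc_min = 0.5,
                                     oe_min = 0.6) {
  v <- strsplit(seq_char, "")[[1]]
  L <- length(v)
  out <- data.frame(start = integer(), end = integer(),
                    gc_fraction = numeric(), obs_exp_cpg = numeric())
  if (L < min_len) return(out)
  qual <- integer(0)
  for (s in 1:(L - min_len + 1)) {
    st <- island_window_stats(v, s, s + min_len - 1)
    if (st[["gc"]] >= gc_min && st[["oe"]] >= oe_min) qual <- c(qual, s)
  }
  if (length(qual) == 0) return(out)
  # union of covered intervals, merging overlapping or adjacent
  starts <- qual; ends <- qual + min_len - 1
  m_start <- starts[1]; m_end <- ends[1]
  merged <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= m_end + 1) m_end <- max(m_end, ends[i])
    else { merged[[length(merged) + 1]] <- c(m_start, m_end)
           m_start <- starts[i]; m_end <- ends[i] }
  }
  merged[[length(merged) + 1]] <- c(m_start, m_end)
  for (mm in merged) {
    st <- island_window_stats(v, mm[1], mm[2])
    if ((mm[2] - mm[1] + 1) >= min_len && st[["gc"]] >= gc_min &&
        st[["oe"]] >= oe_min)
      out <- rbind(out, data.frame(start = mm[1] - 1L, end = mm[2],
                                   gc_fraction = st[["gc"]],
                                   obs_exp_cpg = st[["oe"]]))
  }
  out
}

random_dna <- function(len, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- O(n^3) UPGMA returning the cophenetic distance matrix -----------------
upgma_cophenetic_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d_ij <- mean(D[clusters[[i]], clusters[[j]]])
      if (d_ij < best_d) { best_d <- d_ij; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# --- fixture builders -------------------------------------------------------
make_geno <- function(dos, chr = NULL, pos = NULL, imputed = NULL,
                      imputation_r2 = NULL, posterior_avg = NULL,
                      covariates = NULL) {
  m <- ncol(dos)
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("s%04d", seq_len(m))
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("S%03d", seq_len(nrow(dos)))
  si <- data.frame(snp = colnames(dos),
                   chr = chr %||% rep("chr1", m),
                   pos = pos %||% (seq_len(m) * 1000L),
                   block = NA_integer_,
                   imputed = imputed %||% rep(FALSE, m),
                   imputation_r2 = imputation_r2 %||% rep(NA_real_, m),
                   posterior_avg = posterior_avg %||% rep(NA_real_, m),
                   stringsAsFactors = FALSE)
  structure(list(dosages = dos, snp_info = si, covariates = covariates,
                 truth_dosages = dos, config_seed = NULL),
            class = "geno_matrix")
}

make_traits <- function(values, detection = NULL, probes = NULL,
                        kind = "cpg", tissue = "T1") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("p%04d", seq_len(ncol(values)))
  if (is.null(detection)) {
    detection <- matrix(0, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (is.null(probes)) {
    np <- ncol(values)
    anchor <- seq_len(np) * 10000L
    probes <- data.frame(probe = colnames(values), kind = kind, chr = "chr1",
                         start = anchor, end = anchor + 2L, strand = ".",
                         tss = if (kind == "mrna") anchor else NA_integer_,
                         anchor = anchor, stringsAsFactors = FALSE)
  }
  structure(list(values = values, detection = detection, probes = probes,
                 kind = kind, tissue = tissue),
            class = "trait_matrix")
}

make_covariates <- function(n, seed = 1) {
  with_seed_test(seed, data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    age = round(runif(n, 20, 90)),
    gender = sample(c("M", "F"), n, TRUE),
    pmi = round(runif(n, 2, 20), 1),
    bank = sample(c("bankA", "bankB"), n, TRUE),
    batch = sample(paste0("batch", 1:3), n, TRUE),
    stringsAsFactors = FALSE))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard small simulated cohort reused across tests
small_sim <- function(seed = 7, planted = list(), ...) {
  cfg <- sim_config(n_samples = 80, n_snps = 120, n_cpg_probes = 20,
                    n_mrna_probes = 20, planted_qtls = planted,
                    tissues = c("FCTX", "PONS"), n_x_snps = 12, n_x_cpgs = 12,
                    seed = seed, ...)
  g <- simulate_genotypes(cfg)
  s <- simulate_traits(g, cfg)
  list(cfg = cfg, g = g, s = s)
}
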