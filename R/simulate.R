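# Synthetic cohort generator: LD-block dosages, beta-like CpG methylation and
# log2 expression with planted additive genotype effects, covariate
# confounding and sparse missingness. Everything is a deterministic function
# of the sim_config (including its seed).

N_AUTOSOMES <- 22L
SNP_SPACING <- 3000      # bp between SNPs within an LD block
BLOCK_GAP <- 200000      # bp between blocks on a chromosome
CHR_OFFSET <- 100000     # first block start on each chromosome

sample_ids <- function(n) sprintf("S%03d", seq_len(n))

# Per-sample covariates; seeded by a fixed offset from the master seed so
# genotype simulation (which needs gender for X hemizygosity) and trait
# simulation derive the identical table.
simulate_covariates <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_samples
    data.frame(
      sample = sample_ids(n),
      age = round(pmin(100, pmax(16, stats::rnorm(n, 65, 15)))),
      gender = sample(c("M", "F"), n, replace = TRUE),
      pmi = round(pmax(1, stats::rnorm(n, 10, 4)), 1),
      bank = sample(c("bankA", "bankB"), n, replace = TRUE),
      batch = sample(paste0("batch", 1:4), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# Genomic layout of the autosomal SNP panel: blocks round-robin over 22
# autosomes, SNPs evenly spaced within a block. 0-based coordinates.
snp_layout <- function(n_snps, block_size) {
  block <- (seq_len(n_snps) - 1L) %/% block_size
  within_block <- (seq_len(n_snps) - 1L) %% block_size
  chr_i <- block %% N_AUTOSOMES
  slot <- block %/% N_AUTOSOMES
  pos <- CHR_OFFSET + slot * (block_size * SNP_SPACING + BLOCK_GAP) +
    within_block * SNP_SPACING
  data.frame(snp = sprintf("snp%05d", seq_len(n_snps)),
             chr = paste0("chr", chr_i + 1L), pos = as.integer(pos),
             block = block + 1L, stringsAsFactors = FALSE)
}

#' Simulate allele-dosage genotypes with LD-block structure
#'
#' Haplotypes are drawn from a per-block Gaussian AR(1) copula (latent
#' correlation `ld_rho`) and thresholded at the per-SNP allele frequency, so
#' adjacent SNPs within a block are correlated while blocks are independent.
#' In `"imputed"` mode a fraction of SNPs is flagged imputed, given simulated
#' imputation-quality metrics, and their dosages are jittered (more for lower
#' reported quality) into \[0,2\]. X-chromosome SNPs are hemizygous in males.
#'
#' @param config a [sim_config()].
#' @return a `geno_matrix`: list with `dosages` (samples x SNPs, `NA` =
#'   missing), `snp_info` (snp, chr, pos, block, imputed, imputation_r2,
#'   posterior_avg), `covariates`, and `truth_dosages` (pre-noise,
#'   pre-missingness dosages; simulation ground truth only).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  covariates <- simulate_covariates(config)
  n <- config$n_samples
  m <- config$n_snps
  info <- snp_layout(m, config$ld_block_size)

  planted_snps <- unique(vapply(config$planted_qtls, `[[`, integer(1), "snp_index"))

  with_seed(derive_seed(config$seed, 2L), {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    if (length(planted_snps)) {
      lo <- min(max(config$maf_range[1], config$planted_maf_min),
                config$maf_range[2])
      maf[planted_snps] <- stats::runif(length(planted_snps), lo,
                                        config$maf_range[2])
    }
    rho <- config$ld_rho
    # Latent AR(1) process per haplotype, restarting at block boundaries.
    z <- matrix(stats::rnorm(2L * n * m), nrow = 2L * n, ncol = m)
    if (m > 1L) {
      for (j in 2:m) {
        if (info$block[j] == info$block[j - 1L])
          z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
      }
    }
    alleles <- z < matrix(stats::qnorm(maf), nrow = 2L * n, ncol = m, byrow = TRUE)
    dos <- alleles[seq_len(n), , drop = FALSE] +
      alleles[n + seq_len(n), , drop = FALSE]
    storage.mode(dos) <- "double"

    # X-chromosome SNPs: independent sites, males carry one haplotype.
    mx <- config$n_x_snps
    if (mx > 0L) {
      maf_x <- stats::runif(mx, config$maf_range[1], config$maf_range[2])
      hap1 <- matrix(stats::runif(n * mx), n, mx) <
        matrix(maf_x, n, mx, byrow = TRUE)
      hap2 <- matrix(stats::runif(n * mx), n, mx) <
        matrix(maf_x, n, mx, byrow = TRUE)
      male <- covariates$gender == "M"
      hap2[male, ] <- hap1[male, ]      # hemizygous: second copy mirrors first
      dosx <- hap1 + hap2
      storage.mode(dosx) <- "double"
      dos <- cbind(dos, dosx)
      info <- rbind(info,
                    data.frame(snp = sprintf("snpX%04d", seq_len(mx)),
                               chr = "chrX",
                               pos = as.integer(CHR_OFFSET + (seq_len(mx) - 1L) * 50000),
                               block = NA_integer_, stringsAsFactors = FALSE))
      maf <- c(maf, maf_x)
    }
    m_all <- ncol(dos)

    info$imputed <- FALSE
    info$imputation_r2 <- NA_real_
    info$posterior_avg <- NA_real_
    truth <- dos
    if (config$dosage_mode == "imputed" && config$imputed_fraction > 0) {
      eligible <- setdiff(seq_len(m), planted_snps)  # planted SNPs stay genotyped
      n_imp <- min(length(eligible), floor(config$imputed_fraction * m))
      imp <- sort(sample(eligible, n_imp))
      info$imputed[imp] <- TRUE
      info$imputation_r2[imp] <- stats::runif(n_imp, 0.2, 1)
      info$posterior_avg[imp] <- stats::runif(n_imp, 0.7, 1)
      for (j in imp) {
        noise_sd <- 0.5 * (1 - info$imputation_r2[j])
        dos[, j] <- pmin(2, pmax(0, dos[, j] + stats::rnorm(n, 0, noise_sd)))
      }
      truth <- dos  # planted effects act on the dosages analysts will see
    }

    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m_all) < config$missing_rate, n, m_all)
      dos[miss] <- NA_real_
    }

    dimnames(dos) <- list(sample_ids(n), info$snp)
    dimnames(truth) <- dimnames(dos)
    structure(list(dosages = dos, snp_info = info, covariates = covariates,
                   truth_dosages = truth, maf_target = maf,
                   config_seed = config$seed),
              class = "geno_matrix")
  })
}

chrom_spans <- function(snp_info) {
  sp <- tapply(snp_info$pos, snp_info$chr, max)
  spans <- as.integer(sp + 1e6)
  names(spans) <- names(sp)
  spans
}

# Place probes on the genome honouring planted cis/trans geometry.
place_probes <- function(kind, n_probes, plant_by_probe, snp_info, spans) {
  if (n_probes == 0L)
    return(data.frame(probe = character(), kind = character(),
                      chr = character(), start = integer(), end = integer(),
                      strand = character(), tss = integer(),
                      anchor = integer(), stringsAsFactors = FALSE))
  chrs <- paste0("chr", seq_len(N_AUTOSOMES))
  chr <- sample(chrs, n_probes, replace = TRUE)
  anchor <- integer(n_probes)
  for (i in seq_len(n_probes)) {
    lim <- if (chr[i] %in% names(spans)) spans[[chr[i]]] else 2000000L
    anchor[i] <- as.integer(stats::runif(1, 50000, lim))
  }
  strand <- if (kind == "mrna") sample(c("+", "-"), n_probes, TRUE) else rep(".", n_probes)
  for (i in seq_len(n_probes)) {
    pq <- plant_by_probe[[i]]
    if (is.null(pq)) next
    s_chr <- snp_info$chr[pq$snp_index]
    s_pos <- snp_info$pos[pq$snp_index]
    if (pq$mode == "cis") {
      d <- pq$distance %||% (sample(c(-1, 1), 1) * round(stats::runif(1, 1000, 500000)))
      if (s_pos + d < 1000) d <- abs(d)
      chr[i] <- s_chr
      anchor[i] <- as.integer(s_pos + d)
    } else {
      other <- setdiff(chrs, s_chr)
      chr[i] <- sample(other, 1)
      lim <- if (chr[i] %in% names(spans)) spans[[chr[i]]] else 2000000L
      anchor[i] <- as.integer(stats::runif(1, 50000, lim))
    }
  }
  if (kind == "cpg") {
    data.frame(probe = sprintf("cg%05d", seq_len(n_probes)), kind = "cpg",
               chr = chr, start = anchor, end = anchor + 2L, strand = strand,
               tss = NA_integer_, anchor = anchor, stringsAsFactors = FALSE)
  } else {
    len <- as.integer(round(stats::runif(n_probes, 5000, 50000)))
    start <- ifelse(strand == "+", anchor, pmax(0L, anchor - len))
    end <- ifelse(strand == "+", anchor + len, anchor)
    data.frame(probe = sprintf("tx%05d", seq_len(n_probes)), kind = "mrna",
               chr = chr, start = as.integer(start), end = as.integer(end),
               strand = strand, tss = anchor, anchor = anchor,
               stringsAsFactors = FALSE)
  }
}

new_trait_matrix <- function(values, detection, probes, kind, tissue) {
  structure(list(values = values, detection = detection, probes = probes,
                 kind = kind, tissue = tissue),
            class = "trait_matrix")
}

# Numeric unit-variance score for one covariate column.
covariate_score <- function(x) {
  v <- if (is.numeric(x)) x else as.numeric(factor(x))
  s <- stats::sd(v)
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Simulate CpG methylation and mRNA expression traits with planted QTLs
#'
#' Each probe's liability is an additive model: a planted genotype effect
#' explaining `target_r2` of trait variance (in the tissues carrying it),
#' covariate components with the configured variance fractions, and Gaussian
#' noise split into a cross-tissue shared part (fraction `tissue_cor`) and a
#' tissue-specific part. CpG values are a logistic squash of the liability
#' (bounded in \[0,1\], bimodal at the extremes across probes); mRNA values
#' are on the log2 scale. Detection p-values are emitted, with a configurable
#' fraction of unplanted probes simulated as poorly detected.
#'
#' @param genotypes result of [simulate_genotypes()] under the same config.
#' @param config the same [sim_config()].
#' @return list with `traits` (per tissue, per kind [trait_matrix] objects),
#'   `covariates`, and `truth` (one row per planted effect).
#' @export
simulate_traits <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  if (!identical(genotypes$config_seed, config$seed))
    stop2("genotypes were not simulated under this config")
  for (pq in config$planted_qtls) {
    if (pq$snp_index > config$n_snps) stop2("planted snp_index out of range")
  }
  n <- config$n_samples
  covariates <- genotypes$covariates
  covs <- config$covariate_effect_sizes
  covsum <- sum(covs)
  tissues <- config$tissues
  tc <- config$tissue_cor

  scores <- vapply(names(covs), function(nm) covariate_score(covariates[[nm]]),
                   numeric(n))

  with_seed(derive_seed(config$seed, 3L), {
    spans <- chrom_spans(genotypes$snp_info)
    kinds <- list(cpg = config$n_cpg_probes, mrna = config$n_mrna_probes)
    plant_by <- list(cpg = vector("list", config$n_cpg_probes),
                     mrna = vector("list", config$n_mrna_probes))
    for (pq in config$planted_qtls) plant_by[[pq$trait_kind]][[pq$probe_index]] <- pq

    probes <- list()
    truth_rows <- list()
    values <- list()
    detection <- list()

    for (kind in names(kinds)) {
      np <- kinds[[kind]]
      pr <- place_probes(kind, np, plant_by[[kind]], genotypes$snp_info, spans)
      probes[[kind]] <- pr
      if (np == 0L) next

      # per-probe baselines
      if (kind == "cpg") {
        comp <- sample(1:3, np, replace = TRUE, prob = c(0.65, 0.25, 0.10))
        mu_pool <- c(stats::rnorm(np, -3, 0.8), stats::rnorm(np, 3, 0.8),
                     stats::rnorm(np, 0, 1))
        mu <- mu_pool[seq_len(np) + (comp - 1L) * np]
        squash <- rep(1.0, np)
      } else {
        mu <- stats::rnorm(np, 8, 1.5)
        squash <- rep(1.0, np)
      }
      sign_cov <- matrix(sample(c(-1, 1), np * length(covs), replace = TRUE),
                         np, length(covs))

      vals <- lapply(tissues, function(t) matrix(NA_real_, n, np,
                                                 dimnames = list(sample_ids(n), pr$probe)))
      names(vals) <- tissues
      dets <- vals

      for (i in seq_len(np)) {
        pq <- plant_by[[kind]][[i]]
        r2 <- 0
        gterm <- NULL
        mask <- tissues
        if (!is.null(pq)) {
          r2 <- pq$target_r2
          sgn <- pq$sign %||% sample(c(-1, 1), 1)
          d <- genotypes$truth_dosages[, pq$snp_index]
          sdd <- stats::sd(d)
          if (sdd == 0) stop2("planted SNP is monomorphic; raise maf_range")
          gterm <- sgn * sqrt(r2) * (d - mean(d)) / sdd
          mask <- pq$tissue_mask %||% tissues
          mu[i] <- if (kind == "cpg") 0 else mu[i]
          squash[i] <- if (kind == "cpg") 0.5 else 1.0
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            probe = pr$probe[i], kind = kind,
            snp = genotypes$snp_info$snp[pq$snp_index],
            snp_index = pq$snp_index, target_r2 = r2, sign = sgn,
            mode = pq$mode, probe_chr = pr$chr[i], probe_anchor = pr$anchor[i],
            snp_chr = genotypes$snp_info$chr[pq$snp_index],
            snp_pos = genotypes$snp_info$pos[pq$snp_index],
            tissues = paste(mask, collapse = ","), stringsAsFactors = FALSE)
        }
        covterm <- as.numeric(scores %*% (sign_cov[i, ] * sqrt(covs)))
        e_shared <- stats::rnorm(n)
        # constant per-tissue offset: separates tissues without touching
        # within-tissue variance or planted effect sizes
        shift <- stats::rnorm(length(tissues), 0, config$tissue_shift_sd)
        names(shift) <- tissues
        for (t in tissues) {
          active <- !is.null(gterm) && t %in% mask
          resid_var <- 1 - covsum - if (active) r2 else 0
          e_t <- stats::rnorm(n)
          L <- shift[[t]] + covterm +
            sqrt(resid_var) * (sqrt(tc) * e_shared + sqrt(1 - tc) * e_t)
          if (active) L <- L + gterm
          vals[[t]][, i] <- if (kind == "cpg") stats::plogis(mu[i] + squash[i] * L)
                            else mu[i] + L
        }
      }

      # detection p-values: detected probes near zero, a fraction of
      # unplanted probes poorly detected, sparse random dropouts elsewhere
      planted_idx <- which(!vapply(plant_by[[kind]], is.null, logical(1)))
      n_undet <- round(config$undetected_frac * np)
      undet <- if (n_undet > 0)
        sample(setdiff(seq_len(np), planted_idx), min(n_undet, np - length(planted_idx)))
      else integer(0)
      for (t in tissues) {
        dp <- matrix(stats::runif(n * np, 0, 0.005), n, np,
                     dimnames = dimnames(vals[[t]]))
        if (length(undet)) dp[, undet] <- stats::runif(n * length(undet), 0, 0.05)
        drop <- matrix(stats::runif(n * np) < 0.005, n, np)
        dp[drop] <- stats::runif(sum(drop), 0.011, 1)
        dets[[t]][, ] <- dp
      }
      values[[kind]] <- vals
      detection[[kind]] <- dets
    }

    # X-chromosome CpG probes appended for methylation-based sex inference:
    # females (mosaic X inactivation) intermediate, males low.
    if (config$n_x_cpgs > 0L) {
      nx <- config$n_x_cpgs
      posx <- as.integer(CHR_OFFSET + (seq_len(nx) - 1L) * 40000 + 13000)
      prx <- data.frame(probe = sprintf("cgX%04d", seq_len(nx)), kind = "cpg",
                        chr = "chrX", start = posx, end = posx + 2L,
                        strand = ".", tss = NA_integer_, anchor = posx,
                        stringsAsFactors = FALSE)
      probes$cpg <- rbind(probes$cpg, prx)
      female <- covariates$gender == "F"
      mu_x <- ifelse(female, 0, -2.5)
      for (t in tissues) {
        vx <- stats::plogis(matrix(mu_x, n, nx) + matrix(stats::rnorm(n * nx, 0, 0.5), n, nx))
        dimnames(vx) <- list(sample_ids(n), prx$probe)
        values$cpg[[t]] <- cbind(values$cpg[[t]], vx)
        dx <- matrix(stats::runif(n * nx, 0, 0.005), n, nx,
                     dimnames = dimnames(vx))
        detection$cpg[[t]] <- cbind(detection$cpg[[t]], dx)
      }
    }

    traits <- lapply(tissues, function(t) {
      out <- list()
      for (kind in names(kinds)) {
        if (is.null(values[[kind]])) next
        out[[kind]] <- new_trait_matrix(values[[kind]][[t]], detection[[kind]][[t]],
                                        probes[[kind]], kind, t)
      }
      out
    })
    names(traits) <- tissues

    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(probe = character(), kind = character(), snp = character(),
                 snp_index = integer(), target_r2 = numeric(), sign = numeric(),
                 mode = character(), probe_chr = character(),
                 probe_anchor = integer(), snp_chr = character(),
                 snp_pos = integer(), tissues = character(),
                 stringsAsFactors = FALSE)
    list(traits = traits, covariates = covariates, truth = truth)
  })
}

#' Generate a small FASTA with planted CpG-island and non-island sequence
#'
#' Builds one synthetic contig: AT-rich background (GC about 25%) with an
#' embedded GC- and CpG-rich segment satisfying the island criteria
#' (length >= 200, GC >= 0.5, observed/expected CpG >= 0.6).
#'
#' @param seed integer seed.
#' @param background_len,island_len segment lengths (bp).
#' @param island_at 0-based offset of the island within the contig.
#' @return a [Biostrings::DNAStringSet] of length 1, named `islandtest`, with
#'   attribute `island` = c(start, end) (0-based half-open planted interval).
#' @export
make_island_fasta <- function(seed, background_len = 4000, island_len = 400,
                              island_at = 1500) {
  with_seed(seed, {
    bg_probs <- c(A = 0.375, C = 0.125, G = 0.125, T = 0.375)
    isl_probs <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
    draw <- function(len, probs) sample(names(probs), len, TRUE, probs)
    seqv <- draw(background_len, bg_probs)
    isl <- draw(island_len, isl_probs)
    seqv[island_at + seq_len(island_len)] <- isl
    x <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
    names(x) <- "islandtest"
    attr(x, "island") <- c(island_at, island_at + island_len)
    x
  })
}
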