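#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' follows the Levene-Haldane distribution. The exact two-sided p-value sums
#' the probabilities of every heterozygote count (with the same allele totals)
#' whose probability does not exceed that of the observed count.
#'
#' Probabilities are built by the stable multiplicative recurrence from the
#' modal heterozygote count and normalized by their sum; the "does not exceed"
#' comparison carries a 1e-9 relative guard so analytically tied counts (the
#' distribution can be symmetric) are never split by floating-point noise.
#'
#' @param n_AA,n_AB,n_BB genotype counts (non-negative, total >= 1).
#' @return exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal table: p = 1
#' hwe_exact_test(5, 0, 95)     # strong heterozygote deficit
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0) || any(c(n_AA, n_AB, n_BB) != round(c(n_AA, n_AB, n_BB))))
    stop2("genotype counts must be non-negative integers")
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop2("at least one genotype required")
  # canonicalize so A is the rarer allele: exact symmetry under relabeling
  if (n_AA > n_BB) { tmp <- n_AA; n_AA <- n_BB; n_BB <- tmp }
  nA <- 2L * n_AA + n_AB
  nB <- 2L * n_BB + n_AB
  rare <- min(nA, nB)
  if (rare == 0L) return(1)           # monomorphic site
  # heterozygote counts share the parity of the rare-allele total
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hs))
  # start at (approximately) the modal count and recurse outward:
  # P(h+2)/P(h) = (nA-h)(nB-h) / ((h+2)(h+1) / ... ) for hom pair formation
  mode_h <- round(as.numeric(nA) * nB / (2 * n - 1))
  mode_h <- hs[which.min(abs(hs - mode_h))]
  i0 <- match(mode_h, hs)
  probs[i0] <- 1
  if (i0 < length(hs)) {
    for (i in i0:(length(hs) - 1L)) {
      h <- hs[i]
      probs[i + 1L] <- probs[i] * (nA - h) * (nB - h) / ((h + 2) * (h + 1))
    }
  }
  if (i0 > 1L) {
    for (i in i0:2L) {
      h <- hs[i]
      probs[i - 1L] <- probs[i] * h * (h - 1) / ((nA - h + 2) * (nB - h + 2))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_AB, hs)]
  if (is.na(p_obs)) stop2("heterozygote count inconsistent with allele totals")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}
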