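---
title: "Mapping methylation and expression QTLs with maxT permutation significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping methylation and expression QTLs with maxT permutation significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

permqtl maps quantitative trait loci for two molecular phenotypes measured on
the same subjects across several tissues: CpG methylation beta values
(methQTL) and mRNA expression intensities (eQTL). This vignette is the
package's account of the statistical machinery: the association model, the
two-level multiple-testing correction, the annotation and integration steps,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices behind each stage.

## The association model

For one trait $y$ (a residualized probe) and one SNP with allele dosage
$g \in [0,2]$, the model is ordinary least squares

$$y_i = \mu + \beta g_i + \varepsilon_i,$$

fit on pairwise-complete observations. The reported quantities are the slope
$\beta$ (trait units per dosage unit), the squared Pearson correlation $r^2$,
the two-sided asymptotic t-test p-value, and the genotype class counts
obtained by rounding dosages to the nearest integer (half to even). Dosages
may be non-integer for imputed genotypes; nothing in the model requires hard
calls.

Traits enter the regression as residuals from a covariate model fit per
probe: age and post-mortem interval as numeric covariates, gender, tissue
bank and batch dummy-coded. Methylation is residualized on the raw beta
scale; expression on the log2 scale after (optional) rank-invariant
normalization. Residuals are exactly orthogonal to every retained design
column (QR residuals; the suite checks $|\mathrm{cor}| < 10^{-10}$), and
rank-deficient columns are dropped with a warning rather than silently
absorbed.

## Two-level multiple-testing correction

The correction mirrors the structure of the problem: millions of SNPs per
trait, thousands of traits per tissue.

**Per trait (across SNPs): maxT permutation.** The trait vector is permuted
(label swapping) `n_perm` times; permutations are shared across SNPs within
a trait — the defining requirement of maxT — and drawn independently across
traits from seeds derived from the master seed and the probe name. For each
permutation the genome-wide maximum $|t|$ is recorded, and the empirical
p-value of a SNP is the plus-one estimator

$$\hat p = \frac{1 + \#\{\text{permutation maxima} \ge |t_{\text{obs}}|\}}{n_{\text{perm}} + 1},$$

bounded below by $1/(n_{\text{perm}}+1)$ — with 1,000 permutations the floor
is 0.000999. Label swapping preserves the trait's empirical distribution
exactly (no normality assumption) and keeps the LD structure of the genotype
matrix intact under the null. Within a scan the empirical p-value is
monotone non-increasing in $|t|$ by construction.

**Across traits: FDR with an empirical-p threshold.** Each trait is
represented by its best (minimum) empirical p-value; Benjamini–Hochberg at
level $q = 0.05$ across those per-trait minima fixes an empirical-p
threshold, and every SNP–trait pair at or below it is significant. This
two-level scheme is deliberately conservative: with $m$ traits and floor
$f$, a lone associated trait can only be detected when $f \le q/m$, so the
permutation count bounds the detectable trait fraction. Under a global null
the expected number of traits at the floor is about $m f$, which is why the
null-calibration check (no planted effects, 20 seeds) sees essentially no
calls.

**LD rescue.** A SNP whose dosage $r^2$ (squared Pearson correlation,
defined for unphased dosages without haplotype estimation) with an already
significant SNP for the same trait is at least 0.7 is marked significant
with a `rescue` flag. The boundary is inclusive.

All quoted QC thresholds use strict exclusion semantics ("less than"), so
values exactly at a threshold pass: SNPs are dropped when call rate < 0.95,
exact Hardy–Weinberg p < 0.001, minor-homozygote count < 3, or (for imputed
SNPs) imputation $r^2$ < 0.3 or posterior average < 0.8. The HWE test is the
Levene–Haldane exact test (probabilities by the stable multiplicative
recurrence from the modal heterozygote count, two-sided by summing all
configurations no more probable than the observed one); an exact test rather
than chi-square because the minor-homozygote filter targets exactly the
sparse-cell regime where the asymptotic test misbehaves. For X-chromosome
SNPs the test uses female samples only, males being hemizygous.

## Annotation and integration

A SNP–probe pair is **cis** iff both lie on the same chromosome and the
distance from the SNP to the probe anchor is at most 1 Mb (inclusive, i.e.
cis means ±1 Mb). For CpG probes the anchor is the CpG coordinate. For mRNA
probes an ambiguity had to be resolved: classification uses the distance to
the transcript span (zero inside), while the reported signed distance — and
the positional enrichment curves — use the strand-corrected TSS (negative =
upstream). Coordinates are 0-based half-open internally and 1-based in
human-facing TSV output.

**CpG islands** follow the classical composition definition: maximal regions
of length ≥ 200 bp with GC fraction ≥ 0.5 and observed/expected CpG ratio
$\ge 0.6$, where obs/exp $= \#\mathrm{CpG} \cdot L / (\#C \cdot \#G)$. The
caller slides a 200 bp window at step 1, merges overlapping or adjacent
qualifying windows, and re-tests each merged region against the same
criteria, keeping only regions that still qualify — a deterministic variant
of the classic algorithm, checked exactly against a brute-force all-windows
oracle. `N` bases count toward window length but not toward GC or CpG
counts; membership of a CpG in an island is half-open (start inclusive, end
exclusive).

**Enrichment** compares the proportion of significant pairs among possible
cis pairs to the same proportion among possible trans pairs, where the
universe is every tested SNP–probe combination — significant or not. The
distance scan re-classifies pairs at 50 thresholds, each four-fifths the
size of the next larger one starting from 1 Mb (smallest ≈ 17.8 bp), and
reports the fold at each plus the peak threshold; infinite folds (no
significant trans) outrank finite ones and ties go to the smallest
threshold. When a threshold leaves a possible class empty the fold is
undefined (`NA`) and skipped in peak finding.

**Cross-tissue comparison** takes the union over tissues of significant
pairs and reports each pair's $r^2$ and significance flag in every tissue,
plus counts by the number of tissues in which the pair is significant.
Ternary (barycentric) coordinates — each of three per-tissue $r^2$ values
divided by their sum, with the sum as the cumulative effect — support the
three-tissue comparison plots; they are scale invariant by construction.

**Triplets.** CpG–mRNA pairs with the CpG within 1 Mb of the mRNA TSS where
at least one member has a significant cis QTL are expanded by every SNP
significantly cis-associated with either member. Each triplet records both
effects, the squared CpG–mRNA trait correlation (computed on the samples
shared by both matrices), and the sign quadrant
$(\mathrm{sign}(\beta_{\text{meth}}), \mathrm{sign}(\beta_{\text{expr}}))$;
"+−" is the methylation-positive/expression-negative quadrant. Two choices
were genuinely open and are resolved as follows: the denominator of the
"shared QTL" fraction is all formed triplets, and the non-significant side
of a triplet contributes its observed, unthresholded $\beta$ and $r^2$ when
the pair was tested (zero only when untested) — the quadrant should reflect
measured effects, not censored ones.

**Subsampling.** The stability analysis redraws sample subsets from a fixed
core set without replacement (default subset size: core size − 10), reruns
scan + significance per subset, and records the percentage of probes with a
QTL, the mean number of significant SNPs per such probe, and the mean $r^2$.

## The synthetic-data generator

Every stage is exercised on synthetic cohorts with known planted structure;
the generator is first-class, tested code.

*Genotypes.* Haplotypes come from a per-block Gaussian copula with AR(1)
latent correlation (`ld_rho = 0.95`), thresholded at per-SNP allele
frequencies drawn from `maf_range = (0.05, 0.5)`; dosage correlation between
adjacent SNPs then exceeds $r^2 = 0.5$ in expectation (checked by Monte
Carlo against the generator's own copula), while blocks are independent.
This is the simplest model with a tunable adjacent-$r^2$; it makes no
attempt at realistic recombination maps or allele-frequency spectra. A
configurable fraction of SNPs is flagged imputed with simulated quality
metrics (worse metrics, noisier dosages), X SNPs are hemizygous in males,
and missingness is independent Bernoulli (`missing_rate = 0.01`, matching
call rates around 99%).

*Traits.* Each probe has a unit-variance liability: a planted genotype
effect contributing `target_r2` of variance (in the tissues its mask
names), covariate components with configured variance fractions (defaults
sum to 0.15), and Gaussian noise split into a cross-tissue shared part
(`tissue_cor = 0.3`; no desk-scale default can be calibrated to a real shared-subject
correlation, so it is an exposed parameter rather than a fixed constant) and
a tissue-specific part, plus a constant per-probe tissue offset
(`tissue_shift_sd = 1`) that separates tissues in clustering without
touching within-tissue variances or planted effect sizes. CpG values are a
logistic squash of the liability — bounded in [0,1] and bimodal at the
extremes across probes, as methylation arrays show — while mRNA values sit
directly on the log2 scale. The calibration contract (planted `target_r2`
recovered within ±0.05 at $n = 10{,}000$, averaged over 50 seeds) holds for
both kinds; the logistic squash for planted probes uses a moderate slope at
an intermediate operating point precisely so the squash does not erode the
planted variance fraction.

Planted SNPs are always genotyped (never imputed) and their allele
frequencies are drawn above `planted_maf_min = 0.25`: an effect planted at a
rare SNP that the minor-homozygote filter removes by design would measure
the QC policy, not the pipeline's power. Recovery is therefore judged at the
trait level, with a significant SNP counting as the planted locus when it is
in the planted SNP's LD block or in dosage LD $r^2 \ge 0.5$ with it — a
causal SNP legitimately drags its LD partners to the permutation floor, and
counting those as false positives would misread the method's intent.

*What the generator does not emulate:* bead-level array noise, bisulfite
chemistry, population structure and relatedness, realistic LD decay,
genomic clustering of CpGs into islands (island calling is exercised on
separate sequence fixtures with planted islands), and any dependence of
detection p-values on trait level. Passing tests therefore demonstrate the
correctness and calibration of the machinery under a clean additive model,
not robustness to those real-data complications.

## Numerical choices

- The per-trait scan is a single matrix product between the centered dosage
  matrix and the observed-plus-permuted trait matrix; with missing dosages
  the pairwise-complete statistics come from indicator-matrix algebra (a
  sparse missingness mask), so both paths are exact, not imputation-based.
  The two paths agree to $10^{-10}$ on shared SNPs in the suite.
- Correlations are clamped to $[-1, 1]$ before the t transform;
  $t = r\sqrt{(n-2)/(1-r^2)}$ with degenerate denominators floored at
  machine tiny, so a perfect fit yields $t = \infty$ and an empirical
  p-value at the floor rather than `NaN`.
- SNPs with zero dosage variance or fewer than 3 complete pairs are skipped
  with a recorded reason, never an exception.
- The exact HWE comparison "no more probable than observed" carries a
  $10^{-9}$ relative guard so analytically tied configurations (symmetric
  distributions) are never split by floating-point noise; allele labels are
  canonicalized first, making the test exactly symmetric.
- Rank-invariant normalization selects probes whose rank differs from the
  median pseudo-reference by at most 5% of the probe count, fits a scaling
  through the origin, and iterates to a stable set (scaling preserves
  ranks, so convergence is immediate; the loop caps at 10). The tolerance,
  cap and reference are configuration, since the upstream description
  leaves them open.
- Average-linkage clustering and Newick serialization are delegated to
  `hclust`/`ape`; the suite checks cophenetic equality against an
  independent $O(n^3)$ UPGMA implementation.
- Methylation-based sex inference avoids RNG entirely: two-centre
  assignment seeded at the samples with extreme mean X methylation, iterated
  to a fixed point, with the higher-methylation cluster labelled female
  (mosaic X inactivation). Genotypic sex cutoffs (X heterozygosity < 0.02
  male, > 0.20 female) are conventional defaults and configurable;
  no single pair of cutoffs suits every panel.
- All randomness flows from explicit seeds; per-stage and per-trait streams
  are derived by fixed arithmetic offsets, and seeded functions restore the
  caller's RNG state.

## Problem sizes in the test suite

The suite runs at desk scale, chosen as the smallest sizes at which each
property is meaningfully exercised: generator calibration at
$n = 10{,}000$ samples over 50 seeds; planted-effect recovery on
150 samples × 2,000 SNPs × 200 traits with 25 planted effects
(20 cis, 5 trans; `target_r2` 0.3–0.6) over 10 seeds at 200 permutations;
null calibration on 60 × 150 × 60 over 20 seeds; the exact HWE sweep over
every genotype table with $n \le 200$; island-caller equivalence on
50 random 5 kb sequences; and the analysis workflow on 150 samples ×
1,000 SNPs × 120 probes × 4 tissues. With 200 permutations the empirical-p
floor (0.004975) limits how small a significant trait fraction can be, which
the recovery settings account for by planting 25 of 200 traits.

## Known limitations

- `fwer2fdr`-style FDR is operationalized as BH on per-trait best empirical
  p-values; the historical implementation's internals are not reproducible,
  and other operationalizations could shift thresholds slightly.
- LD rescue uses genotype-dosage correlation, not haplotype $r^2$; the two
  differ away from Hardy–Weinberg equilibrium.
- The FDR is computed jointly per trait kind per tissue (not per
  chromosome); with very unbalanced chromosomes the thresholds would
  differ.
- Permutation p-values inherit maxT's conservatism for SNPs correlated with
  many others; no step-down refinement is applied.
- The island caller implements only the classical composition definition;
  stricter modern definitions (longer windows, higher GC) would call fewer,
  larger islands.
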