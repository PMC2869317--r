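# Positional annotation: cis/trans classification with signed distances, and
# CpG-island calling from sequence (length >= 200 bp, GC >= 50%,
# observed/expected CpG >= 0.6). Coordinates are 0-based half-open
# internally; N bases count toward window length but not toward GC or CpG.

#' Classify SNP-probe pairs as cis or trans
#'
#' A pair is cis iff SNP and probe share a chromosome and the distance from
#' the SNP to the probe anchor is at most `window` (inclusive, i.e. cis is
#' +/- 1 Mb at the default). For CpG probes the anchor is the CpG coordinate;
#' for mRNA probes the classification distance is to the transcript span
#' (zero inside the span), while the reported signed distance is relative to
#' the strand-corrected TSS (negative upstream).
#'
#' @param records QTL record data.frame with `snp_chr`, `snp_pos`, `kind`,
#'   `probe_chr`, `probe_start`, `probe_end`, `probe_strand`, `probe_tss`,
#'   `probe_anchor` columns (as produced by [scan_tissue()]).
#' @param window cis window in bp (default 1e6).
#' @return `records` with `cis_trans` (`"cis"`/`"trans"`) and `distance`
#'   (signed bp; see Details) columns added.
#' @export
classify_cis_trans <- function(records, window = 1e6) {
  if (any(is.na(records$snp_chr)) || any(is.na(records$probe_chr)))
    stop2("records contain unknown chromosomes")
  same <- records$snp_chr == records$probe_chr
  is_mrna <- records$kind == "mrna"
  # classification distance: anchor for CpG, span (0 inside) for mRNA
  span_dist <- pmax(records$probe_start - records$snp_pos,
                    records$snp_pos - (records$probe_end - 1L), 0L)
  class_dist <- ifelse(is_mrna, span_dist,
                       abs(records$snp_pos - records$probe_anchor))
  records$cis_trans <- ifelse(same & class_dist <= window, "cis", "trans")
  # reported signed distance: strand-corrected TSS offset for mRNA
  strand_sign <- ifelse(records$probe_strand == "-", -1L, 1L)
  signed <- ifelse(is_mrna,
                   (records$snp_pos - records$probe_tss) * strand_sign,
                   records$snp_pos - records$probe_anchor)
  records$distance <- ifelse(same, signed, NA_integer_)
  records$class_distance <- ifelse(same, class_dist, NA_integer_)
  records
}

# C, G and CpG counts per 200-bp window and for arbitrary intervals, from
# cumulative counts over the sequence.
seq_cum_counts <- function(seq1) {
  v <- strsplit(as.character(seq1), "")[[1]]
  isC <- v == "C"; isG <- v == "G"
  cpg_start <- isC & c(isG[-1], FALSE)
  # zero-padded cumulative counts: cum[k + 1] = count over positions 1..k
  list(cumC = c(0, cumsum(isC)), cumG = c(0, cumsum(isG)),
       cumCpG = c(0, cumsum(cpg_start)), len = length(v))
}

# Criteria test for intervals [start, end) (0-based) given cumulative counts.
island_criteria <- function(cc, start, end, min_len = 200, gc_min = 0.5,
                            obs_exp_min = 0.6) {
  L <- end - start
  nC <- cc$cumC[end + 1L] - cc$cumC[start + 1L]
  nG <- cc$cumG[end + 1L] - cc$cumG[start + 1L]
  # CpG dinucleotides fully inside [start, end) start (1-based) in
  # [start + 1, end - 1]
  nCpG <- cc$cumCpG[pmax(end, 1L)] - cc$cumCpG[start + 1L]
  gc <- (nC + nG) / L
  obs_exp <- ifelse(nC * nG > 0, nCpG * L / (nC * nG), 0)
  data.frame(start = start, end = end, length = L, gc_fraction = gc,
             obs_exp_cpg = obs_exp,
             pass = L >= min_len & gc >= gc_min & obs_exp >= obs_exp_min)
}

#' Call CpG islands in DNA sequence
#'
#' Scans every 200-bp window (step 1); windows with GC fraction >= `gc_min`
#' and observed/expected CpG ratio >= `obs_exp_min` (obs/exp =
#' `#CpG * L / (#C * #G)`) qualify. Overlapping or adjacent qualifying
#' windows are merged and each merged region is re-tested against the same
#' criteria; only merged regions that still pass are reported.
#'
#' @param sequences a [Biostrings::DNAStringSet] (or single DNAString /
#'   character) over \{A,C,G,T,N\}.
#' @param min_len minimum island length (default 200 bp, also the scan
#'   window size).
#' @param gc_min minimum GC fraction (default 0.5).
#' @param obs_exp_min minimum observed/expected CpG ratio (default 0.6).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `gc_fraction`, `obs_exp_cpg`.
#' @export
call_cpg_islands <- function(sequences, min_len = 200, gc_min = 0.5,
                             obs_exp_min = 0.6) {
  if (is.character(sequences) || inherits(sequences, "DNAString"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  out <- list()
  for (nm in names(sequences)) {
    cc <- seq_cum_counts(sequences[[nm]])
    L <- cc$len
    if (L < min_len) next
    starts <- 0:(L - min_len)
    wins <- island_criteria(cc, starts, starts + min_len,
                            min_len, gc_min, obs_exp_min)
    qual <- wins[wins$pass, , drop = FALSE]
    if (nrow(qual) == 0) next
    merged <- IRanges::reduce(IRanges::IRanges(start = qual$start + 1L,
                                               end = qual$end))
    mi <- island_criteria(cc, IRanges::start(merged) - 1L, IRanges::end(merged),
                          min_len, gc_min, obs_exp_min)
    mi <- mi[mi$pass, , drop = FALSE]
    if (nrow(mi) == 0) next
    out[[nm]] <- data.frame(chrom = nm, start = mi$start, end = mi$end,
                            gc_fraction = mi$gc_fraction,
                            obs_exp_cpg = mi$obs_exp_cpg,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gc_fraction = numeric(),
                      obs_exp_cpg = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate CpG probes with island membership
#'
#' Membership means the CpG coordinate falls within an island interval
#' (half-open: start inclusive, end exclusive). The summary reports the
#' fraction of probes in islands for (a) all supplied probes and (b) probes
#' with a significant methQTL, when significance information is given.
#'
#' @param cpg_probes data.frame with `probe`, `chr` and `anchor` (CpG
#'   coordinate, 0-based) columns.
#' @param islands island data.frame (`chrom`, `start`, `end`), as from
#'   [call_cpg_islands()].
#' @param significant_probes optional character vector of probes with a
#'   significant methQTL.
#' @return list with `membership` (data.frame probe, in_island) and
#'   `summary` (fraction_all, fraction_significant).
#' @export
annotate_island_membership <- function(cpg_probes, islands,
                                       significant_probes = NULL) {
  in_island <- rep(FALSE, nrow(cpg_probes))
  for (ch in unique(islands$chrom)) {
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    sel <- which(cpg_probes$chr == ch)
    for (i in sel) {
      pos <- cpg_probes$anchor[i]
      in_island[i] <- any(pos >= isl$start & pos < isl$end)
    }
  }
  membership <- data.frame(probe = cpg_probes$probe, in_island = in_island,
                           stringsAsFactors = FALSE)
  frac_sig <- NA_real_
  if (!is.null(significant_probes) && length(significant_probes) > 0)
    frac_sig <- mean(membership$in_island[membership$probe %in% significant_probes])
  list(membership = membership,
       summary = c(fraction_all = mean(in_island),
                   fraction_significant = frac_sig))
}
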