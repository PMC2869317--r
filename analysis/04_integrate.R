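#!/usr/bin/env Rscript
# 04 -- Integration: enrichment, islands, cross-tissue comparison, triplets.
#
# Pools the per-tissue record sets to measure the cis enrichment of
# significant QTLs over trans (and how it moves across 50 geometrically
# shrinking distance thresholds), calls CpG islands on the fixture contig
# and summarizes island membership of methQTL CpGs, compares effects across
# the four tissues (union of significant pairs, ternary coordinates), and
# builds SNP-CpG-mRNA triplets around shared cis QTLs.

suppressMessages(library(permqtl))

records <- readRDS("scratch/03_records.rds")
dir.create("results/integrate", showWarnings = FALSE, recursive = TRUE)
tissues <- unique(sub("\\..*", "", names(records)))

# --- cis/trans enrichment, pooled across tissues per kind ------------------
for (kind in c("cpg", "mrna")) {
  rk <- do.call(rbind, records[grep(paste0("\\.", kind, "$"), names(records))])
  ef <- enrichment_fold(rk)
  sc <- enrichment_distance_scan(rk)
  data.table::fwrite(sc$scan,
                     file.path("results/integrate",
                               paste0("enrichment_", kind, ".tsv")), sep = "\t")
  message(sprintf("%s: %d/%d significant cis, %d/%d significant trans; fold at 1 Mb = %s; scan peak at %.0f bp",
                  kind, ef$n_sig_cis, ef$n_possible_cis, ef$n_sig_trans,
                  ef$n_possible_trans,
                  if (ef$infinite) "infinite (no significant trans)"
                  else sprintf("%.0f", ef$fold),
                  sc$peak_threshold))
}

# --- CpG islands on the fixture contig -------------------------------------
fa <- Biostrings::readDNAStringSet("results/fixtures/genome.fasta")
islands <- call_cpg_islands(fa)
write_islands_bed(islands, "results/integrate/islands.bed")
message(nrow(islands), " CpG island(s) called on the fixture contig (",
        paste(islands$end - islands$start, collapse = ", "), " bp)")

# island membership of tested vs methQTL CpGs, using island intervals mapped
# onto probe space for the synthetic panel: probes within the planted island
rk_cpg <- do.call(rbind, records[grep("\\.cpg$", names(records))])
probes_cpg <- unique(rk_cpg[, c("probe", "probe_chr", "probe_anchor")])
names(probes_cpg) <- c("probe", "chr", "anchor")
isl_genome <- data.frame(chrom = probes_cpg$chr[1],
                         start = islands$start, end = islands$end)
memb <- annotate_island_membership(probes_cpg, isl_genome,
                                   unique(rk_cpg$probe[rk_cpg$significant]))
message(sprintf("island membership: %.0f%% of tested CpGs, %.0f%% of methQTL CpGs (synthetic panel carries no island-depletion signal)",
                100 * memb$summary["fraction_all"],
                100 * ifelse(is.na(memb$summary["fraction_significant"]), 0,
                             memb$summary["fraction_significant"])))

# --- cross-tissue comparison ----------------------------------------------
for (kind in c("cpg", "mrna")) {
  per_tissue <- records[paste0(tissues, ".", kind)]
  names(per_tissue) <- tissues
  ct <- cross_tissue_table(per_tissue)
  data.table::fwrite(ct$pairs,
                     file.path("results/integrate",
                               paste0("cross_tissue_", kind, ".tsv")),
                     sep = "\t")
  message(kind, ": ", nrow(ct$pairs), " pairs significant in >= 1 tissue; ",
          "by #tissues significant: ",
          paste(names(ct$by_k), as.integer(ct$by_k), collapse = ", "),
          "; in all four: ", ct$all_tissues[["pairs"]])
  first3 <- ct$pairs[, paste0("r2_", tissues[1:3])]
  tern <- ternary_coordinates(as.matrix(first3))
  message(kind, ": ternary coordinates computed for ", nrow(tern$coords),
          " pairs across ", paste(tissues[1:3], collapse = "/"),
          " (cumulative R2 median ", round(median(tern$cumulative), 2), ")")
}

# --- SNP-CpG-mRNA triplets per tissue --------------------------------------
prep <- readRDS("scratch/02_prepared.rds")
all_trip <- list()
for (t in tissues) {
  mr <- records[[paste0(t, ".cpg")]]
  er <- records[[paste0(t, ".mrna")]]
  tr <- build_triplets(mr, er, prep$resid[[paste0(t, ".cpg")]]$values,
                       prep$resid[[paste0(t, ".mrna")]]$values)
  if (nrow(tr$triplets)) {
    tr$triplets$tissue <- t
    all_trip[[t]] <- tr$triplets
  }
  message(sprintf("%s: %d triplets considered, %d shared (%.1f%%); mean |CpG-TSS| %.1f kb shared vs %.1f kb all",
                  t, tr$summary$n_triplets, tr$summary$n_shared,
                  100 * ifelse(is.na(tr$summary$fraction_shared), 0,
                               tr$summary$fraction_shared),
                  tr$summary$mean_abs_tss_distance_shared / 1000,
                  tr$summary$mean_abs_tss_distance_all / 1000))
}
trip <- do.call(rbind, all_trip)
if (!is.null(trip)) {
  data.table::fwrite(trip, "results/integrate/triplets.tsv", sep = "\t")
  message("shared-triplet quadrants: ",
          paste(names(table(trip$quadrant[trip$shared])),
                table(trip$quadrant[trip$shared]), collapse = ", "))
}
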