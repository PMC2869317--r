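# Interchange formats: TSV dosage matrices (SNP rows, sample columns), BED6
# probe annotations (0-based half-open), covariate/truth TSVs, FASTA, VCF
# dosage (DS field) input, Table S3/S4-style results TSVs. Genomic positions
# are 0-based internally and 1-based in human-facing TSV columns.

fwrite_tsv <- function(x, path) data.table::fwrite(x, path, sep = "\t",
                                                   quote = FALSE, na = "NA")

#' Write a genotype matrix to dosage + SNP annotation TSVs
#'
#' @param genotypes a `geno_matrix`.
#' @param dosage_path,snp_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genotypes <- function(genotypes, dosage_path, snp_path) {
  dt <- data.table::data.table(snp = colnames(genotypes$dosages),
                               t(genotypes$dosages))
  fwrite_tsv(dt, dosage_path)
  si <- genotypes$snp_info
  out <- data.frame(snp = si$snp, chr = si$chr, pos = si$pos + 1L,
                    block = si$block, imputed = si$imputed,
                    imputation_r2 = si$imputation_r2,
                    posterior_avg = si$posterior_avg)
  fwrite_tsv(out, snp_path)
  invisible(c(dosage_path, snp_path))
}

#' Read a genotype matrix from dosage + SNP annotation TSVs
#'
#' Validates that dosages lie in \[0,2\] (reporting the offending file line)
#' and that SNP IDs are unique.
#'
#' @param dosage_path TSV with a `snp` column then one column per sample.
#' @param snp_annotation_path TSV with `snp`, `chr`, `pos` (1-based) and
#'   optionally `block`, `imputed`, `imputation_r2`, `posterior_avg`.
#' @return a `geno_matrix` (without simulation ground truth).
#' @export
read_genotypes <- function(dosage_path, snp_annotation_path) {
  dt <- data.table::fread(dosage_path, sep = "\t")
  if (anyDuplicated(dt$snp))
    stop2("duplicate SNP ID(s) in ", dosage_path, ": ",
          paste(utils::head(dt$snp[duplicated(dt$snp)], 3), collapse = ", "))
  mat <- as.matrix(dt[, -1])
  bad <- which(!is.na(mat) & (mat < 0 | mat > 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop2("dosage outside [0,2] at line ", bad[1, 1] + 1L, " of ", dosage_path)
  dos <- t(mat)
  colnames(dos) <- dt$snp
  si <- as.data.frame(data.table::fread(snp_annotation_path, sep = "\t"))
  if (!all(c("snp", "chr", "pos") %in% names(si)))
    stop2("SNP annotation needs snp, chr, pos columns")
  si <- si[match(dt$snp, si$snp), , drop = FALSE]
  if (anyNA(si$snp)) stop2("SNP annotation missing for some dosage rows")
  si$pos <- as.integer(si$pos) - 1L
  if (is.null(si$block)) si$block <- NA_integer_
  if (is.null(si$imputed)) si$imputed <- FALSE
  if (is.null(si$imputation_r2)) si$imputation_r2 <- NA_real_
  if (is.null(si$posterior_avg)) si$posterior_avg <- NA_real_
  rownames(si) <- NULL
  structure(list(dosages = dos, snp_info = si, covariates = NULL,
                 truth_dosages = NULL, config_seed = NULL),
            class = "geno_matrix")
}

#' Read allele dosages from a VCF with a DS genotype field
#'
#' @param vcf_path uncompressed or gzipped VCF containing per-genotype `DS`
#'   (dosage) values.
#' @return a `geno_matrix` equivalent to the TSV path for the same content.
#' @export
read_vcf_dosages <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (all(is.na(ds))) stop2("no DS field in ", vcf_path)
  if (any(!is.na(ds) & (ds < 0 | ds > 2)))
    stop2("dosage outside [0,2] in ", vcf_path)
  ids <- v@fix[, "ID"]
  if (anyDuplicated(ids)) stop2("duplicate SNP ID(s) in ", vcf_path)
  rownames(ds) <- ids
  si <- data.frame(snp = ids, chr = v@fix[, "CHROM"],
                   pos = as.integer(v@fix[, "POS"]) - 1L,
                   block = NA_integer_, imputed = FALSE,
                   imputation_r2 = NA_real_, posterior_avg = NA_real_,
                   stringsAsFactors = FALSE)
  structure(list(dosages = t(ds), snp_info = si, covariates = NULL,
                 truth_dosages = NULL, config_seed = NULL),
            class = "geno_matrix")
}

probe_bed <- function(probes) {
  data.frame(chr = probes$chr, start = probes$start, end = probes$end,
             name = probes$probe, score = 0L, strand = probes$strand)
}

#' Write probe annotations as BED6
#' @param probes probe data.frame (`probe`, `chr`, `start`, `end`, `strand`).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_probe_bed <- function(probes, path) {
  data.table::fwrite(probe_bed(probes), path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_probe_bed <- function(path, kind) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chr", "start", "end", "name",
                                         "score", "strand"))
  tss <- if (kind == "mrna") ifelse(bed$strand == "-", bed$end, bed$start)
         else NA_integer_
  anchor <- if (kind == "mrna") tss else bed$start
  data.frame(probe = bed$name, kind = kind, chr = bed$chr,
             start = bed$start, end = bed$end, strand = bed$strand,
             tss = as.integer(tss), anchor = as.integer(anchor),
             stringsAsFactors = FALSE)
}

#' Write a trait matrix (values + detection p-values + BED annotation)
#'
#' @param traits a `trait_matrix`.
#' @param trait_path,detection_path,bed_path output paths.
#' @return invisibly, the three paths.
#' @export
write_traits <- function(traits, trait_path, detection_path, bed_path) {
  dtv <- data.table::data.table(probe = colnames(traits$values),
                                t(traits$values))
  fwrite_tsv(dtv, trait_path)
  dtd <- data.table::data.table(probe = colnames(traits$detection),
                                t(traits$detection))
  fwrite_tsv(dtd, detection_path)
  write_probe_bed(traits$probes, bed_path)
  invisible(c(trait_path, detection_path, bed_path))
}

#' Read a trait matrix
#'
#' @param trait_path,detection_path TSVs with a `probe` column then one
#'   column per sample.
#' @param probe_bed_path BED6 probe annotation; for mRNA the strand column
#'   drives the strand-corrected TSS.
#' @param kind `"cpg"` or `"mrna"`; CpG values are validated to lie in
#'   \[0,1\].
#' @param tissue optional tissue label.
#' @return a `trait_matrix`.
#' @export
read_traits <- function(trait_path, detection_path, probe_bed_path,
                        kind = c("cpg", "mrna"), tissue = NA_character_) {
  kind <- match.arg(kind)
  dtv <- data.table::fread(trait_path, sep = "\t")
  dtd <- data.table::fread(detection_path, sep = "\t")
  vals <- t(as.matrix(dtv[, -1])); colnames(vals) <- dtv$probe
  det <- t(as.matrix(dtd[, -1])); colnames(det) <- dtd$probe
  if (!identical(colnames(vals), colnames(det)))
    stop2("trait and detection probe sets differ")
  probes <- read_probe_bed(probe_bed_path, kind)
  unmatched <- setdiff(colnames(vals), probes$probe)
  if (length(unmatched))
    stop2("probe(s) missing from BED: ",
          paste(utils::head(unmatched, 5), collapse = ", "))
  probes <- probes[match(colnames(vals), probes$probe), , drop = FALSE]
  rownames(probes) <- NULL
  if (kind == "cpg" && any(!is.na(vals) & (vals < 0 | vals > 1)))
    stop2("CpG beta values outside [0,1] in ", trait_path)
  new_trait_matrix(vals, det, probes, kind, tissue)
}

#' Write per-sample covariates
#' @param covariates covariate data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_covariates <- function(covariates, path) {
  fwrite_tsv(covariates, path)
  invisible(path)
}

#' Read per-sample covariates
#' @param path covariate TSV with a `sample` column.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write called CpG islands as BED with a score column
#'
#' Score is the GC fraction scaled to 0-1000; the observed/expected ratio is
#' carried in a fifth column.
#' @param islands island data.frame from [call_cpg_islands()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_islands_bed <- function(islands, path) {
  out <- data.frame(chrom = islands$chrom, start = islands$start,
                    end = islands$end,
                    score = as.integer(round(1000 * islands$gc_fraction)),
                    obs_exp = round(islands$obs_exp_cpg, 4))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write QTL records in the supplementary-table column layout
#'
#' Columns mirror the significant-QTL supplementary tables: tissue, probe ID
#' and coordinates, SNP and coordinates, per-SNP HWE/MAF/call-rate (joined
#' from the QC report when given), fraction of samples used, signed distance
#' and cis/trans flag, asymptotic and empirical p-values, r2, beta and
#' genotype counts. Positions are 1-based in the file.
#'
#' @param records annotated, significance-called records.
#' @param path output path.
#' @param qc_report optional per-SNP QC report from [apply_snp_filters()].
#' @return invisibly, the path.
#' @export
write_results_tsv <- function(records, path, qc_report = NULL) {
  r <- records
  hwe <- maf <- cr <- rep(NA_real_, nrow(r))
  if (!is.null(qc_report)) {
    i <- match(r$snp, qc_report$snp)
    hwe <- qc_report$hwe_p[i]; maf <- qc_report$maf[i]
    cr <- qc_report$call_rate[i]
  }
  out <- data.frame(
    Tissue = r$tissue, IlmnID = r$probe, Kind = r$kind,
    Chr = r$probe_chr, Start_Pos = r$probe_start + 1L, Stop_Pos = r$probe_end,
    Strand = r$probe_strand, SNP = r$snp, SNP_Chr = r$snp_chr,
    SNP_Position = r$snp_pos + 1L, HWE = hwe, MAF = maf, SNP_Call_Rate = cr,
    Fraction_Samples_Used = r$fraction_samples_used,
    Dist_to_Trait = r$distance, cis_trans = r$cis_trans,
    pvalue = r$pvalue, empP = r$empP, r2 = r$r2, beta = r$beta,
    Num_AA = r$n_AA, Num_AB = r$n_AB, Num_BB = r$n_BB,
    significant = r$significant %||% NA, rescue = r$rescue %||% NA)
  fwrite_tsv(out, path)
  invisible(path)
}

#' Write the complete synthetic fixture set
#'
#' Serializes a simulated cohort to the interchange formats: dosage and SNP
#' TSVs, per-tissue trait/detection TSVs with BED6 probe annotations,
#' covariate and planted-truth TSVs, and a FASTA contig with an embedded
#' CpG island. Everything round-trips losslessly through the paired readers.
#'
#' @param genotypes a `geno_matrix` from [simulate_genotypes()].
#' @param sim result of [simulate_traits()].
#' @param config the [sim_config()] used.
#' @param directory output directory (created if absent).
#' @return named character vector of file paths.
#' @export
write_fixture_set <- function(genotypes, sim, config, directory) {
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE, showWarnings = FALSE))
      stop2("cannot create directory ", directory)
  fp <- function(...) file.path(directory, paste0(...))
  paths <- c(dosages = fp("dosages.tsv"), snps = fp("snps.tsv"),
             covariates = fp("covariates.tsv"), truth = fp("truth.tsv"),
             fasta = fp("genome.fasta"))
  write_genotypes(genotypes, paths[["dosages"]], paths[["snps"]])
  write_covariates(sim$covariates, paths[["covariates"]])
  fwrite_tsv(sim$truth, paths[["truth"]])
  for (t in names(sim$traits)) {
    for (kind in names(sim$traits[[t]])) {
      tm <- sim$traits[[t]][[kind]]
      tag <- paste0(t, "_", kind)
      p <- c(fp(tag, "_values.tsv"), fp(tag, "_detection.tsv"),
             fp(kind, "_probes.bed"))
      write_traits(tm, p[1], p[2], p[3])
      paths[paste0(tag, c("_values", "_detection"))] <- p[1:2]
      paths[paste0(kind, "_bed")] <- p[3]
    }
  }
  fa <- make_island_fasta(derive_seed(config$seed, 4L))
  Biostrings::writeXStringSet(fa, paths[["fasta"]])
  paths
}
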