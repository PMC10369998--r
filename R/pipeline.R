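# End-to-end drivers behind the `casekit` command-line entry point.

#' Run the cASE analysis from files to files
#'
#' Reads an allelic-count table, runs [run_case()] and writes
#' `reporter_results.tsv` (plus one `null_<reporter>.tsv` per reporter
#' when `save_null = TRUE`) into `out_dir`.  Fully deterministic given
#' `seed`: two invocations on the same inputs produce byte-identical
#' output files.
#'
#' @param counts_path Allelic-count TSV (see [read_allelic_counts()]).
#' @param out_dir Output directory (created if needed).
#' @param min_cov,n_perm,seed,alpha Passed to [run_case()].
#' @param save_null Also write each reporter's permutation draws.
#' @return The results `data.frame`, invisibly.
#' @export
case_pipeline <- function(counts_path, out_dir, min_cov = 10L,
                          n_perm = 1000L, seed = 1L, alpha = 0.05,
                          save_null = FALSE) {
  counts <- read_allelic_counts(counts_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_case(counts, min_cov = min_cov, n_perm = n_perm, seed = seed,
                  alpha = alpha)
  write_reporter_results(res, file.path(out_dir, "reporter_results.tsv"))
  if (save_null) {
    for (rid in sort(unique(counts$variant_id))) {
      grp <- counts[counts$variant_id == rid, , drop = FALSE]
      tab <- sample_z_table(grp, min_cov = min_cov)
      if (nrow(tab) == 0L) next
      null <- permutation_null(tab, n_perm = n_perm, seed = seed)
      con <- file(file.path(out_dir, paste0("null_", rid, ".tsv")), "wb")
      write.table(data.frame(z = sprintf("%.10g", null$z_values)), con,
                  sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
  }
  invisible(res)
}

#' Run the mediation assessment from files to a file
#'
#' Reads counts, genotypes (VCF) and TADs (BED), runs [run_mediation()]
#' for one reporter and writes the assessment table.
#'
#' @param counts_path,vcf_path,tads_path Input files.
#' @param reporter_id Reporter variant id.
#' @param out_path Output TSV.
#' @param min_cov,alpha,min_subgroup Passed to [run_mediation()].
#' @return The assessment `data.frame`, invisibly.
#' @export
mediation_pipeline <- function(counts_path, vcf_path, tads_path, reporter_id,
                               out_path, min_cov = 10L, alpha = 0.05,
                               min_subgroup = 3L) {
  counts <- read_allelic_counts(counts_path)
  geno <- read_genotypes_vcf(vcf_path)
  tads <- read_tads_bed(tads_path)
  res <- run_mediation(counts, geno$genotypes, geno$variants, tads,
                       reporter_id = reporter_id, min_cov = min_cov,
                       alpha = alpha, min_subgroup = min_subgroup)
  out <- res
  for (col in c("R_Z", "C_Z", "hom_Z")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.4f", out[[col]]))
  }
  for (col in c("hom_p", "ld_r2")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.6e", out[[col]]))
  }
  con <- open_write_con(out_path)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(res)
}
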