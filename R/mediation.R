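# Candidate-regulatory-variant assessment.
#
# Every variant sharing a TAD with the reporter is a candidate.  Samples
# heterozygous at the reporter are split by candidate genotype: the
# heterozygous-candidate subgroup should concentrate the allelic signal
# (its combined Z, C.Z, more extreme than the all-sample R.Z) while the
# homozygous-candidate subgroup — where both gene copies sit on the same
# regulatory background — should be quiet.  Both conditions together
# propose the candidate as a putative mediator of the cASE effect.

#' Candidate variants sharing a TAD with a reporter
#'
#' Membership uses the explicit coordinate conversion between 1-based
#' variant positions and 0-based half-open BED intervals: position `p`
#' is inside `(s, e]` iff `s < p <= e`.  When the reporter lies in
#' several (overlapping) TADs the candidate set is their union.  The
#' reporter itself is excluded.
#'
#' @param reporter One-row `data.frame` (or list) with `variant_id`,
#'   `chrom`, `pos` of the reporter.
#' @param variants Variant info `data.frame` (`variant_id`, `chrom`,
#'   `pos`).
#' @param tads TAD `data.frame` from [read_tads_bed()].
#' @return The subset of `variants` sharing at least one TAD with the
#'   reporter (empty, with a warning, when the reporter is in no TAD).
#' @export
variants_in_tad <- function(reporter, variants, tads) {
  if (nrow(tads) == 0L) {
    warning(sprintf("reporter '%s' lies in no TAD; no candidates",
                    reporter$variant_id))
    return(variants[0L, , drop = FALSE])
  }
  tad_gr <- GenomicRanges::GRanges(
    tads$chrom, IRanges::IRanges(start = tads$start + 1L, end = tads$end))
  rep_gr <- GenomicRanges::GRanges(
    reporter$chrom, IRanges::IRanges(start = reporter$pos, end = reporter$pos))
  rep_hits <- GenomicRanges::findOverlaps(rep_gr, tad_gr)
  if (length(rep_hits) == 0L) {
    warning(sprintf("reporter '%s' (%s:%d) lies in no TAD; no candidates",
                    reporter$variant_id, reporter$chrom, reporter$pos))
    return(variants[0L, , drop = FALSE])
  }
  home <- tad_gr[S4Vectors::subjectHits(rep_hits)]
  var_gr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(start = variants$pos, end = variants$pos))
  hits <- GenomicRanges::findOverlaps(var_gr, home)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- variants[keep, , drop = FALSE]
  out <- out[out$variant_id != reporter$variant_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split reporter samples by candidate genotype
#'
#' Heterozygous = dosage 1; homozygous pools dosage 0 and 2; samples
#' with a missing candidate genotype (or absent from the matrix) are
#' dropped from both subgroups, never imputed.
#'
#' @param records Allelic-count rows of one reporter.
#' @param genotypes A [genotype_matrix()].
#' @param candidate_id Candidate variant id (must be in the matrix).
#' @return A list: `het` and `hom` (subsets of `records`) and
#'   `dropped_samples` (character).
#' @export
split_by_candidate_genotype <- function(records, genotypes, candidate_id) {
  if (!(candidate_id %in% genotypes$variant_ids)) {
    stop_input("candidate '%s' is absent from the genotype matrix",
               candidate_id)
  }
  dos <- genotypes$dosage[, candidate_id]
  d <- dos[match(records$sample_id, genotypes$sample_ids)]
  het <- records[!is.na(d) & d == 1L, , drop = FALSE]
  hom <- records[!is.na(d) & d %in% c(0L, 2L), , drop = FALSE]
  dropped <- records$sample_id[is.na(d)]
  list(het = het, hom = hom, dropped_samples = dropped)
}

#' Assess one candidate against the reporter's cASE signal
#'
#' Decision rule: the candidate is proposed as a putative mediator iff
#' the heterozygous-candidate subgroup Z is strictly more extreme than
#' the all-sample reporter Z (`|C.Z| > |R.Z|`), the homozygous subgroup
#' is non-significant (`hom_p >= alpha`, two-sided standard-normal tail
#' of the subgroup Z, which has unit variance under the null by the
#' Stouffer construction), and both subgroups reach `min_subgroup`
#' samples.  `reason` records the first failing clause (`"ok"` when
#' proposed).
#'
#' @param het_records,hom_records Reporter count rows for the
#'   candidate-heterozygous / -homozygous subgroups (from
#'   [split_by_candidate_genotype()], already coverage-filtered).
#' @param R_Z Reporter combined Z over all samples.
#' @param alpha Significance level for the homozygous subgroup
#'   (default 0.05).
#' @param min_subgroup Minimum samples per subgroup (default 3; a
#'   one-sample Z is degenerate for the comparison).
#' @return One-row `data.frame`: `R_Z`, `C_Z`, `hom_Z`, `hom_p`,
#'   `n_het`, `n_hom`, `is_candidate`, `reason`.
#' @export
assess_candidate <- function(het_records, hom_records, R_Z, alpha = 0.05,
                             min_subgroup = 3L) {
  zstat <- function(rec) {
    if (nrow(rec) == 0L) return(NA_real_)
    tab <- sample_z_table(rec)
    if (nrow(tab) == 0L) return(NA_real_)
    combine_weighted_z(tab$z, tab$w)
  }
  C_Z <- zstat(het_records)
  hom_Z <- zstat(hom_records)
  hom_p <- if (is.na(hom_Z)) NA_real_ else 2 * pnorm(-abs(hom_Z))
  n_het <- nrow(het_records)
  n_hom <- nrow(hom_records)
  reason <-
    if (n_het == 0L) "no heterozygous carriers"
    else if (n_het < min_subgroup) "heterozygous subgroup below min_subgroup"
    else if (n_hom < min_subgroup) "homozygous subgroup below min_subgroup"
    else if (!(abs(C_Z) > abs(R_Z))) "subgroup Z not stronger than reporter Z"
    else if (!(hom_p >= alpha)) "homozygous subgroup significant"
    else "ok"
  data.frame(R_Z = R_Z, C_Z = C_Z, hom_Z = hom_Z, hom_p = hom_p,
             n_het = n_het, n_hom = n_hom,
             is_candidate = identical(reason, "ok"), reason = reason,
             stringsAsFactors = FALSE)
}

#' Dosage (composite) LD r-squared between two variants
#'
#' Squared Pearson correlation of genotype dosage vectors over
#' pairwise-complete samples; needs no phase and matches standard
#' tooling output.  Exactly symmetric in its arguments.
#'
#' @param geno_a,geno_b Numeric dosage vectors (0/1/2, `NA` = missing)
#'   of equal length.
#' @return A list: `r2` (in `[0, 1]`, `NA` with a warning when fewer
#'   than two complete pairs or either variant is monomorphic in the
#'   intersection) and `n` (pairwise-complete sample count).
#' @examples
#' ld_r2(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 1, 2, 2))
#' @export
ld_r2 <- function(geno_a, geno_b) {
  if (length(geno_a) != length(geno_b)) {
    stop_input("dosage vectors must have equal length")
  }
  ok <- !is.na(geno_a) & !is.na(geno_b)
  a <- geno_a[ok]; b <- geno_b[ok]
  n <- length(a)
  if (n < 2L) {
    warning("fewer than 2 pairwise-complete samples; LD undefined")
    return(list(r2 = NA_real_, n = n))
  }
  if (var(a) == 0 || var(b) == 0) {
    warning("monomorphic variant in the pairwise-complete set; LD undefined")
    return(list(r2 = NA_real_, n = n))
  }
  list(r2 = cor(a, b)^2, n = n)
}

#' Run the full candidate-mediation assessment for one reporter
#'
#' Computes the reporter's all-sample Z (after the coverage filter),
#' enumerates TAD-resident candidates, and applies [assess_candidate()]
#' to each, annotating dosage LD r-squared against the reporter.
#'
#' @param counts Allelic-count table (may cover several reporters).
#' @param genotypes A [genotype_matrix()].
#' @param variants Variant info `data.frame` (`variant_id`, `chrom`,
#'   `pos`, ...).
#' @param tads TAD `data.frame`.
#' @param reporter_id Reporter variant id.
#' @param min_cov Minimum reads per sample (default 10).
#' @param alpha,min_subgroup Passed to [assess_candidate()].
#' @return A `data.frame`, one row per candidate: `reporter_id`,
#'   `candidate_id`, `chrom`, `pos`, `R_Z`, `C_Z`, `hom_Z`, `hom_p`,
#'   `n_het`, `n_hom`, `ld_r2`, `is_candidate`, `reason`.
#' @examples
#' sim <- simulate_scenario("mediation", seed = 7)
#' run_mediation(sim$counts, sim$genotypes, sim$variants, sim$tads,
#'               reporter_id = "reporter")
#' @export
run_mediation <- function(counts, genotypes, variants, tads, reporter_id,
                          min_cov = 10L, alpha = 0.05, min_subgroup = 3L) {
  rep_row <- variants[variants$variant_id == reporter_id, , drop = FALSE]
  if (nrow(rep_row) != 1L) {
    stop_input("reporter '%s' is not (uniquely) in the variants table",
               reporter_id)
  }
  rec <- counts[counts$variant_id == reporter_id, , drop = FALSE]
  tab <- sample_z_table(rec, min_cov = min_cov)
  if (nrow(tab) == 0L) {
    stop_input("reporter '%s' has no sample passing the coverage filter",
               reporter_id)
  }
  # downstream subgroup statistics reuse the filtered sample set
  rec <- rec[rec$sample_id %in% tab$sample_id, , drop = FALSE]
  R_Z <- combine_weighted_z(tab$z, tab$w)
  cand <- variants_in_tad(rep_row, variants, tads)
  if (nrow(cand) == 0L) return(empty_mediation_frame())
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    cid <- cand$variant_id[i]
    grp <- split_by_candidate_genotype(rec, genotypes, cid)
    a <- assess_candidate(grp$het, grp$hom, R_Z, alpha = alpha,
                          min_subgroup = min_subgroup)
    ld <- suppressWarnings(
      ld_r2(genotypes$dosage[, reporter_id], genotypes$dosage[, cid]))
    cbind(data.frame(reporter_id = reporter_id, candidate_id = cid,
                     chrom = cand$chrom[i], pos = cand$pos[i],
                     stringsAsFactors = FALSE),
          a[, c("R_Z", "C_Z", "hom_Z", "hom_p", "n_het", "n_hom")],
          data.frame(ld_r2 = ld$r2, is_candidate = a$is_candidate,
                     reason = a$reason, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_mediation_frame <- function() {
  data.frame(reporter_id = character(0), candidate_id = character(0),
             chrom = character(0), pos = integer(0), R_Z = numeric(0),
             C_Z = numeric(0), hom_Z = numeric(0), hom_p = numeric(0),
             n_het = integer(0), n_hom = integer(0), ld_r2 = numeric(0),
             is_candidate = logical(0), reason = character(0),
             stringsAsFactors = FALSE)
}
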