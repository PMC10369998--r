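# Generative model used to test every downstream stage.
#
# Haplotypes: within an LD block, the first variant's allele is
# Bernoulli(MAF); each later variant copies the previous variant's
# allele with probability `copy_prob`, else is redrawn Bernoulli(MAF).
# For equal MAFs the haplotype correlation between adjacent variants is
# exactly the copy probability, so pairwise r^2 is directly
# controllable.  Genotypes are sums of two independent haplotypes
# (Hardy-Weinberg equilibrium).
#
# Counts: samples heterozygous at the reporter variant emit one record.
# Total coverage is negative-binomial (mean `coverage_mean`, variance
# mu + dispersion * mu^2), floored at 1 read.  The reference-read count
# is Binomial(n_i, p_i) with
#   p_i = theta      if the haplotype carrying the reporter's REFERENCE
#                    allele also carries the causal risk (ALT) allele,
#   p_i = 1 - theta  if it carries the causal non-risk allele while the
#                    other haplotype carries the risk allele,
#   p_i = 0.5        if the sample is homozygous at the causal variant.
# The skew rides on the haplotype: cis-regulation boosts (or dampens)
# only the gene copy physically linked to the risk allele.

#' Simulation configuration
#'
#' @param n_samples Number of diploid samples.
#' @param variants `data.frame` with columns `variant_id`, `maf`
#'   (minor/ALT allele frequency in (0, 0.5]), `ld_block_id`; optional
#'   `chrom`, `pos`, `ref`, `alt`, and `copy_prob` (per-variant copy
#'   probability from the previous variant of the same block, first
#'   variant ignored; defaults to `ld_copy_prob`).
#' @param reporter_variant_id,causal_variant_id Variant ids of the
#'   transcribed reporter and of the cis-regulatory causal variant (may
#'   coincide).
#' @param theta Reference-allele expression fraction in (0, 1) conferred
#'   when the haplotype bearing the reporter's reference allele carries
#'   the causal risk allele; 0.5 = no effect.
#' @param coverage_mean,coverage_dispersion Mean and overdispersion of
#'   the per-sample read depth (negative binomial,
#'   variance = mu + dispersion * mu^2).  Defaults 50 and 0.3.
#' @param ld_copy_prob Default copy probability in `[0, 1]` for
#'   adjacent variants within a block.
#' @param seed Integer seed; every generator op is deterministic given
#'   the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples, variants, reporter_variant_id,
                       causal_variant_id, theta = 0.5,
                       coverage_mean = 50, coverage_dispersion = 0.3,
                       ld_copy_prob = 0, seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(theta, "theta", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (theta >= 1) stop_input("'theta' must lie strictly inside (0, 1)")
  assert_scalar_number(coverage_mean, "coverage_mean", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(coverage_dispersion, "coverage_dispersion", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(ld_copy_prob, "ld_copy_prob", lower = 0, upper = 1)
  req <- c("variant_id", "maf", "ld_block_id")
  missing <- setdiff(req, names(variants))
  if (length(missing) > 0L) {
    stop_input("variants table is missing column '%s'", missing[1L])
  }
  if (any(variants$maf <= 0 | variants$maf > 0.5)) {
    stop_input("all MAFs must lie in (0, 0.5]")
  }
  if (anyDuplicated(variants$variant_id)) {
    stop_input("variant ids must be unique")
  }
  for (id in c(reporter_variant_id, causal_variant_id)) {
    if (!(id %in% variants$variant_id)) {
      stop_input("variant '%s' is not in the variants table", id)
    }
  }
  nv <- nrow(variants)
  if (is.null(variants$chrom)) variants$chrom <- "chr8"
  if (is.null(variants$pos)) variants$pos <- 118184001L + 2000L * (seq_len(nv) - 1L)
  if (is.null(variants$ref)) variants$ref <- rep_len(c("A", "C"), nv)
  if (is.null(variants$alt)) variants$alt <- rep_len(c("G", "T"), nv)
  if (is.null(variants$copy_prob)) variants$copy_prob <- ld_copy_prob
  variants$copy_prob[is.na(variants$copy_prob)] <- ld_copy_prob
  structure(list(n_samples = as.integer(n_samples), variants = variants,
                 reporter_variant_id = reporter_variant_id,
                 causal_variant_id = causal_variant_id, theta = theta,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 ld_copy_prob = ld_copy_prob, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate phased haplotypes under HWE with block LD
#'
#' See the generative model described in [sim_config()].  Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list: `genotypes` (phased [genotype_matrix()]) and `truth`
#'   (`data.frame` of `sample_id`, `true_ref_fraction` — the per-sample
#'   reference-allele expression fraction at the reporter, `NA` for
#'   samples not heterozygous at the reporter — plus the causal id as
#'   attribute `causal_variant_id`).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variants
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  draw_hap <- function() {
    h <- matrix(0L, nrow = n, ncol = nrow(v),
                dimnames = list(sample_ids, v$variant_id))
    for (block in split(seq_len(nrow(v)), v$ld_block_id)) {
      for (j in seq_along(block)) {
        col <- block[j]
        fresh <- rbinom(n, 1L, v$maf[col])
        if (j == 1L) {
          h[, col] <- fresh
        } else {
          copy <- rbinom(n, 1L, v$copy_prob[col]) == 1L
          h[, col] <- ifelse(copy, h[, block[j - 1L]], fresh)
        }
      }
    }
    h
  }
  with_seed(config$seed, {
    h1 <- draw_hap()
    h2 <- draw_hap()
  })
  gm <- genotype_matrix(h1 + h2, phased = TRUE,
                        haplotypes = list(h1 = h1, h2 = h2))
  truth <- data.frame(sample_id = sample_ids,
                      true_ref_fraction = true_ref_fraction(gm, config),
                      stringsAsFactors = FALSE)
  attr(truth, "causal_variant_id") <- config$causal_variant_id
  list(genotypes = gm, truth = truth)
}

# per-sample true reference fraction at the reporter (NA unless het there)
true_ref_fraction <- function(gm, config) {
  rep_id <- config$reporter_variant_id
  cau_id <- config$causal_variant_id
  h1r <- gm$haplotypes$h1[, rep_id]; h2r <- gm$haplotypes$h2[, rep_id]
  h1c <- gm$haplotypes$h1[, cau_id]; h2c <- gm$haplotypes$h2[, cau_id]
  out <- rep(NA_real_, length(h1r))
  het_rep <- h1r + h2r == 1L
  hom_cau <- h1c == h2c
  out[het_rep & hom_cau] <- 0.5
  # reporter REF allele (0) sits on h1 or h2; which causal allele rides along?
  risk_with_ref <- ifelse(h1r == 0L, h1c, h2c)
  het_cau <- h1c + h2c == 1L
  idx <- het_rep & het_cau
  out[idx] <- ifelse(risk_with_ref[idx] == 1L, config$theta, 1 - config$theta)
  out
}

#' Simulate allele-specific read counts
#'
#' Only samples heterozygous at the reporter emit a record; coverage is
#' overdispersed (negative binomial, floored at one read) and the
#' reference-read count is binomial with the phase-determined fraction
#' (see [sim_config()]).  Deterministic given the config
#' (`config$seed + 1` seeds this op so it is independent of the
#' haplotype stream).
#'
#' @param genotypes Phased [genotype_matrix()] from
#'   [simulate_haplotypes()].
#' @param config The same [sim_config()].
#' @return A list: `counts` (allelic-count `data.frame`, possibly empty
#'   with a warning when no sample is heterozygous at the reporter) and
#'   `truth` (as in [simulate_haplotypes()]).
#' @export
simulate_allelic_counts <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!genotypes$phased) stop_input("phased haplotypes are required")
  v <- config$variants
  rep_id <- config$reporter_variant_id
  if (!(rep_id %in% genotypes$variant_ids) ||
      !(config$causal_variant_id %in% genotypes$variant_ids)) {
    stop_input("reporter and causal variants must be present in the genotypes")
  }
  p_true <- true_ref_fraction(genotypes, config)
  emit <- !is.na(p_true)
  truth <- data.frame(sample_id = genotypes$sample_ids,
                      true_ref_fraction = p_true, stringsAsFactors = FALSE)
  attr(truth, "causal_variant_id") <- config$causal_variant_id
  vrow <- v[v$variant_id == rep_id, ]
  if (!any(emit)) {
    warning(sprintf("reporter '%s' has no heterozygous sample; empty count table",
                    rep_id))
    counts <- data.frame(sample_id = character(0), variant_id = character(0),
                         chrom = character(0), pos = integer(0),
                         ref_count = integer(0), alt_count = integer(0),
                         stringsAsFactors = FALSE)
    return(list(counts = counts, truth = truth))
  }
  k <- sum(emit)
  counts <- with_seed(config$seed + 1L, {
    size <- 1 / config$coverage_dispersion
    cov <- pmax(1L, rnbinom(k, size = size, mu = config$coverage_mean))
    ref <- rbinom(k, cov, p_true[emit])
    data.frame(sample_id = genotypes$sample_ids[emit],
               variant_id = rep_id, chrom = vrow$chrom, pos = vrow$pos,
               ref_count = as.integer(ref),
               alt_count = as.integer(cov - ref), stringsAsFactors = FALSE)
  })
  list(counts = counts, truth = truth)
}

#' Packaged synthetic scenarios
#'
#' Two ready-made study designs:
#'
#' * `"mediation"` (default): a reporter plus a causal regulatory
#'   variant in moderate LD (copy probability 0.7, r^2 about 0.5), two
#'   unlinked variants inside the same TAD, and one variant outside the
#'   TAD; 60 samples, `theta = 0.75`, coverage mean 50.  The TAD is the
#'   super-enhancer-scale interval chr8:118183060-118260108.
#' * `"tagging"`: a causal reporter plus a tag variant in near-perfect
#'   LD (r^2 about 0.96) and two weakly linked variants (r^2 about
#'   0.05), mirroring a GWAS-locus LD structure; `theta = 0.7`.
#'
#' @param scenario `"mediation"` or `"tagging"`.
#' @param n_samples,theta,coverage_mean,coverage_dispersion,maf,seed
#'   Overridable study conditions (defaults per scenario; `maf` 0.3).
#' @return A list with `config`, `genotypes`, `counts`, `variants`
#'   (variant info table), `tads`, `truth`.
#' @examples
#' sim <- simulate_scenario("mediation", seed = 7)
#' head(sim$counts)
#' @export
simulate_scenario <- function(scenario = c("mediation", "tagging"),
                              n_samples = NULL, theta = NULL,
                              coverage_mean = 50, coverage_dispersion = 0.3,
                              maf = 0.3, seed = 1L) {
  scenario <- match.arg(scenario)
  tad <- data.frame(chrom = "chr8", start = 118183060L, end = 118260108L,
                    stringsAsFactors = FALSE)
  if (scenario == "mediation") {
    n_samples <- n_samples %||% 60L
    theta <- theta %||% 0.75
    variants <- data.frame(
      variant_id = c("reporter", "causal", "unlinked1", "unlinked2", "outside"),
      maf = maf,
      ld_block_id = c(1L, 1L, 2L, 3L, 4L),
      copy_prob = c(NA, 0.7, NA, NA, NA),
      pos = c(118184001L, 118190001L, 118200001L, 118210001L, 118500001L),
      stringsAsFactors = FALSE)
    causal <- "causal"
  } else {
    n_samples <- n_samples %||% 60L
    theta <- theta %||% 0.7
    # chained copying: r decays multiplicatively along the block
    c_tag <- sqrt(0.96)
    c_weak_a <- sqrt(0.05)          # cand_a -- reporter
    c_weak_b <- sqrt(0.05) / c_tag  # tag -- cand_b, so r(reporter, cand_b)^2 = 0.05
    variants <- data.frame(
      variant_id = c("cand_a", "reporter", "tag", "cand_b"),
      maf = maf,
      ld_block_id = 1L,
      copy_prob = c(NA, c_weak_a, c_tag, c_weak_b),
      pos = c(118186001L, 118188001L, 118192001L, 118196001L),
      stringsAsFactors = FALSE)
    causal <- "reporter"
  }
  cfg <- sim_config(n_samples = n_samples, variants = variants,
                    reporter_variant_id = "reporter",
                    causal_variant_id = causal, theta = theta,
                    coverage_mean = coverage_mean,
                    coverage_dispersion = coverage_dispersion, seed = seed)
  hap <- simulate_haplotypes(cfg)
  cnt <- simulate_allelic_counts(hap$genotypes, cfg)
  list(config = cfg, genotypes = hap$genotypes, counts = cnt$counts,
       variants = cfg$variants[, c("variant_id", "chrom", "pos", "ref", "alt")],
       tads = tad, truth = cnt$truth)
}

#' Fast panel of single-reporter simulations with a flat effect
#'
#' Generates `n_reporters` independent reporters, each observed in
#' `n_samples` heterozygous samples whose true reference fraction is the
#' same `theta` (the fully linked causal case; `theta = 0.5` gives a
#' null panel).  This is the thin fast path used for calibration and
#' power studies, equivalent to the full generator conditioned on
#' reporter heterozygosity.
#'
#' @param n_reporters Number of reporters.
#' @param n_samples Heterozygous samples per reporter.
#' @param coverage_mean,coverage_dispersion Depth model as in
#'   [sim_config()].
#' @param theta Common true reference fraction.
#' @param seed Integer seed.
#' @return An allelic-count `data.frame` covering all reporters.
#' @export
simulate_reporter_panel <- function(n_reporters, n_samples,
                                    coverage_mean = 50,
                                    coverage_dispersion = 0.3,
                                    theta = 0.5, seed = 1L) {
  k <- n_reporters * n_samples
  with_seed(seed, {
    cov <- pmax(1L, rnbinom(k, size = 1 / coverage_dispersion,
                            mu = coverage_mean))
    ref <- rbinom(k, cov, theta)
  })
  data.frame(sample_id = rep(sprintf("S%03d", seq_len(n_samples)),
                             times = n_reporters),
             variant_id = rep(sprintf("rep%04d", seq_len(n_reporters)),
                              each = n_samples),
             chrom = "chr8",
             pos = rep(118184001L + 2000L * (seq_len(n_reporters) - 1L),
                       each = n_samples),
             ref_count = as.integer(ref),
             alt_count = as.integer(cov - ref),
             stringsAsFactors = FALSE)
}

#' Write a simulated scenario to disk
#'
#' Writes `counts.tsv`, `geno.vcf`, `tads.bed` and `truth.tsv` into
#' `out_dir` using the package writers; deterministic given the
#' scenario.
#'
#' @param sim Result of [simulate_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scenario <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_allelic_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  write_genotypes_vcf(sim$genotypes, sim$variants,
                      file.path(out_dir, "geno.vcf"))
  write_tads_bed(sim$tads, file.path(out_dir, "tads.bed"))
  con <- file(file.path(out_dir, "truth.tsv"), "wb")
  write.table(sim$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(out_dir)
}
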