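# Independent oracles, deliberately written without reusing any package
# internals: binomial tails by pmf enumeration, the weighted Stouffer
# combination by plain loop arithmetic, Pearson r^2 by the raw-sums
# formula.

# two-sided exact binomial p vs 0.5 by enumerating the pmf:
# P(|X - n/2| >= |x - n/2|), X ~ Binomial(n, 0.5)
oracle_binom_two_sided <- function(x, n) {
  k <- 0:n
  pmf <- choose(n, k) / 2^n
  sum(pmf[abs(k - n / 2) >= abs(x - n / 2)])
}

# signed probit deviate from the enumerated p (qnorm as probit table;
# upper-tail form keeps precision when p is tiny)
oracle_signed_z <- function(ref, alt) {
  p <- oracle_binom_two_sided(ref, ref + alt)
  s <- if (ref > alt) 1 else if (ref < alt) -1 else 0
  s * qnorm(p / 2, lower.tail = FALSE)
}

# brute-force weighted Stouffer combination from raw counts
oracle_stouffer <- function(ref, alt) {
  num <- 0
  den <- 0
  for (i in seq_along(ref)) {
    n_i <- ref[i] + alt[i]
    z_i <- oracle_signed_z(ref[i], alt[i])
    num <- num + n_i * z_i
    den <- den + n_i^2
  }
  num / sqrt(den)
}

# Pearson r^2 from raw sums (hand formula, no cor())
oracle_pearson_r2 <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- (n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2)
  num^2 / den
}

# random allelic-count table for one reporter
random_records <- function(n_samples, max_cov = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- sample(1:max_cov, n_samples, replace = TRUE)
  ref <- rbinom(n_samples, cov, runif(n_samples, 0.2, 0.8))
  data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
             variant_id = "rep0001", chrom = "chr8", pos = 118184001L,
             ref_count = as.integer(ref), alt_count = as.integer(cov - ref),
             stringsAsFactors = FALSE)
}

# swap the two allele columns of a count table
swap_alleles <- function(records) {
  tmp <- records$ref_count
  records$ref_count <- records$alt_count
  records$alt_count <- tmp
  records
}

# minimal VCF writer for hand-built parser fixtures
write_vcf_text <- function(path, sample_ids, rows,
                           format_col = rep("GT", length(rows))) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}
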