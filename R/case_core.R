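# The cASE statistic.
#
# Per heterozygous sample i with ref_i + alt_i = n_i reads, the exact
# two-sided binomial p-value against a balanced 0.5 reference fraction is
#   p_i = P(|X - n_i/2| >= |ref_i - n_i/2|),  X ~ Binomial(n_i, 0.5),
# converted to a signed probit deviate
#   z_i = sign(ref_i - alt_i) * qnorm(1 - p_i/2)
# (positive = reference-allele excess).  Deviates are combined with the
# read coverage as weight via the weighted Stouffer rule
#   Z = sum(w_i z_i) / sqrt(sum(w_i^2)),  w_i = n_i,
# which has unit variance under the null of independent N(0,1) deviates.
# Significance is assessed against a sign-flip permutation null: each
# draw flips, independently per sample with probability 1/2, the
# (ref, alt) assignment of that sample's counts and recombines.

Z_CAP <- 38  # |qnorm| at the smallest positive double; keeps z finite

#' Per-sample exact binomial significance and signed deviate
#'
#' Exact two-sided binomial test of the reference-read count against a
#' balanced 0.5 fraction, plus the signed standard-normal (probit)
#' deviate used by the weighted combination.  Vectorised over samples.
#'
#' @param ref_count,alt_count Non-negative integer vectors of reads
#'   supporting the reference / alternative allele.
#' @return A `data.frame` with columns `n` (total coverage), `p` (exact
#'   two-sided p-value in (0, 1]), `z` (signed deviate, capped at
#'   `c(-38, 38)`, carrying the sign of `ref_count - alt_count`).  `z`
#'   is zero exactly when `p` is 1: at balanced counts, and also at the
#'   minimal imbalance under odd coverage, where the exact two-sided
#'   tail covers the whole support.  Zero-coverage entries get `NA` p
#'   and z; batch callers skip them.
#' @examples
#' binomial_signed_z(9, 1)   # p = 22/1024, z ~ +2.30
#' binomial_signed_z(10, 10) # p = 1, z = 0
#' @export
binomial_signed_z <- function(ref_count, alt_count) {
  if (length(ref_count) != length(alt_count)) {
    stop_input("ref_count and alt_count must have equal length")
  }
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    stop_input("read counts must be non-negative")
  }
  n <- ref_count + alt_count
  k <- pmax(ref_count, alt_count)
  # for p = 0.5 the pmf is symmetric: two-sided tail = 2 * P(X >= max side);
  # at the minimal imbalance under odd coverage P(X >= (n+1)/2) = 1/2
  # exactly by symmetry, so the tie is snapped to p = 1 rather than left
  # one ulp short of it
  p <- ifelse(ref_count == alt_count | (n %% 2L == 1L & 2L * k == n + 1L), 1,
              pmin(1, 2 * pbinom(k - 1, n, 0.5, lower.tail = FALSE)))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1] under underflow
  z <- sign(ref_count - alt_count) * qnorm(p / 2, lower.tail = FALSE)
  z <- pmin(pmax(z, -Z_CAP), Z_CAP)
  zero <- n == 0L
  p[zero] <- NA_real_
  z[zero] <- NA_real_
  data.frame(n = n, p = p, z = z)
}

#' Coverage-weighted Stouffer combination
#'
#' `Z = sum(w * z) / sqrt(sum(w^2))`: the weighted Stouffer rule, which
#' preserves unit variance under the null when the `z` are independent
#' standard normal.  Order-invariant.
#'
#' @param z Signed per-sample deviates.
#' @param w Positive weights (the per-sample read coverage).
#' @return The combined Z (scalar).
#' @examples
#' combine_weighted_z(2, 5)                 # single sample: Z = z
#' combine_weighted_z(c(2, -2), c(10, 10))  # antisymmetric cancellation
#' @export
combine_weighted_z <- function(z, w = rep(1, length(z))) {
  if (length(z) == 0L) stop_input("cannot combine an empty set of deviates")
  if (length(w) != length(z)) stop_input("z and w must have equal length")
  if (any(!is.finite(z)) || any(!is.finite(w)) || any(w <= 0)) {
    stop_input("deviates must be finite and weights finite positive")
  }
  sum(w * z) / sqrt(sum(w^2))
}

# per-reporter sample table: one row per usable sample, sorted by
# sample_id so the permutation stream is invariant to input row order
sample_z_table <- function(records, min_cov = 0L) {
  ord <- order(records$sample_id)
  records <- records[ord, , drop = FALSE]
  sz <- binomial_signed_z(records$ref_count, records$alt_count)
  keep <- sz$n >= max(1L, min_cov)
  data.frame(sample_id = records$sample_id[keep],
             ref_count = records$ref_count[keep],
             alt_count = records$alt_count[keep],
             n = sz$n[keep], p = sz$p[keep], z = sz$z[keep],
             w = as.numeric(sz$n[keep]),
             stringsAsFactors = FALSE)
}

#' Sign-flip permutation null for one reporter
#'
#' Each permutation flips, independently per heterozygous sample with
#' probability 1/2, the (ref, alt) assignment of that sample's counts
#' (magnitudes preserved) and recomputes the combined weighted Z.
#' Because the two-sided binomial p is invariant under the swap and the
#' signed deviate is exactly negated, the flip is applied directly to
#' `z_i`.  Note that reassigning intact (ref, alt) pairs across
#' individuals would leave the weighted Stouffer Z unchanged (every
#' `z_i` keeps its own `w_i`), so it cannot form a null; the per-sample
#' allele-label flip is the shuffle that does.
#'
#' Samples are processed in sorted `sample_id` order, so the null is
#' invariant to the row order of `records` for a given seed.
#'
#' @param records Allelic-count rows for a single reporter variant
#'   (columns `sample_id`, `ref_count`, `alt_count`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @param min_cov Minimum per-sample coverage; lower-coverage samples are
#'   excluded (as in [run_case()]).
#' @return An object of class `permutation_null`: list with `z_values`
#'   (length `n_perm`), `n_perm`, `seed`.
#' @export
permutation_null <- function(records, n_perm = 1000L, seed = NULL,
                             min_cov = 0L) {
  if (nrow(records) < 1L) stop_input("permutation null needs >= 1 record")
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  tab <- sample_z_table(records, min_cov = min_cov)
  if (nrow(tab) == 0L) stop_input("no sample passes the coverage filter")
  wz <- tab$w * tab$z
  denom <- sqrt(sum(tab$w^2))
  z_values <- with_seed(seed, {
    flips <- matrix(rbinom(n_perm * nrow(tab), 1L, 0.5), nrow = n_perm)
    as.numeric((1 - 2 * flips) %*% wz) / denom
  })
  structure(list(z_values = z_values, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: %d draws, mean %.3f, sd %.3f\n",
              x$n_perm, mean(x$z_values), sd(x$z_values)))
  invisible(x)
}

#' Empirical (add-one) two-sided permutation p-value
#'
#' `p = (1 + #\{|Z_k| >= |Z_obs|\}) / (1 + n_perm)`; floored at
#' `1/(n_perm + 1)`.
#'
#' @param Z_obs Observed combined Z.
#' @param null A [permutation_null()] object.
#' @return The empirical p-value.
#' @export
empirical_p <- function(Z_obs, null) {
  stopifnot(inherits(null, "permutation_null"))
  (1 + sum(abs(null$z_values) >= abs(Z_obs))) / (1 + null$n_perm)
}

#' Gaussian-tail p-value from a fitted permutation null
#'
#' Fits mean and standard deviation to the permutation draws and returns
#' the two-sided normal tail `2 * (1 - pnorm(|Z_obs - mu| / sigma))`.
#' This parametric tail resolves significance far below the
#' `1/(n_perm + 1)` floor of the empirical estimate; both are reported
#' by [run_case()].
#'
#' @inheritParams empirical_p
#' @return The tail p-value.
#' @export
tail_p <- function(Z_obs, null) {
  stopifnot(inherits(null, "permutation_null"))
  if (null$n_perm < 30L) {
    stop_input("tail_p needs >= 30 permutation draws for a stable fit")
  }
  mu <- mean(null$z_values)
  sigma <- sd(null$z_values)
  if (sigma == 0) stop_input("degenerate permutation null (zero variance)")
  2 * pnorm(abs(Z_obs - mu) / sigma, lower.tail = FALSE)
}

#' Run the combined allele-specific expression analysis
#'
#' For every reporter variant in `records`: drop samples below the
#' coverage floor, combine the per-sample signed binomial deviates into
#' the coverage-weighted Z, build the sign-flip permutation null, and
#' report the empirical and Gaussian-tail p-values plus the bias
#' direction.  Gaussian-tail p-values are Benjamini-Hochberg adjusted
#' across reporters into `q_value`; results are sorted by `p_tail`.
#'
#' Reporters with no sample surviving the filter are kept (not dropped),
#' with `direction = "none"`, both p-values 1 and `low_coverage = TRUE`.
#'
#' @param records Allelic-count table ([read_allelic_counts()] layout),
#'   possibly covering many reporters.
#' @param min_cov Minimum reads per sample (default 10).
#' @param n_perm Permutations per reporter (default 1000).
#' @param seed Integer seed for the permutation stream.  Reporters are
#'   processed in sorted `variant_id` order and samples in sorted
#'   `sample_id` order, so results are invariant to input row order.
#' @param alpha Significance level used for the `significant` flag
#'   (`q_value < alpha`).
#' @return A `data.frame` with one row per reporter: `variant_id`,
#'   `n_samples`, `Z`, `p_perm`, `p_tail`, `direction` (`ref-biased`,
#'   `alt-biased` or `none`), `q_value`, `significant`, `low_coverage`.
#' @examples
#' sim <- simulate_scenario("tagging", n_samples = 30, seed = 1)
#' res <- run_case(sim$counts, n_perm = 200, seed = 1)
#' res[, c("variant_id", "n_samples", "Z", "p_perm", "direction")]
#' @export
run_case <- function(records, min_cov = 10L, n_perm = 1000L, seed = 1L,
                     alpha = 0.05) {
  missing <- setdiff(c("sample_id", "variant_id", "ref_count", "alt_count"),
                     names(records))
  if (length(missing) > 0L) {
    stop_input("records are missing required column '%s'", missing[1L])
  }
  reporters <- sort(unique(records$variant_id))
  rows <- vector("list", length(reporters))
  groups <- split(records, records$variant_id)
  with_seed(seed, {
    for (i in seq_along(reporters)) {
      rid <- reporters[i]
      grp <- groups[[rid]]
      tab <- sample_z_table(grp, min_cov = min_cov)
      if (nrow(tab) == 0L) {
        rows[[i]] <- data.frame(variant_id = rid, n_samples = 0L,
                                Z = NA_real_, p_perm = 1, p_tail = 1,
                                direction = "none", low_coverage = TRUE,
                                stringsAsFactors = FALSE)
        next
      }
      Z <- combine_weighted_z(tab$z, tab$w)
      null <- permutation_null(tab, n_perm = n_perm, seed = NULL)
      p_perm <- empirical_p(Z, null)
      # every per-sample deviate zero: no allelic information, the flip
      # null is degenerate at 0 and so is Z itself
      p_t <- if (sd(null$z_values) == 0) 1 else tail_p(Z, null)
      direction <- if (Z > 0) "ref-biased" else if (Z < 0) "alt-biased" else "none"
      rows[[i]] <- data.frame(variant_id = rid, n_samples = nrow(tab),
                              Z = Z, p_perm = p_perm, p_tail = p_t,
                              direction = direction, low_coverage = FALSE,
                              stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res$q_value <- p.adjust(res$p_tail, method = "BH")
  res$significant <- res$q_value < alpha
  res <- res[order(res$p_tail, res$variant_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("variant_id", "n_samples", "Z", "p_perm", "p_tail", "direction",
          "q_value", "significant", "low_coverage")]
}
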