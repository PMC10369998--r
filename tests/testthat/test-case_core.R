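test_that("exact binomial significance matches the enumerated pmf oracle", {
  # worked example: (9, 1) -> p = 22/1024, z ~ +2.30
  got <- binomial_signed_z(9, 1)
  expect_equal(got$p, 22 / 1024, tolerance = 1e-14)
  expect_equal(round(got$z, 2), 2.30)
  expect_equal(got$z, oracle_signed_z(9, 1), tolerance = 1e-12)

  # antisymmetric partner
  swp <- binomial_signed_z(1, 9)
  expect_identical(swp$p, got$p)
  expect_identical(swp$z, -got$z)

  # perfect balance
  bal <- binomial_signed_z(10, 10)
  expect_identical(bal$p, 1)
  expect_identical(bal$z, 0)

  # random grid vs oracle
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    x <- sample(0:n, 1)
    got <- binomial_signed_z(x, n - x)
    expect_equal(got$p, oracle_binom_two_sided(x, n), tolerance = 1e-12)
    expect_equal(got$z, oracle_signed_z(x, n - x), tolerance = 1e-10)
  }
})

test_that("binomial deviates stay finite, signed, and in-range", {
  # extreme counts: p underflows to the double floor, z stays finite
  # and within the +-38 cap
  ext <- binomial_signed_z(100000, 0)
  expect_true(is.finite(ext$z))
  expect_gte(ext$z, 37); expect_lte(ext$z, 38)
  expect_gt(ext$p, 0)

  set.seed(7)
  cov <- sample(1:100, 300, replace = TRUE)
  ref <- rbinom(300, cov, 0.5)
  got <- binomial_signed_z(ref, cov - ref)
  expect_true(all(got$p > 0 & got$p <= 1))
  # z is zero exactly when the two-sided p is 1 (balanced counts, and
  # the minimal imbalance at odd coverage whose exact p is also 1);
  # otherwise it carries the sign of the allele excess
  expect_true(all((got$z == 0) == (got$p == 1)))
  informative <- got$p < 1
  expect_identical(sign(got$z)[informative],
                   sign(ref - (cov - ref))[informative])
  expect_true(all(got$z[ref == cov - ref] == 0))

  # zero total coverage is an exclusion signal, not an exception
  zz <- binomial_signed_z(0, 0)
  expect_true(is.na(zz$p) && is.na(zz$z))
  expect_error(binomial_signed_z(-1, 3), "non-negative")
})

test_that("weighted Stouffer combination matches the brute-force oracle", {
  # single term: weights cancel
  expect_identical(combine_weighted_z(1.7, 23), 1.7)
  # antisymmetric cancellation at equal coverage
  expect_identical(combine_weighted_z(c(2, -2), c(10, 10)), 0)
  # worked pair (15,5) and (12,8)
  sz <- binomial_signed_z(c(15, 12), c(5, 8))
  expect_equal(combine_weighted_z(sz$z, sz$n),
               oracle_stouffer(c(15, 12), c(5, 8)), tolerance = 1e-12)
  # order invariance
  set.seed(5)
  z <- rnorm(9); w <- sample(10:50, 9)
  o <- sample(9)
  expect_equal(combine_weighted_z(z[o], w[o]), combine_weighted_z(z, w),
               tolerance = 1e-12)
  expect_error(combine_weighted_z(numeric(0)), "empty")
})

test_that("duplicating a sample is not the same as doubling its weight", {
  set.seed(31)
  z <- rnorm(6); w <- as.numeric(sample(10:40, 6))
  S <- sum(w * z); Q <- sum(w^2)
  j <- 3L
  Z_dup <- combine_weighted_z(c(z, z[j]), c(w, w[j]))
  w2 <- w; w2[j] <- 2 * w[j]
  Z_double <- combine_weighted_z(z, w2)
  # same numerator, different denominators: sqrt(Q + w^2) vs sqrt(Q + 3w^2)
  expect_equal(Z_dup, (S + w[j] * z[j]) / sqrt(Q + w[j]^2), tolerance = 1e-12)
  expect_equal(Z_double, (S + w[j] * z[j]) / sqrt(Q + 3 * w[j]^2),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(Z_dup, Z_double)))
})

test_that("sign-flip permutations behave as Bernoulli(1/2) label swaps", {
  # all balanced samples: every permuted Z is exactly zero
  rec <- data.frame(sample_id = c("a", "b"), ref_count = c(5L, 8L),
                    alt_count = c(5L, 8L))
  null <- permutation_null(rec, n_perm = 50, seed = 1)
  expect_identical(unique(null$z_values), 0)

  # single sample: draws live on {+z, -z} with near-even frequencies
  rec1 <- data.frame(sample_id = "a", ref_count = 9L, alt_count = 1L)
  z1 <- binomial_signed_z(9, 1)$z
  null1 <- permutation_null(rec1, n_perm = 1000, seed = 2)
  expect_true(all(abs(abs(null1$z_values) - abs(z1)) < 1e-12))
  n_pos <- sum(null1$z_values > 0)
  expect_gt(n_pos, 450); expect_lt(n_pos, 550)

  # determinism and invariance to input row order (same seed)
  rec <- random_records(12, seed = 3)
  a <- permutation_null(rec, n_perm = 100, seed = 7)
  b <- permutation_null(rec[sample(nrow(rec)), ], n_perm = 100, seed = 7)
  expect_identical(a$z_values, b$z_values)
})

test_that("empirical p is the add-one two-sided count", {
  null <- structure(list(z_values = c(-1, 0, 1, 2), n_perm = 4L, seed = NULL),
                    class = "permutation_null")
  expect_identical(empirical_p(1, null), 0.8)
  expect_identical(empirical_p(0, null), 1)       # every draw qualifies
  expect_identical(empirical_p(99, null), 1 / 5)  # estimator floor
  big <- permutation_null(random_records(10, seed = 4), n_perm = 1000, seed = 5)
  expect_identical(empirical_p(1e6, big), 1 / 1001)
})

test_that("the Gaussian tail fitted to the null is calibrated and affine-safe", {
  set.seed(11)
  draws <- rnorm(5000)
  draws <- (draws - mean(draws)) / sd(draws)  # exact sample moments 0/1
  null <- structure(list(z_values = draws, n_perm = 5000L, seed = NULL),
                    class = "permutation_null")
  expect_equal(tail_p(1.959964, null), 0.05, tolerance = 1e-6)
  expect_identical(tail_p(mean(draws), null), 1)

  scaled <- structure(list(z_values = 3.7 * draws, n_perm = 5000L, seed = NULL),
                      class = "permutation_null")
  expect_equal(tail_p(3.7 * 1.2, scaled), tail_p(1.2, null), tolerance = 1e-12)

  degenerate <- structure(list(z_values = rep(2, 100), n_perm = 100L,
                               seed = NULL), class = "permutation_null")
  expect_error(tail_p(1, degenerate), "degenerate")
  small <- structure(list(z_values = rnorm(10), n_perm = 10L, seed = NULL),
                     class = "permutation_null")
  expect_error(tail_p(1, small), "30")
})

test_that("run_case filters, flags, adjusts and orders reporters", {
  strong <- random_records(15, seed = 21)
  strong$ref_count <- strong$ref_count + 25L   # consistent reference excess
  weak <- random_records(8, seed = 22)
  weak$variant_id <- "rep0002"
  shallow <- data.frame(sample_id = c("S1", "S2"), variant_id = "rep0003",
                        chrom = "chr8", pos = 1L,
                        ref_count = c(2L, 3L), alt_count = c(1L, 4L))
  records <- rbind(strong, weak, shallow)
  res <- run_case(records, min_cov = 10, n_perm = 200, seed = 9)

  expect_identical(res$variant_id[1], "rep0001")   # sorted by p_tail
  expect_true(all(diff(res$p_tail) >= 0))
  expect_identical(res$q_value, p.adjust(res$p_tail, "BH"))

  low <- res[res$variant_id == "rep0003", ]
  expect_true(low$low_coverage)
  expect_identical(low$direction, "none")
  expect_identical(low$p_perm, 1)
  expect_identical(low$n_samples, 0L)

  top <- res[res$variant_id == "rep0001", ]
  expect_gt(top$Z, 0)  # reference allele preferentially transcribed
  expect_identical(top$direction, "ref-biased")
  expect_true(all(res$p_perm >= 1 / 201 & res$p_perm <= 1))

  # invariance to input row order
  res2 <- run_case(records[rev(seq_len(nrow(records))), ],
                   min_cov = 10, n_perm = 200, seed = 9)
  expect_identical(res, res2)
})

test_that("swapping alleles negates Z and preserves both p-values", {
  for (seed in 1:15) {
    rec <- random_records(sample(3:20, 1), seed = seed)
    res <- run_case(rec, min_cov = 1, n_perm = 100, seed = 50 + seed)
    res_swap <- run_case(swap_alleles(rec), min_cov = 1, n_perm = 100,
                         seed = 50 + seed)
    expect_identical(res_swap$Z, -res$Z)
    expect_identical(res_swap$p_perm, res$p_perm)
    expect_identical(res_swap$p_tail, res$p_tail)
    expect_identical(res_swap$q_value, res$q_value)
  }
})

test_that("a strong consistent effect is detected in essentially every run", {
  sig <- vapply(1:100, function(r) {
    cnt <- simulate_reporter_panel(1, 30, coverage_mean = 50, theta = 0.8,
                                   seed = 5000 + r)
    run_case(cnt, min_cov = 10, n_perm = 200, seed = 5000 + r)$q_value[1] < 0.05
  }, logical(1))
  expect_gte(sum(sig), 99)
})

test_that("the case pipeline writes byte-identical results across runs", {
  sim <- simulate_scenario("tagging", n_samples = 40, seed = 6)
  counts_path <- tempfile(fileext = ".tsv")
  write_allelic_counts(sim$counts, counts_path)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- case_pipeline(counts_path, d1, n_perm = 200, seed = 3,
                      save_null = TRUE)
  r2 <- case_pipeline(counts_path, d2, n_perm = 200, seed = 3,
                      save_null = TRUE)
  expect_identical(r1, r2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})
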