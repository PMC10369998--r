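test_that("allelic count tables round-trip exactly, including gzip", {
  df <- data.frame(sample_id = c("S1", "S2", "S3"),
                   variant_id = c("rs1", "rs1", "rs2"),
                   chrom = "chr8", pos = c(100L, 100L, 200L),
                   ref_count = c(12L, 0L, 7L), alt_count = c(8L, 30L, 7L),
                   stringsAsFactors = FALSE)
  for (ext in c(".tsv", ".tsv.gz")) {
    tf <- tempfile(fileext = ext)
    write_allelic_counts(df, tf)
    back <- read_allelic_counts(tf)
    expect_identical(back$sample_id, df$sample_id)
    expect_identical(back$ref_count, df$ref_count)
    expect_identical(back$alt_count, df$alt_count)
    expect_identical(back$pos, df$pos)
    expect_true(is.integer(back$ref_count))
  }
})

test_that("count table validation cites the offending column and row", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tvariant_id\tchrom\tpos\tref_count\talt_count",
               "S1\trs1\tchr8\t100\t5\t5",
               "S2\trs1\tchr8\t100\t-1\t5"), tf)
  expect_error(read_allelic_counts(tf), "ref_count.*row 2")

  writeLines(c("sample_id\tvariant_id\tchrom\tpos\tref_count\talt_count",
               "S1\trs1\tchr8\t100\t5.5\t5"), tf)
  expect_error(read_allelic_counts(tf), "non-integer.*row 1")

  writeLines(c("sample_id\tvariant_id\tchrom\tpos\tref_count",
               "S1\trs1\tchr8\t100\t5"), tf)
  expect_error(read_allelic_counts(tf), "alt_count")

  writeLines(c("sample_id\tvariant_id\tchrom\tpos\tref_count\talt_count",
               "S1\trs1\tchr8\t100\t5\t5",
               "S1\trs1\tchr8\t100\t6\t4"), tf)
  expect_error(read_allelic_counts(tf), "duplicated")
})

test_that("a header-only count file yields an empty table, not an error", {
  tf <- tempfile(fileext = ".tsv")
  writeLines("sample_id\tvariant_id\tchrom\tpos\tref_count\talt_count", tf)
  out <- read_allelic_counts(tf)
  expect_identical(nrow(out), 0L)
  expect_true(all(c("ref_count", "alt_count") %in% names(out)))
})

test_that("VCF GT codes map to dosages and the phased flag is conservative", {
  tf <- tempfile(fileext = ".vcf")
  write_vcf_text(tf, c("S1", "S2"),
                 "chr8\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1")
  got <- read_genotypes_vcf(tf)
  expect_identical(unname(got$genotypes$dosage[, "v1"]), c(1L, 2L))
  expect_true(got$genotypes$phased)
  expect_identical(got$variants$pos, 100L)

  # missing genotype and a 1/0 heterozygote
  write_vcf_text(tf, c("S1", "S2", "S3"),
                 "chr8\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t./.\t1/0\t0/0")
  got <- read_genotypes_vcf(tf)
  expect_identical(unname(got$genotypes$dosage[, "v1"]), c(NA, 1L, 0L))
  expect_false(got$genotypes$phased)

  # mixed separators across records -> unphased for the whole matrix
  write_vcf_text(tf, c("S1", "S2"),
                 c("chr8\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
                   "chr8\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0"))
  got <- read_genotypes_vcf(tf)
  expect_false(got$genotypes$phased)
})

test_that("multi-allelic sites are rejected by default and split on request", {
  tf <- tempfile(fileext = ".vcf")
  write_vcf_text(tf, c("S1", "S2"),
                 "chr8\t100\tv1\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/2")
  expect_error(read_genotypes_vcf(tf), "multi-allelic")
  got <- read_genotypes_vcf(tf, multiallelic = "split")
  expect_identical(unname(got$genotypes$dosage[, "v1:alt1"]), c(1L, 0L))
  expect_identical(unname(got$genotypes$dosage[, "v1:alt2"]), c(1L, 1L))
  expect_identical(got$variants$alt, c("G", "T"))
})

test_that("a region with no variants yields an empty matrix, not an error", {
  tf <- tempfile(fileext = ".vcf")
  write_vcf_text(tf, "S1", "chr8\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1")
  got <- read_genotypes_vcf(tf, region = "chr9:1-1000")
  expect_identical(length(got$genotypes$variant_ids), 0L)
  expect_identical(nrow(got$variants), 0L)
})

test_that("a VCF without GT in FORMAT is a format error", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr8\t100\tv1\tA\tG\t.\tPASS\t.\tDP\t10"), tf)
  expect_error(read_genotypes_vcf(tf), "GT")
})

test_that("simulated genotypes survive a VCF write/read round trip", {
  sim <- simulate_scenario("mediation", n_samples = 25, seed = 3)
  tf <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(sim$genotypes, sim$variants, tf)
  got <- read_genotypes_vcf(tf)
  expect_identical(got$genotypes$dosage[sim$genotypes$sample_ids,
                                        sim$genotypes$variant_ids],
                   sim$genotypes$dosage)
  expect_true(got$genotypes$phased)
  expect_identical(got$variants$variant_id, sim$variants$variant_id)
})

test_that("BED intervals parse, sort, and validate with line numbers", {
  tf <- tempfile(fileext = ".bed")
  writeLines(c("chr9\t500\t900",
               "chr8\t117000000\t118500000",
               "chr8\t100\t200"), tf)
  tads <- read_tads_bed(tf)
  expect_identical(tads$chrom, c("chr8", "chr8", "chr9"))
  expect_identical(tads$start, c(100L, 117000000L, 500L))
  expect_identical(tads$end, c(200L, 118500000L, 900L))

  writeLines(c("chr8\t100\t200", "chr8\t300\t250"), tf)
  expect_error(read_tads_bed(tf), "line 2")

  writeLines("chr8\t100", tf)
  expect_error(read_tads_bed(tf), "at least 3")

  # gzip + track line + round trip
  tg <- tempfile(fileext = ".bed.gz")
  tads <- data.frame(chrom = "chr8", start = 118183060L, end = 118260108L)
  write_tads_bed(tads, tg)
  expect_identical(read_tads_bed(tg), tads)
})

test_that("reporter results keep the Z sign convention through disk", {
  res <- data.frame(variant_id = c("rs75043555", "rs11558471"),
                    n_samples = c(12L, 15L), Z = c(-9.56, 19.30),
                    p_perm = c(9.99e-4, 9.99e-4),
                    p_tail = c(1.13e-4, 4.64e-14),
                    direction = c("alt-biased", "ref-biased"),
                    q_value = c(1.13e-4, 9.28e-14),
                    stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_reporter_results(res, tf)
  back <- read_reporter_results(tf)
  expect_equal(back$Z, res$Z, tolerance = 1e-9)
  expect_true(back$Z[back$variant_id == "rs75043555"] < 0)
  expect_equal(back$p_tail, res$p_tail, tolerance = 1e-6)
  expect_identical(back$direction, res$direction)

  # empty result set -> header-only file
  write_reporter_results(res[0, ], tf)
  expect_identical(nrow(read_reporter_results(tf)), 0L)
  expect_identical(length(readLines(tf)), 1L)

  # Z = 0 / p = 1 row parses back to equal values
  one <- data.frame(variant_id = "v", n_samples = 1L, Z = 0, p_perm = 1,
                    p_tail = 1, direction = "none", q_value = 1,
                    stringsAsFactors = FALSE)
  write_reporter_results(one, tf)
  back <- read_reporter_results(tf)
  expect_identical(back$Z, 0)
  expect_identical(back$p_perm, 1)
})
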