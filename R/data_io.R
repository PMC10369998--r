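# Readers/writers for the on-disk contracts consumed by the rest of the
# package.  Coordinate conventions: variant positions are 1-based (VCF);
# TAD intervals are 0-based half-open (BED).  A variant at position p lies
# inside interval (s, e] iff s < p <= e; the conversion is done explicitly
# wherever the two meet (see variants_in_tad()).

ALLELIC_COUNT_COLUMNS <- c("sample_id", "variant_id", "chrom", "pos",
                           "ref_count", "alt_count")

parse_strict_integer <- function(x, col) {
  x <- trimws(x)
  bad <- which(!grepl("^[+-]?[0-9]+$", x))
  if (length(bad) > 0L) {
    stop_input("column '%s': non-integer value '%s' on row %d",
               col, x[bad[1L]], bad[1L])
  }
  as.integer(x)
}

#' Read a table of allele-specific read counts
#'
#' The table is tab-separated with a header line carrying exactly the
#' columns `sample_id`, `variant_id`, `chrom`, `pos`, `ref_count`,
#' `alt_count` (extra columns are preserved).  One row is one
#' heterozygous-reporter observation: the number of RNA-seq reads
#' supporting the reference and the alternative allele of `variant_id`
#' in `sample_id`.  Gzip-compressed files are read transparently.
#'
#' @param path Path to a TSV (optionally `.gz`) file.
#' @return A `data.frame` with the six columns above; `pos`, `ref_count`
#'   and `alt_count` are integer, the rest character.  Rows keep file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(sample_id = "S1", variant_id = "rs1", chrom = "chr8",
#'                  pos = 118184001L, ref_count = 12L, alt_count = 8L)
#' write_allelic_counts(df, tf)
#' read_allelic_counts(tf)
#' @export
read_allelic_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(ALLELIC_COUNT_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop_input("allelic count table is missing required column '%s'",
               missing[1L])
  }
  df <- df[, union(ALLELIC_COUNT_COLUMNS, names(df)), drop = FALSE]
  if (nrow(df) == 0L) {
    df$pos <- integer(0); df$ref_count <- integer(0); df$alt_count <- integer(0)
    return(df)
  }
  df$pos <- parse_strict_integer(df$pos, "pos")
  df$ref_count <- parse_strict_integer(df$ref_count, "ref_count")
  df$alt_count <- parse_strict_integer(df$alt_count, "alt_count")
  for (col in c("ref_count", "alt_count")) {
    bad <- which(df[[col]] < 0L)
    if (length(bad) > 0L) {
      stop_input("column '%s': negative count (%d) on row %d",
                 col, df[[col]][bad[1L]], bad[1L])
    }
  }
  bad <- which(df$pos < 1L)
  if (length(bad) > 0L) {
    stop_input("column 'pos': position %d on row %d is not 1-based",
               df$pos[bad[1L]], bad[1L])
  }
  key <- paste(df$sample_id, df$variant_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_input("duplicated (sample_id, variant_id) pair ('%s', '%s') on row %d",
               df$sample_id[dup[1L]], df$variant_id[dup[1L]], dup[1L])
  }
  rownames(df) <- NULL
  df
}

#' Write a table of allele-specific read counts
#'
#' Inverse of [read_allelic_counts()]; a write/read round trip reproduces
#' every field exactly.
#'
#' @param counts A `data.frame` with the allelic-count columns.
#' @param path Output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_allelic_counts <- function(counts, path) {
  missing <- setdiff(ALLELIC_COUNT_COLUMNS, names(counts))
  if (length(missing) > 0L) {
    stop_input("allelic count table is missing required column '%s'",
               missing[1L])
  }
  con <- open_write_con(path)
  on.exit(close(con), add = TRUE)
  write.table(counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' Container for samples-by-variants genotype dosages (0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternative, `NA` =
#' missing), optionally with the two phased haplotypes whose allele sums
#' reproduce the dosages.
#'
#' @param dosage Integer matrix, samples in rows, variants in columns;
#'   both dimensions must be named.
#' @param phased Logical; `TRUE` iff haplotype phase is known for all
#'   genotypes.
#' @param haplotypes When `phased`, a list of two 0/1 matrices (`h1`,
#'   `h2`) with the same dimnames as `dosage`, each entry the alternative
#'   allele count on that haplotype.
#' @return An object of class `genotype_matrix` with elements
#'   `sample_ids`, `variant_ids`, `dosage`, `phased`, `haplotypes`.
#' @export
genotype_matrix <- function(dosage, phased = FALSE, haplotypes = NULL) {
  if (!is.matrix(dosage) || is.null(rownames(dosage)) ||
      (ncol(dosage) > 0L && is.null(colnames(dosage)))) {
    stop_input("'dosage' must be a matrix with sample rownames and variant colnames")
  }
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage))) {
    stop_input("dosage codes must be 0, 1, 2 or NA")
  }
  if (phased) {
    if (is.null(haplotypes) || !all(c("h1", "h2") %in% names(haplotypes))) {
      stop_input("phased genotypes require haplotypes$h1 and haplotypes$h2")
    }
    hsum <- haplotypes$h1 + haplotypes$h2
    same <- is.na(dosage) | (!is.na(hsum) & hsum == dosage)
    if (!all(same)) {
      stop_input("dosage must equal the haplotype allele sum where phased")
    }
  }
  structure(list(sample_ids = rownames(dosage),
                 variant_ids = colnames(dosage) %||% character(0),
                 dosage = dosage,
                 phased = isTRUE(phased),
                 haplotypes = haplotypes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              length(x$sample_ids), length(x$variant_ids),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

split_gt_alleles <- function(gt) {
  # returns list of character allele vectors; drops any trailing :FIELDS
  gt <- sub(":.*$", "", gt)
  strsplit(gt, "[/|]")
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file (plain or gzip) into a
#' [genotype_matrix()].  `0/1`, `1/0`, `0|1` and `1|0` all map to dosage
#' 1; `./.` maps to missing; the matrix is flagged phased only when every
#' non-missing genotype uses the `|` separator.  Multi-allelic sites are
#' rejected by default; `multiallelic = "split"` expands each alternative
#' allele into its own biallelic pseudo-variant (dosage = copies of that
#' allele).
#'
#' @param path VCF file path.
#' @param region Optional `"chrom:start-end"` filter (1-based, inclusive).
#' @param multiallelic `"error"` (default) or `"split"`.
#' @return A list with elements `genotypes` (a `genotype_matrix`) and
#'   `variants` (a `data.frame` of `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @export
read_genotypes_vcf <- function(path, region = NULL,
                               multiallelic = c("error", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(gt) || !("FORMAT" %in% colnames(gt)) ||
      nrow(gt) == 0L && nrow(fix) > 0L) {
    stop_input("VCF has no genotype (FORMAT/GT) section")
  }
  sample_ids <- setdiff(colnames(gt), "FORMAT")
  if (nrow(fix) == 0L) {
    dos <- matrix(NA_integer_, nrow = length(sample_ids), ncol = 0L,
                  dimnames = list(sample_ids, character(0)))
    return(list(genotypes = genotype_matrix(dos),
                variants = data.frame(variant_id = character(0),
                                      chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0),
                                      stringsAsFactors = FALSE)))
  }
  has_gt <- vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1L))
  if (!all(has_gt)) stop_input("VCF record without GT in FORMAT")
  gt_index <- vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
                     function(f) match("GT", f), integer(1L))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L) stop_input("region must be 'chrom:start-end'")
    keep <- chrom == m[2L] & pos >= as.integer(m[3L]) & pos <= as.integer(m[4L])
  }
  if (!any(keep)) {
    dos <- matrix(NA_integer_, nrow = length(sample_ids), ncol = 0L,
                  dimnames = list(sample_ids, character(0)))
    return(list(genotypes = genotype_matrix(dos),
                variants = data.frame(variant_id = character(0),
                                      chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0),
                                      stringsAsFactors = FALSE)))
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  gt_index <- gt_index[keep]
  chrom <- chrom[keep]; pos <- pos[keep]
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(chrom, ":", pos, "_", ref, "_", alt)[is.na(ids) | ids == "."]

  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "error") {
    stop_input(paste0("multi-allelic site '%s' (ALT = %s); allelic counts are ",
                      "biallelic by construction - use multiallelic = \"split\""),
               ids[which(multi)[1L]], alt[which(multi)[1L]])
  }

  n_var <- nrow(fix)
  dosage_cols <- list()
  var_rows <- list()
  phased_all <- TRUE
  for (i in seq_len(n_var)) {
    raw <- gt[i, sample_ids]
    fields <- strsplit(raw, ":", fixed = TRUE)
    gtstr <- vapply(fields, function(f) f[[gt_index[i]]], character(1L))
    nonmiss <- !(gtstr %in% c(".", "./.", ".|."))
    if (any(nonmiss) && !all(grepl("|", gtstr[nonmiss], fixed = TRUE))) {
      phased_all <- FALSE
    }
    alleles <- strsplit(gtstr, "[/|]")
    alts_i <- strsplit(alt[i], ",", fixed = TRUE)[[1L]]
    for (k in seq_along(alts_i)) {
      dos <- vapply(alleles, function(a) {
        if (any(a %in% c(".", ""))) return(NA_integer_)
        if (length(a) != 2L) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1L))
      vid <- if (length(alts_i) == 1L) ids[i] else paste0(ids[i], ":alt", k)
      dosage_cols[[vid]] <- dos
      var_rows[[vid]] <- data.frame(variant_id = vid, chrom = chrom[i],
                                    pos = pos[i], ref = ref[i],
                                    alt = alts_i[k], stringsAsFactors = FALSE)
    }
  }
  dosage <- do.call(cbind, dosage_cols)
  rownames(dosage) <- sample_ids
  variants <- do.call(rbind, var_rows)
  rownames(variants) <- NULL
  gm <- genotype_matrix(dosage)
  gm$phased <- phased_all   # flag only; haplotype assignment is not inferred
  list(genotypes = gm, variants = variants)
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' Deterministic plain-text writer (no timestamps), so that identical
#' inputs give byte-identical files.  Phased matrices are written with
#' `|` separators from their haplotypes, unphased ones with `/`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param variants `data.frame` with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` covering all matrix variants.
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, variants, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- match(genotypes$variant_ids, variants$variant_id)
  if (anyNA(idx)) stop_input("variants table does not cover all matrix variants")
  variants <- variants[idx, , drop = FALSE]
  header <- c("##fileformat=VCFv4.2",
              "##source=casekit",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$sample_ids), collapse = "\t"))
  gt_strings <- function(j) {
    if (genotypes$phased) {
      h1 <- genotypes$haplotypes$h1[, j]
      h2 <- genotypes$haplotypes$h2[, j]
      out <- paste0(h1, "|", h2)
      out[is.na(h1) | is.na(h2)] <- ".|."
    } else {
      d <- genotypes$dosage[, j]
      out <- c("0/0", "0/1", "1/1")[d + 1L]
      out[is.na(d)] <- "./."
    }
    out
  }
  body <- vapply(seq_along(genotypes$variant_ids), function(j) {
    paste(c(variants$chrom[j], variants$pos[j], variants$variant_id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".", "GT",
            gt_strings(j)), collapse = "\t")
  }, character(1L))
  con <- open_write_con(path)
  on.exit(close(con), add = TRUE)
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read TAD intervals from a BED file
#'
#' BED3+ convention: 0-based half-open intervals.  `track`/`browser`/`#`
#' lines are skipped; intervals are returned sorted by (chrom, start);
#' overlapping intervals are permitted and preserved.
#'
#' @param path BED file path (plain or gzip).
#' @return A `data.frame` with columns `chrom` (character), `start`,
#'   `end` (integer, 0-based half-open).
#' @export
read_tads_bed <- function(path) {
  lines <- read_lines_any(path)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  out <- list()
  for (i in which(!skip)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(f) < 3L) {
      stop_input("BED line %d has %d field(s); at least 3 required", i, length(f))
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop_input("BED line %d: non-integer coordinates", i)
    }
    if (s >= e) {
      stop_input("BED line %d: start (%d) must be < end (%d)", i, s, e)
    }
    out[[length(out) + 1L]] <- data.frame(chrom = f[1L], start = s, end = e,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  tads <- do.call(rbind, out)
  tads <- tads[order(tads$chrom, tads$start, tads$end), , drop = FALSE]
  rownames(tads) <- NULL
  tads
}

#' Write TAD intervals as BED3
#'
#' @param tads `data.frame` with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tads_bed <- function(tads, path) {
  con <- open_write_con(path)
  on.exit(close(con), add = TRUE)
  writeLines(paste(tads$chrom, tads$start, tads$end, sep = "\t"), con)
  invisible(path)
}

#' Write per-reporter cASE results
#'
#' Fixed numeric formatting: Z to two decimals (sign preserved), p- and
#' q-values in scientific notation, so files are byte-stable across runs.
#'
#' @param results `data.frame` as returned by [run_case()].
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_reporter_results <- function(results, path) {
  fmt_num <- function(x, fmt) ifelse(is.na(x), "NA", sprintf(fmt, x))
  out <- data.frame(variant_id = results$variant_id,
                    n_samples = results$n_samples,
                    Z = fmt_num(results$Z, "%.2f"),
                    p_perm = fmt_num(results$p_perm, "%.6e"),
                    p_tail = fmt_num(results$p_tail, "%.6e"),
                    direction = results$direction,
                    q_value = fmt_num(results$q_value, "%.6e"),
                    stringsAsFactors = FALSE)
  con <- open_write_con(path)
  on.exit(close(con), add = TRUE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a per-reporter results table
#'
#' @param path Path written by [write_reporter_results()].
#' @return A `data.frame` with numeric `Z`, `p_perm`, `p_tail`, `q_value`.
#' @export
read_reporter_results <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE,
                   colClasses = c(variant_id = "character",
                                  direction = "character"))
  for (col in c("Z", "p_perm", "p_tail", "q_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$n_samples <- as.integer(df$n_samples)
  df
}
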