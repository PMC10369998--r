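# Position-weight-matrix relative scoring around a variant.
#
# A JASPAR position frequency matrix (PFM) is converted to log-odds
# against a uniform background with a pseudocount split by background
# (standard JASPAR/TFBS practice).  Columns are first rescaled to a
# common total of 100 observations, so scores depend only on the
# column-wise base proportions — multiplying all counts by a positive
# constant cannot change any score.  A window of motif length L scores
#   raw = sum_j log2(p[base_j, j] / bg[base_j])
# and the relative profile score rescales raw into [0, 1] by the
# column-wise worst/best sums:
#   relative = (raw - min_possible) / (max_possible - min_possible).
# A consensus window therefore scores exactly 1, an anti-consensus
# window exactly 0.  Differential binding between the two alleles of a
# variant is called by thresholding each allele's best score over all
# motif placements overlapping the variant, on both strands.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param counts 4 x L non-negative numeric matrix, rows A, C, G, T.
#' @param matrix_id Identifier string.
#' @param pseudocount Positive pseudocount, split across bases by the
#'   background distribution (default 0.8).
#' @param background Base background probabilities (default uniform).
#' @return An object of class `pwm`.
#' @export
pwm <- function(counts, matrix_id = "pwm", pseudocount = 0.8,
                background = rep(0.25, 4)) {
  if (!is.matrix(counts) || nrow(counts) != 4L || ncol(counts) < 1L) {
    stop_input("counts must be a 4 x L matrix (rows A, C, G, T)")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_input("counts must be finite and non-negative")
  }
  if (any(colSums(counts) <= 0)) {
    stop_input("every column must have a positive count sum")
  }
  assert_scalar_number(pseudocount, "pseudocount", lower = 0,
                       strict_lower = TRUE)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop_input("background must be 4 positive probabilities summing to 1")
  }
  rownames(counts) <- DNA_BASES
  structure(list(matrix_id = matrix_id, counts = counts,
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d columns, consensus %s\n", x$matrix_id,
              ncol(x$counts),
              paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Log-odds matrix of a PWM
#'
#' Counts are column-rescaled to a common total of 100 (so the score is
#' exactly invariant to multiplying all counts by a positive constant),
#' smoothed with the background-split pseudocount, and log-transformed:
#' `log2((scaled[b, j] + pseudocount * background[b]) /
#' ((100 + pseudocount) * background[b]))`.
#'
#' @param x A [pwm()].
#' @return 4 x L numeric log-odds matrix.
#' @export
pwm_log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  scaled <- sweep(x$counts, 2, colSums(x$counts), "/") * 100
  prob <- (scaled + x$pseudocount * x$background) / (100 + x$pseudocount)
  log2(prob / x$background)
}

#' Read a JASPAR-format PFM file
#'
#' Accepts both the bracketed JASPAR syntax (`A [ 3 5 2 ]`) and plain
#' whitespace-separated rows in A, C, G, T order; a `>` header line
#' carries the matrix id.  Only the first matrix of a multi-matrix file
#' is read.
#'
#' @param path PFM file path.
#' @param pseudocount,background Passed to [pwm()].
#' @return A [pwm()].
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8,
                            background = rep(0.25, 4)) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty PFM file")
  matrix_id <- "pfm"
  if (startsWith(lines[1L], ">")) {
    matrix_id <- strsplit(trimws(sub("^>", "", lines[1L])), "[[:space:]]+")[[1L]][1L]
    lines <- lines[-1L]
  }
  nxt <- which(startsWith(lines, ">"))
  if (length(nxt) > 0L) lines <- lines[seq_len(nxt[1L] - 1L)]
  if (length(lines) < 4L) {
    stop_input("PFM must have 4 base rows; found %d", length(lines))
  }
  lines <- lines[1:4]
  labelled <- grepl("^[ACGTacgt][[:space:]]*\\[", lines) |
    grepl("^[ACGTacgt][[:space:]]", lines)
  rows <- list()
  for (i in 1:4) {
    ln <- trimws(lines[i])
    if (labelled[i]) {
      base <- toupper(substr(ln, 1L, 1L))
      ln <- sub("^[ACGTacgt]", "", ln)
    } else {
      base <- DNA_BASES[i]
    }
    ln <- gsub("]", " ", gsub("[", " ", ln, fixed = TRUE), fixed = TRUE)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1L]]))
    if (length(vals) == 0L || any(is.na(vals))) {
      stop_input("PFM row %d ('%s') is not numeric", i, base)
    }
    if (base %in% names(rows)) stop_input("duplicated PFM row for base %s", base)
    rows[[base]] <- vals
  }
  missing <- setdiff(DNA_BASES, names(rows))
  if (length(missing) > 0L) {
    stop_input("PFM is missing the '%s' row", missing[1L])
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop_input("PFM row lengths differ (%s)", paste(lens, collapse = ", "))
  }
  counts <- do.call(rbind, rows[DNA_BASES])
  pwm(counts, matrix_id = matrix_id, pseudocount = pseudocount,
      background = background)
}

#' Write a PWM in JASPAR bracketed format
#'
#' @param x A [pwm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  con <- open_write_con(path)
  on.exit(close(con), add = TRUE)
  body <- vapply(DNA_BASES, function(b) {
    sprintf("%s [ %s ]", b, paste(format(x$counts[b, ], trim = TRUE),
                                  collapse = " "))
  }, character(1L))
  writeLines(c(paste0(">", x$matrix_id), body), con)
  invisible(path)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_dna <- function(seq, name) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1L]]
  bad <- setdiff(chars, DNA_BASES)
  if (length(bad) > 0L) {
    stop_input("'%s' contains non-ACGT character '%s' (ambiguity codes unsupported)",
               name, bad[1L])
  }
  seq
}

#' Relative profile score of a window under a PWM
#'
#' Rescales the log-odds sum of the window into `[0, 1]` by the
#' column-wise minimum/maximum achievable sums; 1 = consensus,
#' 0 = anti-consensus.  `strand = "-"` scores the reverse complement of
#' the window; `"best"` returns the larger of the two strands.
#'
#' @param x A [pwm()].
#' @param window DNA string of exactly the motif length.
#' @param strand `"+"`, `"-"` or `"best"`.
#' @return Relative score in `[0, 1]`.
#' @export
relative_score <- function(x, window, strand = c("best", "+", "-")) {
  stopifnot(inherits(x, "pwm"))
  strand <- match.arg(strand)
  window <- check_dna(window, "window")
  L <- ncol(x$counts)
  if (nchar(window) != L) {
    stop_input("window length %d does not match motif length %d",
               nchar(window), L)
  }
  if (strand == "best") {
    return(max(relative_score(x, window, "+"),
               relative_score(x, window, "-")))
  }
  if (strand == "-") window <- revcomp(window)
  lo <- pwm_log_odds(x)
  idx <- match(strsplit(window, "")[[1L]], DNA_BASES)
  raw <- sum(lo[cbind(idx, seq_len(L))])
  mx <- sum(apply(lo, 2, max))
  mn <- sum(apply(lo, 2, min))
  if (mx == mn) return(1)  # degenerate motif: every window is optimal
  (raw - mn) / (mx - mn)
}

#' Differential-binding call for the two alleles of a variant
#'
#' Scores every motif placement that overlaps the variant site, on both
#' strands, for the reference- and alternative-allele sequence windows,
#' and calls differential binding by thresholding each allele's best
#' relative score (threshold 0.80 by default).
#'
#' @param x A [pwm()].
#' @param seq_ref,seq_alt Equal-length DNA strings containing the
#'   variant (they must differ at >= 1 position) with enough flanking
#'   sequence for the motif to slide over it.
#' @param threshold Relative-score threshold in `[0, 1]`.
#' @return One-row `data.frame`: `matrix_id`, `best_ref`, `best_alt`,
#'   `n_windows`, `call` (one of `"both"`, `"ref_only"`, `"alt_only"`,
#'   `"neither"`).
#' @examples
#' m <- pwm(matrix(c(10, 0, 0, 0,  0, 10, 0, 0,  0, 0, 10, 0), nrow = 4),
#'          matrix_id = "toy")
#' scan_variant(m, "TTACGTT", "TTATGTT", threshold = 0.8)
#' @export
scan_variant <- function(x, seq_ref, seq_alt, threshold = 0.80) {
  stopifnot(inherits(x, "pwm"))
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  seq_ref <- check_dna(seq_ref, "seq_ref")
  seq_alt <- check_dna(seq_alt, "seq_alt")
  if (nchar(seq_ref) != nchar(seq_alt)) {
    stop_input("seq_ref and seq_alt must have equal length")
  }
  L <- ncol(x$counts)
  len <- nchar(seq_ref)
  if (len < L) {
    stop_input("sequence length %d is shorter than the motif (%d)", len, L)
  }
  ref_chars <- strsplit(seq_ref, "")[[1L]]
  alt_chars <- strsplit(seq_alt, "")[[1L]]
  diffs <- which(ref_chars != alt_chars)
  if (length(diffs) == 0L) {
    stop_input("seq_ref and seq_alt are identical; no variant to scan")
  }
  starts <- max(1L, min(diffs) - L + 1L):min(len - L + 1L, max(diffs))
  best <- function(seq) {
    max(vapply(starts, function(s) {
      relative_score(x, substr(seq, s, s + L - 1L), strand = "best")
    }, numeric(1L)))
  }
  best_ref <- best(seq_ref)
  best_alt <- best(seq_alt)
  hit_ref <- best_ref >= threshold
  hit_alt <- best_alt >= threshold
  call <- if (hit_ref && hit_alt) "both"
          else if (hit_ref) "ref_only"
          else if (hit_alt) "alt_only"
          else "neither"
  data.frame(matrix_id = x$matrix_id, best_ref = best_ref,
             best_alt = best_alt, n_windows = length(starts), call = call,
             stringsAsFactors = FALSE)
}
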