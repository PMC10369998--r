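# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL inherits the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# gzfile() transparently reads both plain and gzip-compressed files
read_lines_any <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

open_write_con <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "wb") else file(path, open = "wb")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("'%s' must be a single finite number", name)
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop_input("'%s' = %g is outside its allowed range", name, x)
  }
  invisible(x)
}
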