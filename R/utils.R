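#' @useDynLib REcountR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor median rbinom rmultinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Write `lines` (or a writer function) to `path` atomically: a tempfile in the
# destination directory is renamed into place, so failures never leave a
# partially written output.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path), ".tmp"))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file into place at '", path, "'")
  }
  invisible(path)
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Largest-remainder apportionment of `total` units to probabilities `p`.
# Deterministic: guarantees sum(result) == total with result_i within 1 of
# total * p_i. Ties in remainders are broken by index order.
apportion_counts <- function(p, total) {
  stopifnot(total >= 0, all(p >= 0))
  p <- p / sum(p)
  raw <- p * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Single-record Hamming distance on equal-length strings (internal helper).
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length")
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
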