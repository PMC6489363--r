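# Independent oracles and fixture builders. Everything here is deliberately
# naive (two-pass formulas, per-pair loops, 4-line text writers) so the tests
# check the package against code that shares none of its implementation.

oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

oracle_min_pairwise <- function(seqs) {
  k <- length(seqs)
  best <- Inf
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      best <- min(best, oracle_hamming(seqs[i], seqs[j]))
    }
  }
  best
}

# Brute-force read assignment: full scan, explicit tie detection.
oracle_assign <- function(read, ref, max_mismatches) {
  if (nchar(read) < ref$barcode_length) {
    return(list(status = "unassigned_short", barcode_name = NA_character_))
  }
  pre <- substr(toupper(read), 1, ref$barcode_length)
  d <- vapply(ref$records$sequence, function(b) oracle_hamming(pre, b),
              integer(1))
  dmin <- min(d)
  if (dmin > max_mismatches) {
    list(status = "unassigned_distance", barcode_name = NA_character_)
  } else if (sum(d == dmin) > 1) {
    list(status = "unassigned_ambiguous", barcode_name = NA_character_)
  } else {
    list(status = "assigned", barcode_name = ref$records$name[which.min(d)])
  }
}

# Substitute the bases at `positions` with a different base (deterministic:
# A->C, C->G, G->T, T->A).
mutate_at <- function(seq, positions) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars <- strsplit(seq, "")[[1]]
  chars[positions] <- rot[chars[positions]]
  paste(chars, collapse = "")
}

# Plain 4-line FASTQ writer, independent of the package's simulator.
write_fastq_plain <- function(path, seqs, quals = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("r%04d", seq_len(n))
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

# Small fixed reference used across tests (seed-stable).
fixture_reference <- function(n = 20, seed = 101) {
  random_reference(n, barcode_length = 20, min_distance = 5, seed = seed)
}
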