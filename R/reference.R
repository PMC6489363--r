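#' Construct a barcode reference
#'
#' A barcode reference is the validated panel of fixed-length DNA barcodes that
#' reads are assigned to. Each record carries a unique name, a sequence over
#' `{A, C, G, T}` of exactly `barcode_length` bases, an optional restriction
#' `enzyme_group` label (used for orthogonal-enzyme multiplexing reports), and
#' a `role` (`"pool_barcode"`, `"size_standard"`, or `"normalization"`).
#' The minimum pairwise Hamming distance over the panel is computed on
#' construction; a panel supports unambiguous assignment at mismatch budget
#' `m` iff this minimum is at least `2 m + 1`.
#'
#' @param names character vector of unique record names.
#' @param sequences character vector of DNA sequences, all of length
#'   `barcode_length`.
#' @param barcode_length barcode length in nucleotides (default 20).
#' @param enzyme_group optional character vector of enzyme-group labels
#'   (e.g. MlyI/BsmI/BtsI/BsrDI), recycled to the number of records.
#' @param role character vector of record roles, recycled.
#'
#' @return An object of class `barcode_reference`: a list with elements
#'   `barcode_length`, `records` (data frame with columns `name`, `sequence`,
#'   `enzyme_group`, `role`) and `min_pairwise_distance`.
#' @export
barcode_reference <- function(names, sequences, barcode_length = 20L,
                              enzyme_group = NA_character_,
                              role = "pool_barcode") {
  names <- as.character(names)
  sequences <- toupper(as.character(sequences))
  if (length(names) != length(sequences)) {
    stop("'names' and 'sequences' must have the same length")
  }
  if (length(names) == 0L) {
    stop("a barcode reference needs at least one record")
  }
  dup <- unique(names[duplicated(names)])
  if (length(dup) > 0L) {
    stop("duplicate record names in reference: ", paste(dup, collapse = ", "))
  }
  dup_seq <- unique(names[duplicated(sequences) |
                            duplicated(sequences, fromLast = TRUE)])
  if (length(unique(sequences)) != length(sequences)) {
    stop("duplicate barcode sequences in reference (records: ",
         paste(dup_seq, collapse = ", "), ")")
  }
  bad_len <- which(nchar(sequences) != barcode_length)
  if (length(bad_len) > 0L) {
    stop("sequence length differs from barcode_length (", barcode_length,
         ") for: ", paste(names[bad_len], collapse = ", "))
  }
  bad <- regexpr("[^ACGT]", sequences)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-ACGT character in record '", names[i], "' at position ",
         bad[i])
  }
  records <- data.frame(
    name = names,
    sequence = sequences,
    enzyme_group = rep_len(as.character(enzyme_group), length(names)),
    role = rep_len(as.character(role), length(names)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      barcode_length = as.integer(barcode_length),
      records = records,
      min_pairwise_distance = min_pairwise_distance(sequences)
    ),
    class = "barcode_reference"
  )
}

# Smallest Hamming distance over all sequence pairs (Inf for a single record).
min_pairwise_distance <- function(sequences) {
  k <- length(sequences)
  if (k < 2L) {
    return(Inf)
  }
  d <- hamming_matrix_cpp(sequences)
  min(d[upper.tri(d)])
}

#' @export
print.barcode_reference <- function(x, ...) {
  cat("barcode_reference:", nrow(x$records), "records of",
      x$barcode_length, "nt; min pairwise Hamming distance",
      x$min_pairwise_distance, "\n")
  roles <- table(x$records$role)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a barcode reference from FASTA
#'
#' Reads a FASTA file of barcode sequences and validates it into a
#' [barcode_reference()]. Sequences longer than `barcode_length` are truncated
#' to their first `barcode_length` bases with a warning (the assay reads the
#' barcode from the adapter, so only the leading bases are informative);
#' shorter sequences are an error, as are duplicate names, duplicate
#' (truncated) sequences, and non-ACGT characters.
#'
#' Record metadata (enzyme group, role, size-standard pairing) lives in an
#' optional sidecar tab-separated table keyed by record name, keeping the
#' sequence file plain FASTA.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @param barcode_length expected barcode length in nt (default 20).
#' @param metadata optional path to a tab-separated file with a header and
#'   columns `name` plus any of `enzyme_group`, `role`; joined by name.
#' @return A `barcode_reference`.
#' @export
read_reference <- function(path, barcode_length = 20L, metadata = NULL) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: '", path, "'")
  }
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  nm <- names(seqs)
  nm <- sub("\\s.*$", "", nm)  # FASTA description after first token dropped
  s <- toupper(as.character(seqs))
  names(s) <- NULL
  short <- which(nchar(s) < barcode_length)
  if (length(short) > 0L) {
    stop("records shorter than barcode_length (", barcode_length, "): ",
         paste(nm[short], collapse = ", "))
  }
  if (any(nchar(s) > barcode_length)) {
    n_tr <- sum(nchar(s) > barcode_length)
    warning(n_tr, " record(s) longer than ", barcode_length,
            " nt truncated to their first ", barcode_length, " bases")
    s <- substr(s, 1L, barcode_length)
  }
  eg <- NA_character_
  role <- "pool_barcode"
  if (!is.null(metadata)) {
    meta <- read.delim(metadata, stringsAsFactors = FALSE)
    if (!"name" %in% names(meta)) {
      stop("metadata table must have a 'name' column")
    }
    idx <- match(nm, meta$name)
    if ("enzyme_group" %in% names(meta)) eg <- meta$enzyme_group[idx]
    if ("role" %in% names(meta)) {
      role <- ifelse(is.na(idx), "pool_barcode", meta$role[idx])
    }
  }
  barcode_reference(nm, s, barcode_length = barcode_length,
                    enzyme_group = eg, role = role)
}

#' Write a barcode reference to FASTA
#'
#' Inverse of [read_reference()]: round-tripping preserves names, sequences
#' and record order exactly.
#'
#' @param ref a `barcode_reference`.
#' @param path output FASTA path.
#' @return The path, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "barcode_reference"))
  x <- Biostrings::DNAStringSet(ref$records$sequence)
  names(x) <- ref$records$name
  write_atomic(path, function(tmp) Biostrings::writeXStringSet(x, tmp))
}

#' Check whether a reference supports unambiguous assignment
#'
#' A panel is assignment-safe at mismatch budget `m` when every pair of
#' barcodes is at Hamming distance at least `2 m + 1`, so no read can sit
#' within `m` mismatches of two different barcodes.
#'
#' @param ref a `barcode_reference`.
#' @param max_mismatches mismatch budget `m` (default 2, the standard
#'   tolerance for 20-bp barcode panels).
#' @return A list with `safe` (logical), `min_pairwise_distance`,
#'   `required_distance`, and `offending_pairs` (data frame of every pair
#'   below the bound: `name1`, `name2`, `distance`; empty when safe).
#' @export
check_assignment_safety <- function(ref, max_mismatches = 2L) {
  stopifnot(inherits(ref, "barcode_reference"), max_mismatches >= 0)
  need <- 2L * as.integer(max_mismatches) + 1L
  seqs <- ref$records$sequence
  nm <- ref$records$name
  pairs <- data.frame(name1 = character(), name2 = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (length(seqs) >= 2L) {
    d <- hamming_matrix_cpp(seqs)
    idx <- which(upper.tri(d) & d < need, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      pairs <- data.frame(name1 = nm[idx[, 1L]], name2 = nm[idx[, 2L]],
                          distance = d[idx], stringsAsFactors = FALSE)
    }
  }
  list(
    safe = ref$min_pairwise_distance >= need,
    min_pairwise_distance = ref$min_pairwise_distance,
    required_distance = need,
    offending_pairs = pairs
  )
}
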