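#' Assign a read to a barcode by mismatch-tolerant prefix matching
#'
#' The first `barcode_length` bases of the read are compared against every
#' barcode in the reference by Hamming distance. The read is assigned to the
#' unique barcode with minimal distance at most `max_mismatches`; a tie at
#' the minimal distance yields `unassigned_ambiguous` (never an arbitrary
#' split), a minimal distance above the budget yields `unassigned_distance`,
#' and a read shorter than the barcode yields `unassigned_short`. Any
#' non-ACGT base in the prefix (including `N`) counts as a mismatch at that
#' position. Only the forward prefix is searched.
#'
#' @param read_sequence a DNA string (one read).
#' @param ref a [barcode_reference()].
#' @param max_mismatches mismatch budget (default 2).
#' @return A list with `status` (one of `assigned`, `unassigned_distance`,
#'   `unassigned_ambiguous`, `unassigned_short`), `barcode_name` (`NA` unless
#'   assigned) and `distance` (`NA` unless assigned or ambiguous).
#' @export
assign_read <- function(read_sequence, ref, max_mismatches = 2L) {
  res <- assign_reads(read_sequence, ref, max_mismatches)
  list(status = res$status[1L],
       barcode_name = res$barcode_name[1L],
       distance = res$distance[1L])
}

# Vectorized assignment over many reads; returns a data frame with one row
# per read (status, barcode_name, distance).
assign_reads <- function(read_sequences, ref, max_mismatches = 2L) {
  stopifnot(inherits(ref, "barcode_reference"), max_mismatches >= 0)
  reads <- toupper(as.character(read_sequences))
  n <- length(reads)
  status <- rep("unassigned_short", n)
  barcode_name <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  long_enough <- nchar(reads) >= ref$barcode_length
  if (any(long_enough)) {
    prefixes <- substr(reads[long_enough], 1L, ref$barcode_length)
    res <- hamming_assign_cpp(prefixes, ref$records$sequence,
                              as.integer(max_mismatches))
    st <- c("assigned", "unassigned_distance", "unassigned_ambiguous")
    status[long_enough] <- st[res$status]
    barcode_name[long_enough] <- ifelse(
      is.na(res$index), NA_character_, ref$records$name[res$index])
    distance[long_enough] <- res$distance
  }
  data.frame(status = status, barcode_name = barcode_name,
             distance = distance, stringsAsFactors = FALSE)
}

#' Count barcode assignments in a FASTQ file
#'
#' Applies [assign_read()] to every read of a FASTQ (optionally
#' gzip-compressed) file and accumulates a per-barcode count table for one
#' sample. The table satisfies exact read conservation:
#' `sum(counts) + unassigned_distance + unassigned_ambiguous +
#' unassigned_short == total_reads`.
#'
#' @param fastq path to a FASTQ or FASTQ.gz file.
#' @param ref a [barcode_reference()].
#' @param max_mismatches mismatch budget (default 2).
#' @param sample_id sample label recorded in the table (defaults to the file
#'   name).
#' @return An object of class `count_table`: list with `sample_id`, `counts`
#'   (named integer vector over every reference barcode, zeros kept),
#'   `unassigned_distance`, `unassigned_ambiguous`, `unassigned_short`,
#'   `total_reads`.
#' @export
count_fastq <- function(fastq, ref, max_mismatches = 2L, sample_id = NULL) {
  if (!file.exists(fastq)) stop("FASTQ not found: '", fastq, "'")
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  res <- assign_reads(as.character(reads), ref, max_mismatches)
  counts_from_assignments(res, ref,
                          sample_id = sample_id %||% basename(fastq))
}

# Build a count_table from an assignment data frame.
counts_from_assignments <- function(assignments, ref, sample_id) {
  counts <- setNames(integer(nrow(ref$records)), ref$records$name)
  assigned <- assignments$barcode_name[assignments$status == "assigned"]
  if (length(assigned) > 0L) {
    tab <- table(factor(assigned, levels = ref$records$name))
    counts[] <- as.integer(tab)
  }
  out <- structure(
    list(
      sample_id = sample_id,
      counts = counts,
      unassigned_distance = sum(assignments$status == "unassigned_distance"),
      unassigned_ambiguous = sum(assignments$status == "unassigned_ambiguous"),
      unassigned_short = sum(assignments$status == "unassigned_short"),
      total_reads = nrow(assignments)
    ),
    class = "count_table"
  )
  validate_count_table(out)
}

# The conservation invariant is structural: violating it means a bug, so it
# is asserted on every construction.
validate_count_table <- function(x) {
  stopifnot(inherits(x, "count_table"))
  if (sum(x$counts) + x$unassigned_distance + x$unassigned_ambiguous +
      x$unassigned_short != x$total_reads) {
    stop("count_table conservation violated for sample '", x$sample_id, "'")
  }
  invisible(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table '", x$sample_id, "': ", x$total_reads, " reads, ",
      sum(x$counts), " assigned over ", length(x$counts), " barcodes; ",
      "unassigned distance/ambiguous/short = ", x$unassigned_distance, "/",
      x$unassigned_ambiguous, "/", x$unassigned_short, "\n", sep = "")
  invisible(x)
}

#' Convert a count table to relative abundances
#'
#' Relative abundance of barcode `i` is `p_i = counts_i / sum(counts)` over
#' assigned reads; the abundances sum to one.
#'
#' @param table a `count_table`.
#' @return An object of class `abundance_vector`: list with `sample_id`, `p`
#'   (named numeric vector summing to 1) and `n_assigned`.
#' @export
to_abundances <- function(table) {
  stopifnot(inherits(table, "count_table"))
  n <- sum(table$counts)
  if (n == 0L) {
    stop("no assigned reads in sample '", table$sample_id,
         "': abundances undefined")
  }
  structure(
    list(sample_id = table$sample_id, p = table$counts / n, n_assigned = n),
    class = "abundance_vector"
  )
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("abundance_vector '", x$sample_id, "': ", length(x$p),
      " barcodes over ", x$n_assigned, " assigned reads; range ",
      sprintf("%.4g", min(x$p)), "-", sprintf("%.4g", max(x$p)), "\n",
      sep = "")
  invisible(x)
}

#' Read / write a count table as tab-separated text
#'
#' The body has columns `sample_id`, `barcode_name`, `count` (one row per
#' reference barcode, zeros kept); unassigned categories and the read total
#' follow as a `#`-prefixed footer block.
#'
#' @param table a `count_table`.
#' @param path file path.
#' @return `read_count_table` returns a `count_table`.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    df <- data.frame(sample_id = table$sample_id,
                     barcode_name = names(table$counts),
                     count = as.integer(table$counts))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(
      paste0("#unassigned_distance\t", table$unassigned_distance),
      paste0("#unassigned_ambiguous\t", table$unassigned_ambiguous),
      paste0("#unassigned_short\t", table$unassigned_short),
      paste0("#total_reads\t", table$total_reads)
    ), con)
  })
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: '", path, "'")
  lines <- readLines(path)
  footer <- grep("^#", lines, value = TRUE)
  get_foot <- function(key) {
    m <- grep(paste0("^#", key, "\t"), footer, value = TRUE)
    if (length(m) == 0L) stop("count table footer missing '", key, "'")
    as.integer(sub(".*\t", "", m[1L]))
  }
  body <- read.delim(text = paste(grep("^#", lines, invert = TRUE,
                                       value = TRUE), collapse = "\n"),
                     stringsAsFactors = FALSE)
  out <- structure(
    list(
      sample_id = body$sample_id[1L],
      counts = setNames(as.integer(body$count), body$barcode_name),
      unassigned_distance = get_foot("unassigned_distance"),
      unassigned_ambiguous = get_foot("unassigned_ambiguous"),
      unassigned_short = get_foot("unassigned_short"),
      total_reads = get_foot("total_reads")
    ),
    class = "count_table"
  )
  validate_count_table(out)
}
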