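#' Per-construct mean quality scores
#'
#' Splits reads by barcode assignment, trims every assigned read to a fixed
#' length so constructs and runs are comparable, and reports the mean Phred
#' quality per construct over all bases of all trimmed reads. Reads shorter
#' than `trim_length` contribute no bases and are tallied; constructs with
#' fewer than `min_reads` assigned reads are listed but carry no mean.
#'
#' By default the mean is the arithmetic mean of Phred scores over bases;
#' with `prob_domain = TRUE` per-base error probabilities are averaged and
#' the mean converted back to the Phred scale
#' (`-10 log10(mean(10^(-q/10)))`), which weights low-quality bases more
#' heavily.
#'
#' @param fastq path to a FASTQ or FASTQ.gz file (Phred+33 qualities).
#' @param ref a [barcode_reference()].
#' @param max_mismatches mismatch budget for assignment (default 2).
#' @param trim_length bases retained per read (default 50).
#' @param min_reads minimum assigned reads for a construct to carry a mean
#'   (default 100).
#' @param prob_domain average in error-probability domain (default `FALSE`).
#' @return An object of class `quality_report`: list with `per_construct`
#'   (data frame `barcode_name`, `n_reads`, `n_used`, `mean_quality` — `NA`
#'   below the read floor), `trim_length`, `min_reads`, `n_short_reads`
#'   (assigned reads shorter than `trim_length`) and `prob_domain`.
#' @export
per_construct_quality <- function(fastq, ref, max_mismatches = 2L,
                                  trim_length = 50L, min_reads = 100L,
                                  prob_domain = FALSE) {
  if (!file.exists(fastq)) stop("FASTQ not found: '", fastq, "'")
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(fastq),
    # Biostrings emits an informational warning about dropped metadata
    # columns on every FASTQ load; nothing in the report uses them.
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  res <- assign_reads(as.character(reads), ref, max_mismatches)

  assigned <- res$status == "assigned"
  usable <- assigned & Biostrings::width(reads) >= trim_length
  n_short <- sum(assigned & !usable)

  qual_sums <- setNames(numeric(nrow(ref$records)), ref$records$name)
  n_used <- setNames(integer(nrow(ref$records)), ref$records$name)
  if (any(usable)) {
    q <- Biostrings::quality(IRanges::narrow(reads[usable], 1L,
                                             trim_length))
    qm <- matrix(as.integer(unlist(methods::as(q, "IntegerList"),
                                   use.names = FALSE)),
                 ncol = trim_length, byrow = TRUE)
    if (anyNA(qm)) stop("malformed quality string in '", fastq, "'")
    per_read <- if (prob_domain) rowSums(10^(-qm / 10)) else rowSums(qm)
    bc <- factor(res$barcode_name[usable], levels = ref$records$name)
    qual_sums[] <- as.numeric(tapply(per_read, bc, sum, default = 0))
    n_used[] <- as.integer(table(bc))
  }
  n_reads <- setNames(integer(nrow(ref$records)), ref$records$name)
  tab <- table(factor(res$barcode_name[assigned], levels = ref$records$name))
  n_reads[] <- as.integer(tab)

  mean_q <- ifelse(n_used > 0, qual_sums / (n_used * trim_length), NA_real_)
  if (prob_domain) mean_q <- -10 * log10(mean_q)
  mean_q[n_reads < min_reads] <- NA_real_

  structure(
    list(
      per_construct = data.frame(
        barcode_name = ref$records$name,
        n_reads = n_reads,
        n_used = n_used,
        mean_quality = mean_q,
        row.names = NULL,
        stringsAsFactors = FALSE
      ),
      trim_length = as.integer(trim_length),
      min_reads = as.integer(min_reads),
      n_short_reads = n_short,
      prob_domain = prob_domain
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  ok <- sum(!is.na(x$per_construct$mean_quality))
  cat("quality_report: ", nrow(x$per_construct), " constructs, ", ok,
      " with >= ", x$min_reads, " reads; trim ", x$trim_length, " nt",
      if (x$prob_domain) "; probability-domain mean" else "", "\n", sep = "")
  invisible(x)
}

#' @rdname per_construct_quality
#' @param report a `quality_report`.
#' @param path output TSV path.
#' @export
write_quality_report <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# trim_length=", report$trim_length),
      paste0("# min_reads=", report$min_reads),
      paste0("# n_short_reads=", report$n_short_reads),
      paste0("# prob_domain=", report$prob_domain)
    ), con)
    write.table(report$per_construct, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
}
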