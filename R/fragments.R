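#' Read / write a headered SAM file for fragment-size analysis
#'
#' A light line-oriented SAM reader used for subsampling and insert-size
#' binning, where header lines and alignment records must be preserved
#' verbatim. Only the query name, flag, reference name and template length
#' fields are interpreted; each record keeps its original line so output is
#' byte-identical to input.
#'
#' @param path SAM file path.
#' @return An object of class `sam_records`: list with `header` (character
#'   vector of `@`-lines) and `records` (data frame `qname`, `flag`,
#'   `rname`, `tlen`, `line`).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: '", path, "'")
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  body <- lines[!is_header]
  if (length(body) == 0L) {
    records <- data.frame(qname = character(), flag = integer(),
                          rname = character(), tlen = integer(),
                          line = character(), stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L)) {
      stop("malformed SAM record (fewer than 11 fields) at alignment line ",
           which(nf < 11L)[1L])
    }
    records <- data.frame(
      qname = vapply(fields, `[`, character(1), 1L),
      flag = as.integer(vapply(fields, `[`, character(1), 2L)),
      rname = vapply(fields, `[`, character(1), 3L),
      tlen = as.integer(vapply(fields, `[`, character(1), 9L)),
      line = body,
      stringsAsFactors = FALSE
    )
  }
  structure(list(header = lines[is_header], records = records),
            class = "sam_records")
}

#' @rdname read_sam
#' @param sam a `sam_records` object.
#' @export
write_sam <- function(sam, path) {
  stopifnot(inherits(sam, "sam_records"))
  write_atomic(path, function(tmp) {
    writeLines(c(sam$header, sam$records$line), tmp)
  })
}

#' @export
print.sam_records <- function(x, ...) {
  cat("sam_records:", length(x$header), "header lines,",
      nrow(x$records), "alignment records,",
      length(unique(x$records$qname)), "templates\n")
  invisible(x)
}

#' Subsample a paired-end alignment file to a fixed read depth
#'
#' Draws a uniform random sample of `depth / 2` templates without
#' replacement, keeping or dropping both mates of a pair together, so the
#' output contains exactly `depth` reads with pair integrity intact. The
#' sample is deterministic given `seed`; the header and the surviving
#' records are preserved verbatim, in their original order.
#'
#' @param sam a [read_sam()] object whose records form whole pairs (two
#'   records per query name).
#' @param depth target depth in reads (must be even and at most the number
#'   of reads available).
#' @param seed integer seed making the draw reproducible.
#' @return A `sam_records` object with an `achieved_depth` attribute.
#' @export
subsample_alignments <- function(sam, depth, seed) {
  stopifnot(inherits(sam, "sam_records"))
  if (missing(seed)) stop("subsampling requires an explicit seed")
  depth <- as.numeric(depth)
  if (depth %% 2 != 0) stop("depth must be even (reads form pairs)")
  qn <- sam$records$qname
  per_template <- table(qn)
  if (any(per_template != 2L)) {
    bad <- names(per_template)[per_template != 2L][1L]
    stop("input is not whole pairs: template '", bad, "' has ",
         per_template[bad], " record(s)")
  }
  templates <- unique(qn)
  n_avail <- 2L * length(templates)
  if (depth > n_avail) {
    stop("requested depth ", format(depth, scientific = FALSE),
         " exceeds available reads (", n_avail, ")")
  }
  pick <- with_seed(as.integer(seed), {
    sample(templates, depth / 2, replace = FALSE)
  })
  keep <- qn %in% pick
  out <- structure(
    list(header = sam$header, records = sam$records[keep, , drop = FALSE]),
    class = "sam_records"
  )
  attr(out, "achieved_depth") <- sum(keep)
  out
}

#' Nucleosomal insert-size bins
#'
#' The standard ATAC-seq insert-size classes: non-nucleosomal (< 100 bp),
#' mono-nucleosomal (180-247 bp), di-nucleosomal (315-473 bp) and
#' tri-nucleosomal (558-615 bp). Inserts in the gaps between classes
#' (100-179, 248-314, 474-557) or beyond 615 bp are `unbinned` — an explicit
#' category, never merged into a neighbour.
#'
#' @return A data frame with columns `label`, `min`, `max` (inclusive
#'   integer bounds) defining the four classes.
#' @export
nucleosome_bins <- function() {
  data.frame(
    label = c("non_nucleosomal", "mono_nucleosomal", "di_nucleosomal",
              "tri_nucleosomal"),
    min = c(1L, 180L, 315L, 558L),
    max = c(99L, 247L, 473L, 615L),
    stringsAsFactors = FALSE
  )
}

#' Classify insert sizes into nucleosomal bins
#'
#' Pure function from a positive insert size to a bin label under the
#' configured inclusive ranges; sizes falling in no range are `"unbinned"`.
#'
#' @param insert_size vector of positive insert sizes in bp.
#' @param bins bin table as returned by [nucleosome_bins()].
#' @return Character vector of bin labels.
#' @export
classify_insert <- function(insert_size, bins = nucleosome_bins()) {
  if (any(insert_size <= 0)) {
    stop("insert sizes must be positive (got ",
         insert_size[insert_size <= 0][1L], ")")
  }
  out <- rep("unbinned", length(insert_size))
  for (i in seq_len(nrow(bins))) {
    hit <- insert_size >= bins$min[i] & insert_size <= bins$max[i]
    out[hit] <- bins$label[i]
  }
  out
}

#' Nucleosomal bin proportions of a paired-end alignment set
#'
#' Takes one insert size per template — the absolute template length read
#' from the mate bearing the positive value — classifies it with
#' [classify_insert()], and reports counts and proportions per bin. Pairs
#' with no positive template length, or whose mates map to different
#' contigs, cannot be sized and are tallied separately as
#' `undefined_templates`, never guessed. Mitochondrial and duplicate
#' filtering are assumed done upstream.
#'
#' @param sam a [read_sam()] (typically after [subsample_alignments()]).
#' @param bins bin table as returned by [nucleosome_bins()].
#' @return An object of class `fragment_bin_summary`: list with `depth`
#'   (reads), `counts` and `proportions` (named over `non_nucleosomal`,
#'   `mono_nucleosomal`, `di_nucleosomal`, `tri_nucleosomal`, `unbinned`;
#'   counts sum to the sized templates, proportions to 1) and
#'   `undefined_templates`.
#' @export
bin_proportions <- function(sam, bins = nucleosome_bins()) {
  stopifnot(inherits(sam, "sam_records"))
  r <- sam$records
  if (nrow(r) == 0L) stop("no alignment records")
  split_idx <- split(seq_len(nrow(r)), r$qname)
  insert <- vapply(split_idx, function(idx) {
    tl <- r$tlen[idx]
    if (length(unique(r$rname[idx])) > 1L) return(NA_integer_)
    pos <- tl[!is.na(tl) & tl > 0L]
    if (length(pos) == 0L) NA_integer_ else pos[1L]
  }, integer(1))
  defined <- !is.na(insert)
  labels <- c(bins$label, "unbinned")
  cls <- factor(classify_insert(insert[defined], bins), levels = labels)
  counts <- setNames(as.integer(table(cls)), labels)
  n_pairs <- sum(defined)
  if (n_pairs == 0L) stop("no template with a defined insert size")
  structure(
    list(
      depth = nrow(r),
      counts = counts,
      proportions = counts / n_pairs,
      undefined_templates = sum(!defined)
    ),
    class = "fragment_bin_summary"
  )
}

#' @export
print.fragment_bin_summary <- function(x, ...) {
  cat("fragment_bin_summary: depth", x$depth, "reads;",
      x$undefined_templates, "undefined template(s)\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' @rdname bin_proportions
#' @param summary a `fragment_bin_summary`.
#' @param path output TSV path.
#' @export
write_bin_summary <- function(summary, path) {
  stopifnot(inherits(summary, "fragment_bin_summary"))
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# depth_reads=", summary$depth),
      paste0("# undefined_templates=", summary$undefined_templates)
    ), con)
    df <- data.frame(bin = names(summary$counts),
                     count = as.integer(summary$counts),
                     proportion = as.numeric(summary$proportions))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
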