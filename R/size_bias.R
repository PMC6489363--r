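#' Sequencer size-bias profile from paired standard/normalization counts
#'
#' For each design entry, clustering efficiency is the count ratio
#' `E_i = S_i / N_i` of the variable-length size standard (`S_i`, molecule
#' length `L_i`) to its same-plasmid constant-length normalization barcode
#' (`N_i`). Because the two cassettes are equimolar on the plasmid, any
#' pooling inaccuracy scales `S_i` and `N_i` together and cancels in the
#' ratio; what remains is the sequencer's length-dependent clustering
#' behaviour. The reported curve is `E_norm_i = E_i / median_j(E_j)`,
#' normalized to the median efficiency across retained standards (robust to
#' single-point depletion); the raw `E_i` is always retained.
#'
#' Entries whose normalization count falls below `min_norm_count` are
#' excluded with a reason rather than producing unstable ratios.
#'
#' @param table a `count_table` over the design's barcodes.
#' @param design a `size_standard_design` (see
#'   [generate_size_standard_design()], [read_design()]).
#' @param min_norm_count minimum normalization-barcode reads for a point to
#'   be retained (default 100).
#' @param run_id label for the run (defaults to the table's sample id).
#' @return An object of class `size_bias_profile`: list with `run_id`,
#'   `points` (data frame ordered by `molecule_length` with columns
#'   `standard_name`, `backbone`, `molecule_length`, `S`, `N`, `E`,
#'   `E_norm`) and `excluded` (data frame `standard_name`, `reason`).
#' @export
size_bias_profile <- function(table, design, min_norm_count = 100L,
                              run_id = NULL) {
  validate_count_table(table)
  validate_design(design)
  e <- design$entries
  missing <- setdiff(c(e$standard_name, e$normalization_name),
                     names(table$counts))
  if (length(missing) > 0L) {
    stop("design barcodes absent from count table: ",
         paste(missing, collapse = ", "))
  }
  S <- as.numeric(table$counts[e$standard_name])
  N <- as.numeric(table$counts[e$normalization_name])
  keep <- N >= min_norm_count
  excluded <- data.frame(
    standard_name = e$standard_name[!keep],
    reason = sprintf("normalization count %d below floor %d",
                     as.integer(N[!keep]), as.integer(min_norm_count)),
    stringsAsFactors = FALSE
  )
  pts <- data.frame(
    standard_name = e$standard_name[keep],
    backbone = e$backbone[keep],
    molecule_length = e$molecule_length[keep],
    S = as.integer(S[keep]),
    N = as.integer(N[keep]),
    stringsAsFactors = FALSE
  )
  pts$E <- pts$S / pts$N
  pts$E_norm <- pts$E / median(pts$E)
  pts <- pts[order(pts$molecule_length, pts$standard_name), ]
  rownames(pts) <- NULL
  structure(
    list(run_id = run_id %||% table$sample_id, points = pts,
         excluded = excluded),
    class = "size_bias_profile"
  )
}

#' @export
print.size_bias_profile <- function(x, ...) {
  cat("size_bias_profile '", x$run_id, "': ", nrow(x$points),
      " points over ", min(x$points$molecule_length), "-",
      max(x$points$molecule_length), " bp (", nrow(x$excluded),
      " excluded)\n", sep = "")
  invisible(x)
}

#' Compare size-bias profiles across runs, platforms or treatments
#'
#' Aligns profiles on the standards retained by every run. For the first two
#' profiles it reports the per-length ratio
#' `R_i = E_norm_i(run A) / E_norm_i(run B)`; across all runs it reports the
#' per-length CV of `E_norm`. The divergence summary `max_fold_difference`
#' is `max_i(R_i) / min_i(R_i)`, the spread of the between-run ratio across
#' the shared length range — a quantity independent of how each profile is
#' normalized, so it compares the *shapes* of the curves.
#'
#' @param profiles list of at least 2 [size_bias_profile()] objects sharing
#'   at least 3 retained standards.
#' @return A list with `run_ids`, `by_length` (data frame: `standard_name`,
#'   `molecule_length`, one `E_norm` column per run, `ratio` (first pair),
#'   `cv`) and `max_fold_difference`.
#' @export
compare_profiles <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  stopifnot(all(vapply(profiles, inherits, logical(1), "size_bias_profile")))
  ids <- vapply(profiles, function(p) p$run_id, character(1))
  shared <- Reduce(intersect, lapply(profiles, function(p) {
    p$points$standard_name
  }))
  if (length(shared) < 3L) {
    stop("profiles share only ", length(shared),
         " retained standards; need at least 3")
  }
  first <- profiles[[1L]]$points
  base <- first[match(shared, first$standard_name),
                c("standard_name", "molecule_length")]
  en <- vapply(profiles, function(p) {
    p$points$E_norm[match(shared, p$points$standard_name)]
  }, numeric(length(shared)))
  colnames(en) <- make.unique(ids)
  ratio <- en[, 1L] / en[, 2L]
  cv <- apply(en, 1L, coefficient_of_variation)
  by_length <- cbind(base, en, ratio = ratio, cv = cv)
  by_length <- by_length[order(by_length$molecule_length), ]
  rownames(by_length) <- NULL
  list(
    run_ids = ids,
    by_length = by_length,
    max_fold_difference = max(ratio) / min(ratio)
  )
}

#' Write a size-bias profile as tab-separated text
#'
#' Columns: `run_id`, `standard_name`, `backbone`, `molecule_length`, `S`,
#' `N`, `E`, `E_norm`; excluded standards follow as `#`-prefixed footer
#' lines.
#'
#' @param profile a `size_bias_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "size_bias_profile"))
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    df <- cbind(run_id = profile$run_id, profile$points)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(profile$excluded) > 0L) {
      writeLines(paste0("#excluded\t", profile$excluded$standard_name, "\t",
                        profile$excluded$reason), con)
    }
  })
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile not found: '", path, "'")
  lines <- readLines(path)
  body <- read.delim(text = paste(grep("^#", lines, invert = TRUE,
                                       value = TRUE), collapse = "\n"),
                     stringsAsFactors = FALSE)
  excl <- grep("^#excluded\t", lines, value = TRUE)
  excluded <- if (length(excl) > 0L) {
    parts <- strsplit(sub("^#excluded\t", "", excl), "\t")
    data.frame(standard_name = vapply(parts, `[`, character(1), 1L),
               reason = vapply(parts, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(standard_name = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  pts <- body[, setdiff(names(body), "run_id")]
  structure(
    list(run_id = body$run_id[1L], points = pts, excluded = excluded),
    class = "size_bias_profile"
  )
}
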