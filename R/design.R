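# Random barcode panel with a guaranteed minimum pairwise Hamming distance
# (rejection sampling; at 20 nt random pairs average distance 15, so
# rejections are rare for the panel sizes used here).
random_barcodes <- function(n, barcode_length = 20L, min_distance = 5L,
                            seed = 1L) {
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), barcode_length,
                           replace = TRUE), collapse = "")
      ok <- all(vapply(out, function(b) hamming_distance(cand, b),
                       integer(1)) >= min_distance)
      if (ok) out <- c(out, cand)
      tries <- tries + 1L
      if (tries > 1000L * n) {
        stop("could not generate ", n, " barcodes at min distance ",
             min_distance)
      }
    }
    out
  })
}

#' Generate a size-standard design and its barcode reference
#'
#' A size-standard pool measures length-dependent clustering efficiency on a
#' sequencer. Each construct carries two restriction-liberated cassettes on
#' the same plasmid: a variable-length size standard (adapter-flanked molecule
#' between `min_molecule` and `max_molecule` bp) and a constant-length
#' normalization barcode. Because the two cassettes are equimolar by
#' construction, the ratio of their read counts cancels pooling inaccuracy
#' and isolates the sequencer's length bias.
#'
#' Inserts are nested fragments of three backbone molecules (by default
#' labelled 16S, Tubulin and GAPDH); molecule length = insert length +
#' `flank_length` (the constant adapter flank, 128 bp by default, so the
#' canonical 150-1500 bp molecules carry 22-1372 bp inserts).
#'
#' @param sizes_per_backbone number of standards per backbone (>= 2); the
#'   canonical pool uses 10, for 30 constructs total.
#' @param min_molecule,max_molecule adapter-flanked molecule length range, bp.
#' @param flank_length constant adapter flank added to every insert, bp.
#' @param normalization_length molecule length of every normalization
#'   barcode, bp (164 by default).
#' @param backbones optional named character vector of 3 backbone seed
#'   sequences from which nested inserts are taken; random seeds labelled
#'   `16S`, `Tubulin`, `GAPDH` are generated when `NULL`.
#' @param barcode_length barcode length for the generated reference, nt.
#' @param seed integer seed for barcode (and default backbone) generation.
#'
#' @return A list with `design` (a `size_standard_design`: entry table plus
#'   `flank_length` and `normalization_length`) and `reference` (a
#'   [barcode_reference()] containing one `size_standard` and one
#'   `normalization` barcode per entry).
#' @export
generate_size_standard_design <- function(sizes_per_backbone = 10L,
                                          min_molecule = 150L,
                                          max_molecule = 1500L,
                                          flank_length = 128L,
                                          normalization_length = 164L,
                                          backbones = NULL,
                                          barcode_length = 20L,
                                          seed = 1L) {
  if (!(max_molecule > min_molecule && min_molecule > flank_length)) {
    stop("need max_molecule > min_molecule > flank_length")
  }
  if (sizes_per_backbone < 2L) {
    stop("sizes_per_backbone must be at least 2")
  }
  molecule <- as.integer(round(seq(min_molecule, max_molecule,
                                   length.out = sizes_per_backbone)))
  insert <- molecule - as.integer(flank_length)
  if (is.null(backbones)) {
    backbones <- with_seed(seed + 1L, vapply(
      c("16S", "Tubulin", "GAPDH"),
      function(nm) paste(sample(c("A", "C", "G", "T"), max(insert),
                                replace = TRUE), collapse = ""),
      character(1)))
  }
  if (is.null(names(backbones)) || any(!nzchar(names(backbones)))) {
    stop("'backbones' must be a named vector of seed sequences")
  }
  too_short <- nchar(backbones) < max(insert)
  if (any(too_short)) {
    stop("requested insert of ", max(insert), " bp longer than backbone ",
         "seed(s): ", paste(names(backbones)[too_short], collapse = ", "))
  }

  entries <- do.call(rbind, lapply(names(backbones), function(b) {
    data.frame(
      standard_name = sprintf("%s_%04d", b, molecule),
      normalization_name = sprintf("%s_%04d_norm", b, molecule),
      insert_length = insert,
      molecule_length = molecule,
      backbone = b,
      stringsAsFactors = FALSE
    )
  }))

  n_entry <- nrow(entries)
  bcs <- random_barcodes(2L * n_entry, barcode_length = barcode_length,
                         min_distance = 5L, seed = seed)
  ref <- barcode_reference(
    names = c(entries$standard_name, entries$normalization_name),
    sequences = bcs,
    barcode_length = barcode_length,
    enzyme_group = "MlyI",
    role = rep(c("size_standard", "normalization"), each = n_entry)
  )

  design <- structure(
    list(entries = entries,
         flank_length = as.integer(flank_length),
         normalization_length = as.integer(normalization_length)),
    class = "size_standard_design"
  )
  validate_design(design, ref)
  list(design = design, reference = ref)
}

# Check the design invariants against a reference: every name resolves,
# molecule = insert + flank for each entry.
validate_design <- function(design, ref = NULL) {
  stopifnot(inherits(design, "size_standard_design"))
  e <- design$entries
  bad <- e$molecule_length != e$insert_length + design$flank_length
  if (any(bad)) {
    stop("molecule_length != insert_length + flank_length for: ",
         paste(e$standard_name[bad], collapse = ", "))
  }
  if (!is.null(ref)) {
    need <- c(e$standard_name, e$normalization_name)
    missing <- setdiff(need, ref$records$name)
    if (length(missing) > 0L) {
      stop("design names absent from reference: ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(design)
}

#' @export
print.size_standard_design <- function(x, ...) {
  cat("size_standard_design:", nrow(x$entries), "entries over",
      length(unique(x$entries$backbone)), "backbones; molecules",
      min(x$entries$molecule_length), "-", max(x$entries$molecule_length),
      "bp; flank", x$flank_length, "bp; normalization",
      x$normalization_length, "bp\n")
  invisible(x)
}

#' Read / write a size-standard design table
#'
#' Tab-separated with a single header line (`standard_name`,
#' `normalization_name`, `insert_length`, `molecule_length`, `backbone`) and
#' `#`-prefixed metadata lines carrying `flank_length` and
#' `normalization_length`.
#'
#' @param path file path.
#' @return `read_design` returns a `size_standard_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design table not found: '", path, "'")
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\s*=\\s*"), meta, value = TRUE)
    if (length(m) == 0L) return(default)
    as.integer(sub(".*=\\s*", "", m[1L]))
  }
  body <- lines[!grepl("^#", lines)]
  e <- read.delim(text = paste(body, collapse = "\n"),
                  stringsAsFactors = FALSE)
  need <- c("standard_name", "normalization_name", "insert_length",
            "molecule_length", "backbone")
  if (!all(need %in% names(e))) {
    stop("design table must have columns: ", paste(need, collapse = ", "))
  }
  flank <- get_meta("flank_length",
                    unique(e$molecule_length - e$insert_length)[1L])
  design <- structure(
    list(entries = e[, need],
         flank_length = flank,
         normalization_length = get_meta("normalization_length", 164L)),
    class = "size_standard_design"
  )
  validate_design(design)
}

#' @rdname read_design
#' @param design a `size_standard_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "size_standard_design"))
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# flank_length=", design$flank_length),
      paste0("# normalization_length=", design$normalization_length)
    ), con)
    write.table(design$entries, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
}
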