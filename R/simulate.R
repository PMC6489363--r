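#' Random assignment-safe barcode reference
#'
#' Generates `n` random barcodes whose pairwise Hamming distances are all at
#' least `min_distance`, so the panel is assignment-safe at mismatch budget
#' `(min_distance - 1) / 2`. Used to build simulated pools and test
#' fixtures.
#'
#' @param n number of barcodes.
#' @param barcode_length barcode length in nt (default 20).
#' @param min_distance minimum pairwise Hamming distance (default 5, safe at
#'   2 mismatches).
#' @param seed integer seed.
#' @param prefix name prefix; names are `prefix` + zero-padded index.
#' @param enzyme_group,role passed through to [barcode_reference()].
#' @return A [barcode_reference()].
#' @export
random_reference <- function(n, barcode_length = 20L, min_distance = 5L,
                             seed = 1L, prefix = "BC",
                             enzyme_group = NA_character_,
                             role = "pool_barcode") {
  seqs <- random_barcodes(n, barcode_length, min_distance, seed)
  barcode_reference(sprintf("%s%02d", prefix, seq_len(n)), seqs,
                    barcode_length = barcode_length,
                    enzyme_group = enzyme_group, role = role)
}

# Deterministic filler appended after the barcode to reach the read length
# (an adapter-like constant, so every read of a construct is identical
# before sequencing error).
read_tail <- function(len) {
  if (len <= 0L) return("")
  base <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  paste(rep(substr(strrep(base, ceiling(len / nchar(base))), 1L, len), 1L),
        collapse = "")
}

#' Simulate FASTQ reads from a barcode pool
#'
#' Draws read identities from the pool proportions (multinomially, or by
#' largest-remainder apportionment in exact-count mode so that realized
#' counts match `depth * p_i` to within one read), builds each read as its
#' barcode followed by a constant tail, applies i.i.d. substitution errors
#' at rate `error_rate` (each erroneous base replaced by a uniformly chosen
#' different base), and attaches Phred+33 qualities from the quality model.
#' Deterministic given `seed`.
#'
#' @param ref a [barcode_reference()].
#' @param proportions named numeric vector of pool proportions summing to 1
#'   (default: even over the reference).
#' @param depth number of reads.
#' @param error_rate per-base substitution probability (0 to 0.1).
#' @param quality constant Phred score, or a per-position integer vector of
#'   length `read_length`.
#' @param read_length total read length in nt (default 50).
#' @param seed integer seed.
#' @param exact_counts use largest-remainder apportionment instead of a
#'   multinomial draw (default `FALSE`).
#' @param fastq optional output path (`.gz` supported); when `NULL`, reads
#'   are only returned.
#' @return A list with `reads` (named character vector of read sequences),
#'   `qualities` (Phred+33 strings), `truth` (data frame `read_id`,
#'   `barcode_name` of generating barcodes) and `fastq` (path or `NULL`).
#' @export
simulate_pool_reads <- function(ref, proportions = NULL, depth = 10000L,
                                error_rate = 0, quality = 35L,
                                read_length = 50L, seed = 1L,
                                exact_counts = FALSE, fastq = NULL) {
  stopifnot(inherits(ref, "barcode_reference"))
  nm <- ref$records$name
  if (is.null(proportions)) {
    proportions <- setNames(rep(1 / length(nm), length(nm)), nm)
  }
  match_names(names(proportions), nm, "proportions", "reference")
  p <- proportions[nm]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("proportions must be non-negative and sum to 1")
  }
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must be in [0, 0.1]")
  }
  if (read_length < ref$barcode_length) {
    stop("read_length shorter than the barcode")
  }
  qvec <- if (length(quality) == 1L) rep(as.integer(quality), read_length)
          else as.integer(quality)
  if (length(qvec) != read_length || any(qvec < 0 | qvec > 60)) {
    stop("quality must be a Phred score in [0, 60], scalar or of length ",
         "read_length")
  }
  tail <- read_tail(read_length - ref$barcode_length)
  templates <- paste0(ref$records$sequence, tail)

  with_seed(as.integer(seed), {
    idx <- if (exact_counts) {
      rep(seq_along(p), apportion_counts(p, depth))
    } else {
      sample(seq_along(p), depth, replace = TRUE, prob = p)
    }
    reads <- templates[idx]
    if (error_rate > 0 && depth > 0) {
      hit <- which(runif(depth * read_length) < error_rate)
      if (length(hit) > 0L) {
        read_i <- ((hit - 1L) %/% read_length) + 1L
        pos_i <- ((hit - 1L) %% read_length) + 1L
        touched <- unique(read_i)
        chars <- strsplit(reads[touched], "", fixed = TRUE)
        slot <- match(read_i, touched)
        alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
        pick <- sample.int(3L, length(hit), replace = TRUE)
        for (k in seq_along(hit)) {
          s <- slot[k]
          old <- chars[[s]][pos_i[k]]
          chars[[s]][pos_i[k]] <- alt[[old]][pick[k]]
        }
        reads[touched] <- vapply(chars, paste, character(1), collapse = "")
      }
    }
    read_id <- sprintf("read%07d", seq_len(length(reads)))
    names(reads) <- read_id
    qual <- rep(intToUtf8(qvec + 33L, multiple = FALSE), length(reads))
    truth <- data.frame(read_id = read_id,
                        barcode_name = ref$records$name[idx],
                        stringsAsFactors = FALSE)
    if (!is.null(fastq)) {
      write_atomic(fastq, function(tmp) {
        con <- if (grepl("\\.gz$", fastq)) gzfile(tmp, "w") else file(tmp, "w")
        on.exit(close(con))
        writeLines(paste0("@", read_id, "\n", reads, "\n+\n", qual), con)
      })
    }
    list(reads = reads, qualities = qual, truth = truth, fastq = fastq)
  })
}

#' Simulate PCR amplification bias on a pool composition
#'
#' Models per-template amplification efficiency: template `i` grows by
#' factor `(1 + e_i)` per cycle. In deterministic mode the output is the
#' expectation `p_i (1 + e_i)^c`, renormalized; in stochastic mode molecule
#' counts are duplicated per cycle by a binomial draw with success `e_i`
#' and renormalized, capturing amplification noise. Heterogeneous
#' efficiencies drive the composition away from the input increasingly with
#' cycle number; equal efficiencies leave it unchanged.
#'
#' @param p named numeric vector of proportions summing to 1.
#' @param efficiencies named numeric vector of per-template efficiencies
#'   `e_i` in (0, 1], over the same names.
#' @param cycles number of PCR cycles (>= 0).
#' @param mode `"deterministic"` (expectation) or `"stochastic"` (per-cycle
#'   binomial duplication).
#' @param initial_copies starting molecule count for stochastic mode.
#' @param seed seed for stochastic mode.
#' @return Named numeric vector of biased proportions summing to 1.
#' @export
simulate_pcr_bias <- function(p, efficiencies, cycles,
                              mode = c("deterministic", "stochastic"),
                              initial_copies = 1e6, seed = 1L) {
  mode <- match.arg(mode)
  match_names(names(p), names(efficiencies), "proportions", "efficiencies")
  e <- efficiencies[names(p)]
  if (any(e <= 0 | e > 1)) stop("efficiencies must be in (0, 1]")
  if (cycles < 0) stop("cycles must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  if (mode == "deterministic") {
    out <- p * (1 + e)^cycles
    return(out / sum(out))
  }
  with_seed(as.integer(seed), {
    n <- round(p * initial_copies)
    for (cyc in seq_len(cycles)) {
      dup <- ifelse(n < 1e9,
                    rbinom(length(n), size = as.integer(pmin(n, 2^31 - 1)),
                           prob = e),
                    round(n * e + sqrt(n * e * (1 - e)) *
                            rnorm(length(n))))
      n <- n + dup
      if (max(n) > 1e12) n <- n / max(n) * 1e9  # rescale; ratios preserved
    }
    n / sum(n)
  })
}

#' Exponential length-dependent clustering weight
#'
#' The default clustering-bias model: weight halves every `half_length` bp
#' above the reference length, `w(L) = 2^(-(L - L0) / half_length)` —
#' shorter molecules cluster preferentially, as observed on patterned and
#' non-patterned flowcells alike.
#'
#' @param L molecule length(s), bp.
#' @param half_length length increase that halves the clustering weight, bp.
#' @param L0 reference length with weight 1, bp.
#' @return Positive weight(s).
#' @export
cluster_weight <- function(L, half_length = 400, L0 = 150) {
  2^(-(L - L0) / half_length)
}

#' Simulate size-standard counts under length-dependent clustering bias
#'
#' Each design entry contributes two barcodes: its variable-length standard,
#' sampled with probability proportional to `m_i * w(L_i)`, and its
#' same-plasmid normalization barcode, proportional to `m_i * w(L_norm)`,
#' where `m_i` is an optional per-plasmid copy-number perturbation
#' (mimicking pooling inaccuracy; because it scales both cassettes it must
#' cancel in downstream efficiency ratios). Counts are a multinomial draw at
#' `depth` (or exact apportionment).
#'
#' @param design a `size_standard_design`.
#' @param depth total reads.
#' @param seed integer seed.
#' @param weight_fn clustering weight function of molecule length (default
#'   [cluster_weight()] with its default parameters).
#' @param copy_number optional named vector of per-plasmid perturbations
#'   `m_i`, keyed by `standard_name` (default all 1).
#' @param exact_counts largest-remainder apportionment instead of a
#'   multinomial draw.
#' @param sample_id label of the returned table.
#' @return A `count_table` over all standard and normalization barcodes.
#' @export
simulate_clustered_counts <- function(design, depth = 1e6, seed = 1L,
                                      weight_fn = cluster_weight,
                                      copy_number = NULL,
                                      exact_counts = FALSE,
                                      sample_id = "simulated_run") {
  validate_design(design)
  e <- design$entries
  m <- setNames(rep(1, nrow(e)), e$standard_name)
  if (!is.null(copy_number)) {
    m[names(copy_number)] <- copy_number
  }
  if (any(m <= 0)) stop("copy-number perturbations must be positive")
  w_std <- m * weight_fn(e$molecule_length)
  w_norm <- m * weight_fn(rep(design$normalization_length, nrow(e)))
  nm <- c(e$standard_name, e$normalization_name)
  prob <- c(w_std, w_norm)
  prob <- prob / sum(prob)
  counts <- if (exact_counts) {
    apportion_counts(prob, depth)
  } else {
    with_seed(as.integer(seed),
              as.integer(rmultinom(1L, size = depth, prob = prob)))
  }
  out <- structure(
    list(sample_id = sample_id,
         counts = setNames(counts, nm),
         unassigned_distance = 0L, unassigned_ambiguous = 0L,
         unassigned_short = 0L,
         total_reads = sum(counts)),
    class = "count_table"
  )
  validate_count_table(out)
}

#' Simulate a paired-end SAM file with a chosen insert-size mixture
#'
#' Writes properly paired templates whose absolute template lengths are
#' drawn from a weighted mixture of insert sizes (or apportioned exactly),
#' producing a headered SAM suitable for [subsample_alignments()] and
#' [bin_proportions()]. Deterministic given `seed`.
#'
#' @param mixture data frame with columns `insert_size` (bp, positive) and
#'   `weight` (non-negative, positive sum).
#' @param n_pairs number of templates.
#' @param contig reference name used in the header and records.
#' @param seed integer seed.
#' @param read_length read length for the dummy alignment records.
#' @param exact_counts apportion `n_pairs` across mixture components
#'   exactly.
#' @return A `sam_records` object (write with [write_sam()]).
#' @export
simulate_atac_sam <- function(mixture, n_pairs = 1000L, contig = "chr1",
                              seed = 1L, read_length = 50L,
                              exact_counts = FALSE) {
  stopifnot(is.data.frame(mixture),
            all(c("insert_size", "weight") %in% names(mixture)))
  if (any(mixture$insert_size <= 0)) stop("insert sizes must be positive")
  if (any(mixture$weight < 0) || sum(mixture$weight) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  sizes <- with_seed(as.integer(seed), {
    if (exact_counts) {
      rep(mixture$insert_size, apportion_counts(mixture$weight, n_pairs))
    } else {
      mixture$insert_size[sample.int(nrow(mixture), n_pairs,
                                     replace = TRUE,
                                     prob = mixture$weight)]
    }
  })
  qname <- sprintf("tpl%07d", seq_len(n_pairs))
  pos1 <- 1000L + 2L * (seq_len(n_pairs) - 1L)
  pos2 <- pos1 + sizes - read_length
  seq_str <- strrep("A", read_length)
  qual_str <- strrep("I", read_length)
  cigar <- paste0(read_length, "M")
  rec <- function(q, flag, pos, pnext, tlen) {
    paste(q, flag, contig, pos, 60L, cigar, "=", pnext, tlen,
          seq_str, qual_str, sep = "\t")
  }
  lines1 <- rec(qname, 99L, pos1, pos2, sizes)
  lines2 <- rec(qname, 147L, pos2, pos1, -sizes)
  body <- character(2L * n_pairs)
  body[c(TRUE, FALSE)] <- lines1
  body[c(FALSE, TRUE)] <- lines2
  header <- c("@HD\tVN:1.6\tSO:queryname",
              paste0("@SQ\tSN:", contig, "\tLN:",
                     max(pos2 + read_length) + 1000L))
  records <- data.frame(
    qname = rep(qname, each = 2L),
    flag = rep(c(99L, 147L), n_pairs),
    rname = contig,
    tlen = as.integer(rbind(sizes, -sizes)),
    line = body,
    stringsAsFactors = FALSE
  )
  structure(list(header = header, records = records), class = "sam_records")
}
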