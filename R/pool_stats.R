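#' Expected pool composition
#'
#' The design composition a pool was mixed to: strictly positive fractions
#' over the barcode panel, summing to one.
#'
#' @param p named numeric vector of target fractions (`t_i`).
#' @param label composition label (e.g. `"even 5%"`, `"staggered"`).
#' @return An `expected_composition` (named numeric vector with a `label`
#'   attribute).
#' @export
expected_composition <- function(p, label = "custom") {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop("expected composition must be a named vector")
  }
  if (any(p <= 0)) stop("all expected fractions must be > 0")
  if (abs(sum(p) - 1) > 1e-12) {
    stop("expected fractions must sum to 1 (got ", format(sum(p)), ")")
  }
  structure(as.numeric(p), names = names(p), label = label,
            class = "expected_composition")
}

#' @rdname expected_composition
#' @param barcode_names barcode names for an equimolar (even) composition.
#' @export
even_composition <- function(barcode_names) {
  k <- length(barcode_names)
  expected_composition(setNames(rep(1 / k, k), barcode_names),
                       label = sprintf("even %.3g%%", 100 / k))
}

#' Coefficient of variation
#'
#' `CV = sd / mean` with the sample (n-1) standard deviation, the convention
#' appropriate to small replicate counts.
#'
#' @param values numeric vector of at least 2 non-negative measurements with
#'   positive mean.
#' @return The dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("CV needs at least 2 values")
  m <- mean(values)
  if (!(m > 0)) stop("CV undefined: mean is not positive")
  sd(values) / m
}

#' Replicate precision of abundance measurements
#'
#' Per-barcode CV of the relative abundance across replicate measurements of
#' the same pool, plus the unweighted average over barcodes — the standard
#' replicate-precision summary for counting assays.
#'
#' @param replicates list of at least 2 [to_abundances()] results over the
#'   same barcode set.
#' @return A list with `per_barcode` (named CV vector) and `average_cv`.
#' @export
replicate_cv <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  stopifnot(all(vapply(replicates, inherits, logical(1), "abundance_vector")))
  nm <- names(replicates[[1L]]$p)
  for (r in replicates[-1L]) {
    extra <- setdiff(names(r$p), nm)
    missing <- setdiff(nm, names(r$p))
    if (length(extra) > 0L || length(missing) > 0L) {
      stop("replicate barcode sets differ (missing: ",
           paste(missing, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "), ")")
    }
  }
  mat <- vapply(replicates, function(r) r$p[nm], numeric(length(nm)))
  per <- apply(mat, 1L, coefficient_of_variation)
  list(per_barcode = setNames(per, nm), average_cv = mean(per))
}

#' Root mean squared deviation from an expected composition
#'
#' `RMSD = sqrt(mean_i (p_i - t_i)^2)` in abundance units: the accuracy of a
#' measured composition against the design targets.
#'
#' @param p an `abundance_vector` (or named numeric vector of fractions).
#' @param expected an [expected_composition()] — or a plain named numeric
#'   vector of targets, e.g. a sub-pool of a larger design — over the same
#'   barcodes.
#' @return The RMSD (non-negative scalar).
#' @export
rmsd_from_expected <- function(p, expected) {
  pv <- if (inherits(p, "abundance_vector")) p$p else p
  match_names(names(pv), names(expected), "measured", "expected")
  sqrt(mean((pv[names(expected)] - as.numeric(expected))^2))
}

match_names <- function(a, b, what_a, what_b) {
  missing <- setdiff(b, a)
  extra <- setdiff(a, b)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop(what_a, " and ", what_b, " barcode sets differ (only in ",
         what_b, ": ", paste(missing, collapse = ", "), "; only in ",
         what_a, ": ", paste(extra, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Pearson correlation matrix across measurement methods
#'
#' Correlates per-barcode abundance vectors from different measurement
#' methods (e.g. PCR-free counting, digital PCR, amplicon measurements at
#' several PCR cycle numbers) pairwise. Optionally correlates `log10`
#' fractions instead of fractions.
#'
#' @param measurements named list (method labels) of at least 2 abundance
#'   vectors (`abundance_vector` or named numeric) over the same barcodes,
#'   each with at least 3 barcodes.
#' @param log10 correlate `log10(p)` instead of `p` (default `FALSE`).
#' @return A symmetric correlation matrix with unit diagonal, labelled by
#'   method.
#' @export
correlation_matrix <- function(measurements, log10 = FALSE) {
  if (length(measurements) < 2L) stop("need at least 2 measurement vectors")
  if (is.null(names(measurements))) stop("measurements must be labelled")
  vecs <- lapply(measurements, function(m) {
    if (inherits(m, "abundance_vector")) m$p else m
  })
  nm <- names(vecs[[1L]])
  if (length(nm) < 3L) stop("need at least 3 barcodes per vector")
  for (lab in names(vecs)) {
    match_names(names(vecs[[lab]]), nm, lab, names(vecs)[1L])
  }
  mat <- vapply(vecs, function(v) v[nm], numeric(length(nm)))
  if (log10) mat <- log10(mat)
  zero_var <- apply(mat, 2L, sd) == 0
  if (any(zero_var)) {
    stop("zero-variance measurement vector(s): ",
         paste(colnames(mat)[zero_var], collapse = ", "))
  }
  r <- cor(mat, method = "pearson")
  diag(r) <- 1
  r
}

#' Re-pooling volumes from a measured composition
#'
#' Given the measured relative abundances `p_i` of a pool and the target
#' composition `t_i`, the corrective volume of each stock (assumed at equal
#' concentration) is proportional to `t_i / p_i`, scaled to the requested
#' total volume. Re-measuring a pool mixed at these volumes moves the
#' composition toward the target.
#'
#' @param measured an `abundance_vector` with all `p_i > 0`.
#' @param target an [expected_composition()] over the same barcodes.
#' @param total_volume total volume to distribute (e.g. microlitres).
#' @return Named numeric vector of per-barcode volumes summing to
#'   `total_volume`.
#' @export
repooling_volumes <- function(measured, target, total_volume = 100) {
  pv <- if (inherits(measured, "abundance_vector")) measured$p else measured
  match_names(names(pv), names(target), "measured", "target")
  if (any(pv == 0)) {
    stop("cannot correct undetected construct(s): ",
         paste(names(pv)[pv == 0], collapse = ", "))
  }
  w <- as.numeric(target) / pv[names(target)]
  w / sum(w) * total_volume
}

#' Per-enzyme-group read accounting for multiplexed digests
#'
#' For a pool whose constructs are flanked by different (orthogonal)
#' restriction-enzyme sites, a digest with one enzyme should release only its
#' own group's cassettes. This report partitions the mapped (assigned) reads
#' of a count table by the reference's `enzyme_group` labels and computes the
#' fraction landing in the digested group (on-target) versus all other groups
#' (off-target).
#'
#' @param table a `count_table`.
#' @param ref the [barcode_reference()] used for counting, with
#'   `enzyme_group` set on every record.
#' @param digest enzyme label of the digest (must be one of the reference's
#'   groups).
#' @return A list with `digest`, `group_reads` (named vector over groups,
#'   summing to the mapped total), `mapped_reads`, `on_target_fraction` and
#'   `off_target_fraction`.
#' @export
enzyme_group_report <- function(table, ref, digest) {
  validate_count_table(table)
  groups <- ref$records$enzyme_group
  if (any(is.na(groups))) {
    stop("every reference record needs an enzyme_group for this report")
  }
  if (!digest %in% groups) {
    stop("digest label '", digest, "' is not an enzyme group of the ",
         "reference (groups: ", paste(unique(groups), collapse = ", "), ")")
  }
  counts <- table$counts[ref$records$name]
  mapped <- sum(counts)
  if (mapped == 0L) {
    stop("no mapped reads in sample '", table$sample_id,
         "': on/off-target fractions undefined")
  }
  group_reads <- tapply(counts, groups, sum)
  on_target <- as.numeric(group_reads[digest]) / mapped
  list(
    digest = digest,
    group_reads = setNames(as.integer(group_reads), names(group_reads)),
    mapped_reads = as.integer(mapped),
    on_target_fraction = on_target,
    off_target_fraction = 1 - on_target
  )
}
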