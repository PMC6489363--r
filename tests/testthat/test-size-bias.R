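# Build a count table directly from chosen S/N counts for a design.
table_from_counts <- function(design, S, N, id = "manual") {
  e <- design$entries
  counts <- setNames(as.integer(c(S, N)),
                     c(e$standard_name, e$normalization_name))
  structure(list(sample_id = id, counts = counts,
                 unassigned_distance = 0L, unassigned_ambiguous = 0L,
                 unassigned_short = 0L, total_reads = sum(counts)),
            class = "count_table")
}

test_that("equal standard and normalization counts give a flat profile", {
  gen <- generate_size_standard_design(seed = 1)
  tab <- table_from_counts(gen$design, rep(5000, 30), rep(5000, 30))
  prof <- size_bias_profile(tab, gen$design)
  expect_equal(prof$points$E, rep(1, 30))
  expect_equal(prof$points$E_norm, rep(1, 30))
  expect_equal(nrow(prof$excluded), 0L)
})

test_that("normalization counts below the floor exclude the point, not the profile", {
  gen <- generate_size_standard_design(seed = 1)
  N <- rep(5000, 30); N[7] <- 0
  tab <- table_from_counts(gen$design, rep(5000, 30), N)
  prof <- size_bias_profile(tab, gen$design, min_norm_count = 100)
  expect_equal(nrow(prof$points), 29L)
  expect_equal(prof$excluded$standard_name,
               gen$design$entries$standard_name[7])
  expect_match(prof$excluded$reason, "below floor")
  expect_false(gen$design$entries$standard_name[7] %in%
                 prof$points$standard_name)
})

test_that("median of normalized efficiencies is exactly one", {
  gen <- generate_size_standard_design(seed = 2)
  for (seed in c(10, 20)) {
    tab <- simulate_clustered_counts(gen$design, depth = 2e5, seed = seed)
    prof <- size_bias_profile(tab, gen$design)
    expect_equal(median(prof$points$E_norm), 1)
  }
})

test_that("the profile recovers the generator's clustering weight", {
  gen <- generate_size_standard_design(seed = 3)
  depth <- 1e6
  tab <- simulate_clustered_counts(gen$design, depth = depth, seed = 4,
                                   weight_fn = function(L)
                                     cluster_weight(L, 400, 150))
  prof <- size_bias_profile(tab, gen$design)
  e <- gen$design$entries
  # truth: E_i = w(L_i) / w(164); E_norm_i = that over its median
  w <- cluster_weight(e$molecule_length, 400, 150)
  wn <- cluster_weight(164, 400, 150)
  truth <- (w / wn) / median(w / wn)
  idx <- match(prof$points$standard_name, e$standard_name)
  # 3-SE band via the delta method on the count ratio
  p_all <- c(w, rep(wn, 30)) / sum(c(w, rep(wn, 30)))
  ES <- depth * p_all[seq_len(30)]
  EN <- depth * p_all[30 + seq_len(30)]
  se <- truth[idx] * sqrt(1 / ES[idx] + 1 / EN[idx])
  expect_true(all(abs(prof$points$E_norm - truth[idx]) <= 3 * se + 0.01))
  # monotone weight => monotone profile up to noise
  expect_lt(cor(prof$points$E_norm, prof$points$molecule_length,
                method = "spearman"), -0.95)
})

test_that("per-plasmid copy-number perturbations cancel in the efficiency ratio", {
  gen <- generate_size_standard_design(seed = 5)
  e <- gen$design$entries
  m <- setNames(withr::with_seed(6, runif(30, 0.5, 2)), e$standard_name)
  depth <- 1e6
  tab <- simulate_clustered_counts(gen$design, depth = depth, seed = 7,
                                   copy_number = m)
  prof <- size_bias_profile(tab, gen$design)
  w <- cluster_weight(e$molecule_length)
  truth_E <- w / cluster_weight(164)
  idx <- match(prof$points$standard_name, e$standard_name)
  mw <- m * w
  p_all <- c(mw, m * cluster_weight(164)) / sum(c(mw, m * cluster_weight(164)))
  ES <- depth * p_all[seq_len(30)]
  EN <- depth * p_all[30 + seq_len(30)]
  se <- truth_E[idx] * sqrt(1 / ES[idx] + 1 / EN[idx])
  expect_true(all(abs(prof$points$E - truth_E[idx]) <= 3 * se + 0.005))
})

test_that("a profile compared against itself is flat", {
  gen <- generate_size_standard_design(seed = 8)
  tab <- simulate_clustered_counts(gen$design, depth = 2e5, seed = 9)
  prof <- size_bias_profile(tab, gen$design, run_id = "runA")
  prof2 <- prof; prof2$run_id <- "runA_copy"
  cmp <- compare_profiles(list(prof, prof2))
  expect_equal(cmp$by_length$ratio, rep(1, 30))
  expect_equal(cmp$by_length$cv, rep(0, 30))
  expect_equal(cmp$max_fold_difference, 1)
})

test_that("platforms with different half-lengths diverge with molecule length", {
  gen <- generate_size_standard_design(seed = 10)
  e <- gen$design$entries
  depth <- 1e6
  pa <- size_bias_profile(simulate_clustered_counts(
    gen$design, depth, seed = 11,
    weight_fn = function(L) cluster_weight(L, 400, 150)), gen$design,
    run_id = "A")
  pb <- size_bias_profile(simulate_clustered_counts(
    gen$design, depth, seed = 12,
    weight_fn = function(L) cluster_weight(L, 150, 150)), gen$design,
    run_id = "B")
  cmp <- compare_profiles(list(pa, pb))
  by_len <- cmp$by_length
  # closed form: ratio R(L) proportional to 2^(L (1/150 - 1/400)), so the
  # between-platform ratio grows monotonically with L ...
  med_ratio <- vapply(split(by_len$ratio, by_len$molecule_length), median,
                      numeric(1))
  expect_true(all(diff(med_ratio) > 0))
  # ... and the fold relative to the smallest length exceeds 10 by 1200 bp
  fold_vs_150 <- med_ratio / med_ratio[["150"]]
  expect_gt(fold_vs_150[["1200"]], 10)
  closed_form <- 2^((1200 - 150) * (1 / 150 - 1 / 400))
  expect_equal(unname(fold_vs_150[["1200"]]), closed_form,
               tolerance = 0.1)
  expect_gt(cmp$max_fold_difference, 10)
})

test_that("small-fragment depletion shows as a reduced ratio at that length", {
  gen <- generate_size_standard_design(seed = 13)
  depth <- 1e6
  fresh_w <- function(L) cluster_weight(L, 400, 150)
  frozen_w <- function(L) ifelse(L == 150, 0.3, 1) * fresh_w(L)
  fresh <- size_bias_profile(simulate_clustered_counts(
    gen$design, depth, seed = 14, weight_fn = fresh_w), gen$design,
    run_id = "fresh")
  frozen <- size_bias_profile(simulate_clustered_counts(
    gen$design, depth, seed = 15, weight_fn = frozen_w), gen$design,
    run_id = "frozen")
  cmp <- compare_profiles(list(frozen, fresh))
  by_len <- cmp$by_length
  # expected ratio at 150 bp: 0.3 times the ratio of the two profile medians
  e <- gen$design$entries
  wf <- fresh_w(e$molecule_length) / fresh_w(164)
  wz <- frozen_w(e$molecule_length) / frozen_w(164)
  expected_150 <- (wz[1] / median(wz)) / (wf[1] / median(wf))
  at150 <- by_len$ratio[by_len$molecule_length == 150]
  expect_equal(median(at150), expected_150, tolerance = 0.05)
  expect_lt(median(at150), 0.5)
  # other lengths shift up by the renormalization (to median(wf)/median(wz))
  above <- by_len$ratio[by_len$molecule_length > 150]
  expect_equal(median(above), median(wf) / median(wz), tolerance = 0.05)
  expect_gt(median(above), 1)
})

test_that("profile comparison needs 3 shared points and profiles round-trip", {
  gen <- generate_size_standard_design(sizes_per_backbone = 2, seed = 16)
  tab <- simulate_clustered_counts(gen$design, depth = 5e4, seed = 17)
  prof <- size_bias_profile(tab, gen$design, run_id = "rt")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, tsv)
  back <- read_profile(tsv)
  expect_equal(back$run_id, "rt")
  expect_equal(back$points$E_norm, prof$points$E_norm)

  few <- prof
  few$points <- few$points[1:2, ]
  expect_error(compare_profiles(list(few, few)), "at least 3")
})
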