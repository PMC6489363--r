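test_that("coefficient of variation matches closed forms and a two-pass oracle", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(4, 5, 6)), 0.2)
  # independent two-pass implementation
  oracle_cv <- function(x) {
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    sqrt(v) / m
  }
  set.seed(42)
  for (i in 1:20) {
    x <- runif(sample(2:10, 1), 0.1, 10)
    expect_equal(coefficient_of_variation(x), oracle_cv(x),
                 tolerance = 1e-12)
  }
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(0, 0)), "mean")
})

make_abundance <- function(p, id = "s") {
  structure(list(sample_id = id, p = p, n_assigned = 1000L),
            class = "abundance_vector")
}

test_that("replicate CV is zero for identical replicates and errors on set mismatch", {
  p <- setNames(rep(0.25, 4), paste0("B", 1:4))
  r <- replicate_cv(list(make_abundance(p), make_abundance(p),
                         make_abundance(p)))
  expect_equal(unname(r$per_barcode), rep(0, 4))
  expect_equal(r$average_cv, 0)

  q <- setNames(rep(1 / 3, 3), paste0("B", 1:3))
  expect_error(replicate_cv(list(make_abundance(p), make_abundance(q))),
               "differ")
})

test_that("doubling one barcode in one replicate gives the formula CV", {
  k <- 10
  p1 <- setNames(rep(1 / k, k), paste0("B", 1:k))
  w <- rep(1 / k, k); w[1] <- 2 / k
  p2 <- setNames(w / sum(w), names(p1))
  r <- replicate_cv(list(make_abundance(p1), make_abundance(p2)))
  # expected from the definition, computed independently per barcode
  for (i in seq_len(k)) {
    x <- c(p1[i], p2[i])
    expected <- sqrt(sum((x - mean(x))^2)) / mean(x)  # n-1 = 1
    expect_equal(unname(r$per_barcode[i]), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("RMSD from expected matches closed forms and a loop oracle", {
  t2 <- expected_composition(c(a = 0.5, b = 0.5))
  expect_equal(rmsd_from_expected(c(a = 0.5, b = 0.5), t2), 0)
  # target given as a plain named vector (sub-pool of a larger design)
  expect_equal(rmsd_from_expected(c(a = 0.06, b = 0.04),
                                  c(a = 0.05, b = 0.05)),
               0.01, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:10) {
    k <- sample(3:20, 1)
    p <- runif(k); p <- p / sum(p); names(p) <- paste0("x", 1:k)
    tt <- runif(k); tt <- tt / sum(tt); names(tt) <- names(p)
    oracle <- {
      s <- 0
      for (j in 1:k) s <- s + (p[j] - tt[j])^2
      sqrt(s / k)
    }
    expect_equal(rmsd_from_expected(p, expected_composition(tt)),
                 unname(oracle), tolerance = 1e-12)
  }
})

test_that("correlation matrix is Pearson, symmetric, unit-diagonal, affine-invariant", {
  set.seed(3)
  v <- runif(10, 0.01, 0.2); names(v) <- paste0("B", 1:10)
  m <- correlation_matrix(list(a = v, b = 2 * v + 0.01, c = -3 * v + 1))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m, t(m))
  # direct covariance-formula oracle
  w <- runif(10); names(w) <- names(v)
  r <- correlation_matrix(list(a = v, b = w))["a", "b"]
  oracle <- {
    num <- sum((v - mean(v)) * (w - mean(w)))
    num / sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  }
  expect_equal(r, oracle, tolerance = 1e-10)
  expect_error(correlation_matrix(list(a = v, b = setNames(rep(1, 10),
                                                           names(v)))),
               "zero-variance.*b")
})

test_that("correlation matrices are positive semidefinite on random fixtures", {
  set.seed(11)
  for (i in 1:5) {
    vecs <- lapply(1:4, function(j) {
      x <- runif(8, 0.01, 1); names(x) <- paste0("B", 1:8); x
    })
    names(vecs) <- paste0("m", 1:4)
    m <- correlation_matrix(vecs)
    expect_true(all(eigen(m, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-8))
  }
})

test_that("re-pooling volumes correct measured deviations as t/p", {
  k <- 4
  even <- even_composition(paste0("B", 1:k))
  measured_even <- make_abundance(setNames(rep(1 / k, k), names(even)))
  v <- repooling_volumes(measured_even, even, total_volume = 100)
  expect_equal(unname(v), rep(25, k))

  skew <- c(0.10, 0.05, 0.05, 0.05)
  measured <- make_abundance(setNames(skew / sum(skew), names(even)))
  v2 <- repooling_volumes(measured, even, total_volume = 100)
  expect_equal(unname(v2[1] / v2[2]), 0.5, tolerance = 1e-12)

  zero <- make_abundance(setNames(c(0, 1 / 3, 1 / 3, 1 / 3), names(even)))
  expect_error(repooling_volumes(zero, even), "undetected")
})

test_that("enzyme-group report partitions mapped reads and guards edge cases", {
  groups <- rep(c("MlyI", "BsmI", "BtsI", "BsrDI"), each = 3)
  ref <- random_reference(12, seed = 19)
  ref$records$enzyme_group <- groups
  counts <- setNames(rep(0L, 12), ref$records$name)
  counts[groups == "MlyI"] <- c(3000L, 3200L, 3300L)   # 9500 on-target
  counts[groups == "BtsI"] <- c(200L, 150L, 150L)      # 500 off-target
  tab <- structure(list(sample_id = "digestMlyI", counts = counts,
                        unassigned_distance = 0L, unassigned_ambiguous = 0L,
                        unassigned_short = 0L, total_reads = 10000L),
                   class = "count_table")
  rep <- enzyme_group_report(tab, ref, "MlyI")
  expect_equal(rep$off_target_fraction, 0.05, tolerance = 1e-12)
  expect_equal(rep$on_target_fraction + rep$off_target_fraction, 1)
  expect_equal(sum(rep$group_reads), rep$mapped_reads)

  only_own <- tab
  only_own$counts[groups != "MlyI"] <- 0L
  only_own$total_reads <- sum(only_own$counts)
  expect_equal(enzyme_group_report(only_own, ref,
                                   "MlyI")$on_target_fraction, 1)

  none <- tab
  none$counts[] <- 0L
  none$total_reads <- 0L
  expect_error(enzyme_group_report(none, ref, "MlyI"), "no mapped reads")
  expect_error(enzyme_group_report(tab, ref, "EcoRI"), "not an enzyme group")
})

test_that("pool statistics are invariant under barcode reordering", {
  set.seed(23)
  p <- runif(8, 0.05, 0.2); p <- p / sum(p); names(p) <- paste0("B", 1:8)
  q <- runif(8, 0.05, 0.2); q <- q / sum(q); names(q) <- names(p)
  tt <- even_composition(names(p))
  perm <- sample(8)
  expect_equal(rmsd_from_expected(p, tt),
               rmsd_from_expected(p[perm], tt))
  r1 <- replicate_cv(list(make_abundance(p), make_abundance(q)))
  r2 <- replicate_cv(list(make_abundance(p[perm]), make_abundance(q[perm])))
  expect_equal(r1$average_cv, r2$average_cv)
  expect_equal(r1$per_barcode[names(p)], r2$per_barcode[names(p)])
})
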