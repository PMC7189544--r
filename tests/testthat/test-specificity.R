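test_that("tau closed forms hold", {
  expect_equal(tau_index(rep(7, 10)), 0)            # uniform
  expect_equal(tau_index(c(5, 0, 0, 0)), 1)         # single tissue
  expect_equal(tau_index(c(1, 0.5, 0)), 0.75)       # (0 + 0.5 + 1) / 2
  expect_error(tau_index(c(0, 0, 0)), "all-zero")
  expect_error(tau_index(5), ">= 2")
})

test_that("tau agrees with direct formula evaluation on random profiles", {
  set.seed(8)
  for (i in 1:500) {
    v <- runif(sample(2:40, 1)) * 10^runif(1, -2, 3)
    direct <- sum(1 - v / max(v)) / (length(v) - 1)
    expect_equal(tau_index(v), direct, tolerance = 1e-12)
  }
})

test_that("tau is scale-invariant and monotone under mass transfer", {
  set.seed(9)
  for (i in 1:50) {
    v <- runif(12)
    expect_equal(tau_index(v * runif(1, 0.01, 100)), tau_index(v), tolerance = 1e-12)
    # move mass from a low tissue to the maximal tissue
    w <- v
    lo <- which.min(w); hi <- which.max(w)
    d <- w[lo] * runif(1)
    w[lo] <- w[lo] - d; w[hi] <- w[hi] + d
    expect_gte(tau_index(w), tau_index(v) - 1e-12)
  }
})

test_that("max-gap binarization finds the gap and resolves ties upward", {
  bp <- binary_pattern(c(a = 10, b = 9, c = 1, d = 0.5))
  expect_equal(bp$pattern, c(a = 1L, b = 1L, c = 0L, d = 0L))
  expect_equal(bp$gap, 8)
  expect_equal(binary_pattern(c(x = 5, y = 0))$pattern, c(x = 1L, y = 0L))
  expect_error(binary_pattern(c(1, 1, 1)), "no gap")
  # two equal maximal gaps: the one nearer the top wins (fewer overexpressing)
  bp2 <- binary_pattern(c(a = 10, b = 6, c = 2))   # gaps 4, 4
  expect_equal(sum(bp2$pattern), 1L)
  expect_equal(bp2$overexpressing, "a")
  # exhaustive small-vector check of the tie policy against a naive oracle
  grids <- expand.grid(v1 = 0:3, v2 = 0:3, v3 = 0:3, v4 = 0:3)
  for (r in seq_len(nrow(grids))) {
    v <- as.numeric(grids[r, ])
    names(v) <- letters[1:4]
    if (diff(range(v)) == 0) next
    sorted <- sort(v, decreasing = TRUE)
    gaps <- -diff(sorted)
    k <- unname(which.max(gaps))    # which.max returns the first (topmost)
    expect_equal(sum(binary_pattern(v)$pattern), k)
  }
  # invariance to tissue ordering
  set.seed(10)
  v <- c(a = 9, b = 4, c = 2, d = 7, e = 0)
  for (i in 1:5) {
    p <- sample(5)
    expect_equal(binary_pattern(v[p])$pattern[names(v)], binary_pattern(v)$pattern)
  }
})

test_that("restricted calling applies threshold, floor and specificity flag", {
  m <- matrix(c(
    100, 2, 2, 2,       # restricted, tissue-specific
    5, 5, 5, 5,         # uniform
    0.5, 0.01, 0, 0,    # high tau but below the 1-TPM floor
    0, 0, 0, 0),        # unscoreable
    4, 4, byrow = TRUE,
    dimnames = list(c("res", "hk", "trace", "zero"), paste0("t", 1:4)))
  calls <- call_restricted(expr_tbl(m))
  expect_equal(calls$feature_id, "res")
  expect_true(calls$tissue_specific)
  expect_equal(calls$overexpressing[[1]], "t1")
  # floor disabled picks up the trace feature too
  calls0 <- call_restricted(expr_tbl(m), floor = 0)
  expect_setequal(calls0$feature_id, c("res", "trace"))
  # threshold 0 returns every scoreable non-constant feature
  callsT0 <- call_restricted(expr_tbl(m), tau_threshold = 0, floor = 0)
  expect_setequal(callsT0$feature_id, c("res", "trace"))
  at <- attr(calls, "all_tau")
  expect_true(is.na(at$tau[at$feature_id == "zero"]))
})

test_that("planted restricted families are recovered exactly on the panel", {
  tp <- small_panel()
  prof <- median_profile(tp$expression, tp$sample_to_tissue)
  calls <- call_restricted(prof)
  restricted <- tp$truth$family[tp$truth$type == "restricted"]
  housekeeping <- tp$truth$family[tp$truth$type == "housekeeping"]
  expect_setequal(intersect(calls$feature_id, restricted), restricted)
  expect_length(intersect(calls$feature_id, housekeeping), 0)
  for (i in seq_len(nrow(calls))) {
    planted <- tp$truth$tissues[[match(calls$feature_id[i], tp$truth$family)]]
    expect_setequal(calls$overexpressing[[i]], planted)
  }
})

test_that("group enrichment matches hand-computed chi-squared", {
  fams <- tibble::tibble(
    family = sprintf("f%02d", 1:30),
    group = rep(c("LINE", "LTR", "SINE"), each = 10))
  restricted <- tibble::tibble(feature_id = sprintf("f%02d", 11:16))  # all LTR
  enr <- group_enrichment(restricted, fams)
  expect_equal(unname(enr$observed), c(0, 6, 0))
  expect_equal(unname(enr$expected), c(2, 2, 2))
  expect_equal(enr$test$statistic, (0 - 2)^2 / 2 * 2 + (6 - 2)^2 / 2)  # = 12
  expect_error(group_enrichment(tibble::tibble(feature_id = "nope"), fams),
               "empty restricted")
  expect_error(group_enrichment(restricted,
                                dplyr::mutate(fams, group = "LTR")),
               "degenerate")
})

test_that("null-drawn restricted sets give roughly uniform enrichment p", {
  set.seed(12)
  fams <- tibble::tibble(family = sprintf("f%03d", 1:90),
                         group = rep(c("LINE", "LTR", "SINE"), 30))
  ps <- vapply(1:200, function(i) {
    group_enrichment(tibble::tibble(feature_id = sample(fams$family, 30)),
                     fams)$test$p
  }, numeric(1))
  # a calibrated null: p should not pile up near 0
  expect_gt(mean(ps > 0.05), 0.85)
  expect_gt(mean(ps < 0.5), 0.25)
})
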