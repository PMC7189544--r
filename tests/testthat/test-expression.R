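test_that("aggregation sums members and conserves per-sample totals", {
  m <- matrix(c(2, 3.5, 1, 4, 0.5, 2), 3, 2,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  tbl <- expr_tbl(m)
  agg <- aggregate_expression(tbl, c(t1 = "famA", t2 = "famA", t3 = "famB"))
  expect_equal(agg$s1[agg$feature_id == "famA"], 5.5)
  expect_equal(agg$s1[agg$feature_id == "famB"], 1)
  # single-member group equals the member row
  expect_equal(agg$s2[agg$feature_id == "famB"], m["t3", "s2"])
  # conservation under a partition, random tables
  set.seed(1)
  for (i in 1:5) {
    rm <- matrix(runif(40), 10, 4,
                 dimnames = list(sprintf("tx%02d", 1:10), sprintf("s%d", 1:4)))
    map <- setNames(sample(c("a", "b", "c"), 10, replace = TRUE), rownames(rm))
    agg2 <- aggregate_expression(expr_tbl(rm), map)
    expect_equal(colSums(as.matrix(agg2[-1])), colSums(rm))
  }
  # unmapped ids are reported, not silently grouped
  expect_warning(a3 <- aggregate_expression(tbl, c(t1 = "famA", t2 = "famA")),
                 "missing")
  expect_equal(attr(a3, "unmapped"), "t3")
})

test_that("median profile follows the even-count convention", {
  m <- matrix(c(1, 3, 100, 1, 3, 7), 1, 6,
              dimnames = list("f1", sprintf("s%d", 1:6)))
  s2t <- c(s1 = "liver", s2 = "liver", s3 = "liver",
           s4 = "lung", s5 = "lung", s6 = "brain")
  prof <- median_profile(expr_tbl(m), s2t)
  expect_equal(prof$liver, 3)    # odd count
  expect_equal(prof$lung, 2)     # even count: mean of central pair
  expect_equal(prof$brain, 7)    # single sample
  expect_error(median_profile(expr_tbl(m), s2t[-6]), "tissue")
})

test_that("row Z-scores normalise rows and invert exactly", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "const"), c("t1", "t2", "t3")))
  z <- row_zscore(expr_tbl(m))
  expect_equal(as.numeric(z[z$feature_id == "a", -1]), c(-1, 0, 1))
  expect_equal(as.numeric(z[z$feature_id == "const", -1]), c(0, 0, 0))
  expect_equal(attr(z, "constant_rows"), "const")
  zm <- as.matrix(z[-1])
  expect_true(all(abs(rowMeans(zm)) < 1e-9))
  # un-scaling recovers the input exactly
  rec <- zm * attr(z, "row_sds") + attr(z, "row_means")
  expect_equal(unname(rec), unname(m))
})

test_that("quintile bins partition tissues with the 6,6,8,6,6 scheme at N = 32", {
  expect_equal(eremap:::quintile_sizes(32), c(6, 6, 8, 6, 6))
  expect_equal(eremap:::quintile_sizes(10), c(2, 2, 2, 2, 2))
  for (N in 5:40) expect_equal(sum(eremap:::quintile_sizes(N)), N)
  set.seed(2)
  m <- matrix(runif(3 * 32), 3, 32,
              dimnames = list(c("f1", "f2", "f3"), sprintf("t%02d", 1:32)))
  qr <- quintile_rank(expr_tbl(m))
  expect_equal(qr$bin_sizes, c(6, 6, 8, 6, 6))
  counts <- table(as.integer(as.matrix(qr$assignments[-1])[1, ]))
  expect_equal(as.integer(counts), c(6, 6, 8, 6, 6))
  # the tissue with the maximal median lands in the fifth quintile
  top <- colnames(m)[which.max(m[1, ])]
  expect_equal(qr$assignments[[top]][1], 5L)
  expect_equal(sum(qr$tally$n_top_quintile), 3L * 6L)
  # deterministic tie handling is flagged
  mt <- matrix(rep(c(1, 2), each = 16), 1, 32,
               dimnames = list("tied", sprintf("t%02d", 1:32)))
  qt <- quintile_rank(expr_tbl(mt))
  expect_true("tied" %in% qt$ties)
})

test_that("inter-individual SD uses n-1 and signals single-sample tissues", {
  m <- matrix(c(2, 2, 2, 0, 2, 9), 1, 6,
              dimnames = list("f", sprintf("s%d", 1:6)))
  s2t <- c(s1 = "a", s2 = "a", s3 = "a", s4 = "b", s5 = "b", s6 = "c")
  sds <- interindividual_sd(expr_tbl(m), s2t)
  expect_equal(sds$a, 0)
  expect_equal(sds$b, sqrt(2))
  expect_true(is.na(sds$c))
})

test_that("tissue clustering reports calibrated bootstrap support", {
  set.seed(4)
  m <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(sprintf("f%03d", 1:200), sprintf("t%d", 1:6)))
  m <- cbind(m, t7 = m[, "t1"])    # duplicated tissue column
  z <- row_zscore(expr_tbl(m))
  cl <- cluster_tissues(z, n_boot = 200, seed = 1)
  expect_s3_class(cl, "ere_clust")
  expect_true(all(cl$support$support >= 0 & cl$support$support <= 1))
  dup <- cl$support[cl$support$members == "t1|t7", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$support, 1)     # duplicated columns always merge first
  expect_error(cluster_tissues(z, n_boot = 0), "n_boot")
  # deterministic given seed
  cl2 <- cluster_tissues(z, n_boot = 200, seed = 1)
  expect_identical(cl$support, cl2$support)
  nwk <- as_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(c("t1", "t7") %in% cl$hclust$labels))
  td <- generics::tidy(cl)
  expect_identical(td, cl$support)
})
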