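test_that("rphm follows the worked example exactly", {
  mcs <- paste(rep(c("ACG", "TAC", "GGA"), 3), collapse = "")  # 27 nt, 4 k-mers
  kmers <- substring(mcs, 1:4, 24:27)
  tab <- build_kmer_table(rep(kmers, c(5, 7, 3, 9)), k = 24)
  prof <- rphm_profile(mcs, list(s1 = tab), c(s1 = 2e8), c(s1 = "blood"))
  expect_equal(prof$samples$r_overlap, 3L)        # min of {5, 7, 3, 9}
  expect_equal(prof$samples$rphm, 1.5)            # 3 / 2e8 * 1e8
  # scale invariance: doubling depth with proportional counts
  tab2 <- build_kmer_table(rep(kmers, 2 * c(5, 7, 3, 9)), k = 24)
  prof2 <- rphm_profile(mcs, list(s1 = tab2), c(s1 = 4e8), c(s1 = "blood"))
  expect_equal(prof2$samples$rphm, 1.5)
  # an absent k-mer zeroes rphm
  tab3 <- build_kmer_table(rep(kmers[-2], c(5, 3, 9)), k = 24)
  prof3 <- rphm_profile(mcs, list(s1 = tab3), c(s1 = 2e8), c(s1 = "blood"))
  expect_equal(prof3$samples$rphm, 0)
  expect_error(rphm_profile(mcs, list(), c(s1 = 1), c(s1 = "b")), "empty")
})

test_that("the 10-rphm significance flag flips exactly at the threshold", {
  mcs <- paste(rep(c("ACG", "TAC", "GGA"), 3), collapse = "")
  kmers <- substring(mcs, 1:4, 24:27)
  # one sample per tissue: mean log10(rphm + 1) = log10(rphm + 1)
  tab_at <- function(n) build_kmer_table(rep(kmers, rep(n, 4)), k = 24)
  at_rphm <- function(r) {
    rphm_profile(mcs, list(s1 = tab_at(r)), c(s1 = 1e8), c(s1 = "t"))$tissues
  }
  expect_false(at_rphm(10)$significant)   # exactly 10 is not "> 10"
  expect_true(at_rphm(11)$significant)
  lin <- rphm_profile(mcs, list(s1 = tab_at(10)), c(s1 = 1e8), c(s1 = "t"),
                      scale = "linear")
  expect_false(lin$tissues$significant)
})

test_that("amino-acid composition sums to one with the documented bins", {
  f <- aa_frequencies("AAAA")
  expect_equal(f$frequency[f$aa == "A"], 1)
  expect_equal(sum(f$frequency), 1)
  f2 <- aa_frequencies(c("AC", "CA"))
  expect_equal(f2$frequency[f2$aa %in% c("A", "C")], c(0.5, 0.5))
  set.seed(20)
  f3 <- aa_frequencies(eremap:::random_peptides(50, 9))
  expect_equal(sum(f3$frequency), 1, tolerance = 1e-12)
  expect_error(aa_frequencies(character(0)), "empty")
  # positional frequencies: 9-mers all starting with M
  peps <- paste0("M", eremap:::random_peptides(5, 8))
  pos <- positional_aa_frequencies(peps, lengths = 9)
  expect_equal(pos$frequency[pos$position == 1 & pos$aa == "M"], 1)
  sums <- dplyr::summarise(dplyr::group_by(pos, position),
                           s = sum(frequency))$s
  expect_equal(sums, rep(1, 9))
  # an 11-mer bin with 2 peptides is dropped and reported
  mix <- c(eremap:::random_peptides(6, 9), eremap:::random_peptides(2, 11))
  pf <- positional_aa_frequencies(mix, lengths = c(9, 11))
  expect_equal(sort(unique(pf$length)), 9)
  expect_equal(attr(pf, "dropped_lengths"), 11)
})

test_that("the embedded PAM30 equals the reference copy", {
  data(PAM30, package = "Biostrings", envir = environment())
  aa <- rownames(pam30_matrix())
  expect_identical(pam30_matrix(), PAM30[aa, aa])
})

test_that("Smith-Waterman equals exhaustive enumeration on tiny peptides", {
  mat <- pam30_matrix()
  expect_equal(local_align("MKLVQWERT", "MKLVQWERT")$matches, 9L)
  expect_equal(local_align("MKLVQWERT", "MKLVQWERT")$alignment_length, 9L)
  # disjoint alphabets with all-negative scores: empty local alignment
  empty <- local_align("WWWW", "DDDD")
  expect_equal(empty$score, 0)
  expect_equal(empty$alignment_length, 0L)
  set.seed(21)
  alpha <- c("A", "R", "N", "D", "C", "Q")   # reduced 6-letter alphabet
  for (i in 1:12) {
    a <- paste(sample(alpha, sample(2:4, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(2:4, 1), replace = TRUE), collapse = "")
    expect_equal(local_align(a, b)$score,
                 oracle_local_align(a, b, mat, 5, 2), label = paste(a, b))
  }
})

test_that("percent identity implements matches over peptide length", {
  db <- c("SIINFEKL", "MKLVQWERT", "AAAAAAAA")
  expect_equal(percent_identity("SIINFEKL", db), 100)    # verbatim member
  set.seed(22)
  for (i in 1:20) {
    q <- eremap:::random_peptides(1, 9)
    pid <- percent_identity(q, db)
    expect_gte(pid, 0); expect_lte(pid, 100)
    if (pid == 100) expect_true(q %in% db)               # 100 iff verbatim
  }
  # worked case: best hit aligns 8 positions with 6 identities on a 9-mer
  al <- local_align("MKLVQWERT", "MKLAQWER")
  expect_equal(al$matches / 9 * 100, percent_identity("MKLVQWERT", "MKLAQWER"),
               tolerance = 1e-12)
  # the literal published scaling multiplies by a further 100
  expect_equal(percent_identity("SIINFEKL", db, mmax_as_percentage = TRUE), 1e4)
  expect_error(percent_identity("SIINFEKL", character(0)), "empty")
})

test_that("viral homology bootstrap is deterministic with sound reporting", {
  set.seed(23)
  viral <- eremap:::random_peptides(15, 9)
  pool <- eremap:::random_peptides(40, 9)
  vt1 <- viral_homology_test(pool[1:10], pool[11:40], viral, n_boot = 100, seed = 9)
  vt2 <- viral_homology_test(pool[1:10], pool[11:40], viral, n_boot = 100, seed = 9)
  expect_identical(vt1$p, vt2$p)
  expect_length(vt1$boot_means, 100)
  # queries that are verbatim viral members beat every bootstrap group
  vt3 <- viral_homology_test(viral[1:10], pool, viral, n_boot = 50, seed = 1)
  expect_equal(vt3$observed_mean, 100)
  expect_equal(vt3$p, 0)
  expect_match(capture.output(print(vt3))[1], "< 0.02")   # reported as < 1/n_boot
  expect_error(viral_homology_test(pool, pool[1:3], viral), "smaller")
})

test_that("methylation correlation respects the 5000-nt window boundary", {
  rphm <- setNames(seq(0, 98, by = 2), sprintf("s%02d", 1:50))
  locus <- list(chrom = "chr1", start = 50000L, end = 50027L)
  probes <- tibble::tibble(
    probe_id = c("edge_in", "edge_out", "other_chrom"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(50026L + 5000L, 50026L + 5001L, 50000L))
  probes[names(rphm)] <- as.data.frame(matrix(runif(150), nrow = 3))
  res <- methylation_correlation(rphm, probes, locus)
  expect_equal(res$probe_id, "edge_in")
  # no probe in window: empty result, not an error
  res2 <- methylation_correlation(rphm, probes[2, ], locus)
  expect_equal(nrow(res2), 0L)
  expect_error(methylation_correlation(rphm[1:2], probes, locus), ">= 3")
})
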