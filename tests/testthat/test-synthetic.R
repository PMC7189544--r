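test_that("generators are deterministic given the seed", {
  g1 <- make_genome(repeat_families = 6, copies_per_family = 6, n_straddle = 2,
                    seed = 99)
  g2 <- make_genome(repeat_families = 6, copies_per_family = 6, n_straddle = 2,
                    seed = 99)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$repeats, g2$repeats)
  p1 <- make_tissue_panel(n_tissues = 6, n_families = 30, n_restricted = 3, seed = 4)
  p2 <- make_tissue_panel(n_tissues = 6, n_families = 30, n_restricted = 3, seed = 4)
  expect_identical(p1$expression, p2$expression)
  r1 <- make_blcl_readset(small_genome(), n_pairs = 3000, seed = 5)
  r2 <- make_blcl_readset(small_genome(), n_pairs = 3000, seed = 5)
  expect_identical(r1$alignments, r2$alignments)
  expect_identical(r1$psms, r2$psms)
})

test_that("genome structure honours divergence and context geometry", {
  g0 <- make_genome(repeat_families = 6, copies_per_family = 6, divergence = 0,
                    n_straddle = 2, seed = 3)
  # divergence 0: every copy is the consensus (up to strand)
  for (i in sample(nrow(g0$repeats), 10)) {
    r <- g0$repeats[i, ]
    seq <- substr(g0$genome$sequence[match(r$chrom, g0$genome$name)],
                  r$start + 1, r$end)
    expected <- if (r$strand == "+") g0$consensus[[r$family]] else
      eremap::revcomp(g0$consensus[[r$family]])
    expect_equal(seq, expected)
  }
  expect_error(make_genome(divergence = 0.5), "divergence")
  # default context mix matches the genome-wide intronic share
  gb <- small_genome()
  ctx <- table(gb$repeats$context)
  n_ctx <- sum(ctx[c("intronic", "intergenic", "exonic")])
  expect_equal(unname(ctx["intronic"]) / n_ctx, 0.51, tolerance = 0.02)
  # intronic copies sit inside a gene span but outside every exon
  spans <- eremap:::gene_spans(gb$genes)
  intronic <- gb$repeats[gb$repeats$context == "intronic", ]
  for (i in sample(nrow(intronic), 10)) {
    r <- intronic[i, ]
    expect_true(any(spans$start <= r$start & spans$end >= r$end))
    ex <- gb$genes[gb$genes$feature == "exon", ]
    expect_false(any(ex$start < r$end & ex$end > r$start))
  }
})

test_that("panel truth behaves at the tau limits", {
  # no restricted families: nothing reaches the call threshold
  p0 <- make_tissue_panel(n_tissues = 10, n_families = 40, n_restricted = 0,
                          samples_per_tissue = 3, seed = 6)
  prof <- median_profile(p0$expression, p0$sample_to_tissue)
  expect_equal(nrow(call_restricted(prof)), 0L)
  taus <- attr(call_restricted(prof), "all_tau")$tau
  expect_true(all(taus < 0.8, na.rm = TRUE))
  expect_true(all(taus <= 0.4 + 1e-9, na.rm = TRUE))  # housekeeping regime
  # a family expressed in exactly one tissue with zero elsewhere scores tau = 1
  expect_equal(tau_index(c(8, rep(0, 31))), 1)
  expect_error(make_tissue_panel(samples_per_tissue = 0), "samples_per_tissue")
  expect_error(make_tissue_panel(n_families = 5, n_restricted = 6),
               "n_restricted")
  # sample columns renormalise to 1e6
  expect_equal(unname(colSums(as.matrix(p0$expression[-1]))),
               rep(1e6, 30), tolerance = 1e-9)
})

test_that("methylation probes hit the target correlation and placement", {
  rphm <- setNames(runif(50, 0, 100), sprintf("s%02d", 1:50))
  locus <- list(chrom = "chr1", start = 10000L, end = 10027L)
  # rho = 1, no noise: downstream r = 1
  probes1 <- make_methylation(locus, rphm, rho = 1, seed = 2)
  res1 <- methylation_correlation(rphm, probes1, locus)
  expect_true(all(abs(res1$r - 1) < 1e-12))
  # probes beyond the window are excluded downstream
  expect_equal(nrow(res1), 3L)
  expect_true(all(res1$distance <= 5000))
  # rho = 0 at n = 50: |r| stays within sampling error
  probes0 <- make_methylation(locus, rphm, rho = 0, seed = 3)
  res0 <- methylation_correlation(rphm, probes0, locus)
  expect_true(all(abs(res0$r) < 0.3))
  expect_error(make_methylation(locus, rphm[1:2], rho = 0), ">= 3")
  expect_error(make_methylation(locus, rphm, rho = 2), "rho")
})

test_that("readset planting covers every case class with passing ranks", {
  rs <- small_readset()
  expect_error(make_blcl_readset(small_genome(), read_len = 20), "read_len")
  counts <- table(rs$truth$intended_verdict)
  expect_equal(unname(counts["ereMAP"]), 30)
  expect_equal(unname(counts["canonical"]), 30)
  expect_equal(unname(counts["ambiguous-keep"]) +
                 unname(counts["ambiguous-discard"]), 12)
  expect_equal(unname(counts["discard-oneread"]), 4)
  # decoys 1:1 with targets, reversed sequences
  expect_equal(sum(rs$psms$is_decoy), sum(!rs$psms$is_decoy))
  tg <- rs$psms$peptide[!rs$psms$is_decoy]
  dc <- rs$psms$peptide[rs$psms$is_decoy]
  rev_str <- function(x) vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  expect_setequal(dc, rev_str(tg))
  # planted peptides pass the binder filter
  planted <- rs$truth$peptide[rs$truth$intended_verdict != "not_called"]
  pr <- rs$psms[rs$psms$peptide %in% planted, ]
  expect_true(all(pr$best_rank[!pr$is_decoy] <= 2))
  # every planted ereMAP appears as a substring of the built ERE proteome
  part <- partition_reads(filter_alignments(rs$alignments), rs$repeats, rs$genes)
  prot <- build_ere_proteome(part$ere)
  mem <- proteome_contains(prot, rs$truth$peptide[rs$truth$intended_verdict == "ereMAP"])
  expect_true(all(mem$in_ere))
  # intended read support is planted exactly for controlled cases
  one <- rs$truth[rs$truth$intended_verdict == "discard-oneread", ]
  for (p in one$peptide) {
    hits <- find_peptide_mcs(prot, p)
    expect_equal(dplyr::n_distinct(hits$read_id), 1L)
  }
})
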