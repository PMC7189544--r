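psm_row <- function(peptide, score, is_decoy = FALSE, rank = 0.5,
                    sample = "s1") {
  tibble::tibble(peptide = peptide, sample = sample, score = score,
                 is_decoy = is_decoy, best_rank = rank)
}

test_that("target-decoy FDR picks the maximal passing threshold", {
  cand <- dplyr::bind_rows(
    psm_row(c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD", "EEEEEEEE"), c(10, 9, 8, 7)),
    psm_row(c("FFFFFFFF", "GGGGGGGG"), c(6, 5), is_decoy = TRUE))
  pass <- apply_fdr(cand, q = 0.05)
  expect_equal(nrow(pass), 4L)                      # 0/4 at t = 7
  expect_equal(attr(pass, "score_threshold"), 7)
  # a decoy outscoring every target empties the pass set at q = 0.05
  cand2 <- dplyr::bind_rows(
    psm_row(sprintf("AAAAAAA%s", LETTERS[1:10]), 10:1),
    psm_row("WWWWWWWW", 99, is_decoy = TRUE))
  expect_equal(nrow(apply_fdr(cand2, q = 0.05)), 0L)
  # q = 1 admits every target
  expect_equal(nrow(apply_fdr(cand2, q = 1)), 10L)
  expect_error(apply_fdr(psm_row("AAAAAAAA", 1)), "no decoys")
})

test_that("binder filter is inclusive at 2% and 8-11 residues", {
  cand <- dplyr::bind_rows(
    psm_row("AAAAAAAAA", 1, rank = 0.5),     # 9-mer, strong binder
    psm_row("CCCCCCCCCCCC", 1, rank = 0.1),  # 12-mer
    psm_row("DDDDDDDDD", 1, rank = 2.0),     # inclusive bound
    psm_row("EEEEEEEE", 1, rank = 2.01),     # just over
    psm_row("FFFFFFF", 1, rank = 0.1))       # 7-mer
  kept <- filter_binders(cand)
  expect_setequal(kept$peptide, c("AAAAAAAAA", "DDDDDDDDD"))
})

test_that("ERE status covers the four membership cases", {
  mem <- tibble::tibble(peptide = c("A", "B", "C", "D"),
                        in_ere = c(TRUE, FALSE, TRUE, FALSE),
                        in_canonical = c(FALSE, TRUE, TRUE, FALSE))
  st <- assign_status(mem)
  expect_equal(st$status, c("yes", "no", "maybe", "undetermined"))
})

test_that("MCS recovery maps peptides back to their coding nucleotides", {
  nt <- paste0(eremap:::reverse_translate("MKLVQWERT"), "TGG")
  reads <- tibble::tibble(read_id = c("r1", "r2"), sequence = c(nt, nt))
  prot <- build_ere_proteome(reads)
  hits <- find_peptide_mcs(prot, "MKLVQWERT")
  expect_true(all(hits$mcs == eremap:::reverse_translate("MKLVQWERT")))
  expect_setequal(unique(hits$read_id), c("r1", "r2"))
})

test_that("10x arbitration follows the worked ratios and read-support rule", {
  mcs27 <- eremap:::reverse_translate("MKLVQWERT")
  tab_of <- function(n) build_kmer_table(rep(mcs27, n), k = 24)
  # 50 vs 4: keep (50 >= 40)
  r1 <- resolve_maybe(mcs27, tab_of(50), tab_of(4), n_support_reads = 50)
  expect_true(r1$keep)
  # 9 vs 1: discard
  r2 <- resolve_maybe(mcs27, tab_of(9), tab_of(1), n_support_reads = 9)
  expect_false(r2$keep)
  expect_equal(r2$reason, "ratio_below_10x")
  # exactly 10x is kept (inclusive reading)
  expect_true(resolve_maybe(mcs27, tab_of(10), tab_of(1), 10)$keep)
  # one read of support: discard regardless of abundance
  r3 <- resolve_maybe(mcs27, tab_of(50), tab_of(0), n_support_reads = 1)
  expect_false(r3$keep)
  expect_equal(r3$reason, "insufficient_reads")
  # an MCS seen only in the canonical dataset discards the peptide
  other <- eremap:::reverse_translate("WWWWYYYYH")
  r4 <- resolve_maybe(c(mcs27, other), tab_of(50), build_kmer_table(rep(other, 3)),
                      n_support_reads = 50)
  expect_false(r4$keep)
  expect_equal(r4$reason, "mcs_canonical_only")
  # canonical absence means an infinite ratio: keep
  expect_true(resolve_maybe(mcs27, tab_of(2), tab_of(0), 2)$keep)
  expect_error(resolve_maybe("ACGT", tab_of(2), tab_of(0), 2), "shorter")
})

test_that("arbitration is monotone in ERE support", {
  mcs27 <- eremap:::reverse_translate("MKLVQWERT")
  can <- build_kmer_table(rep(mcs27, 3), k = 24)
  kept <- vapply(c(5, 15, 29, 30, 31, 60, 120), function(n) {
    resolve_maybe(mcs27, build_kmer_table(rep(mcs27, n), k = 24), can,
                  n_support_reads = n)$keep
  }, logical(1))
  # once keep, never flips back to discard as support grows
  expect_false(is.unsorted(kept))
  expect_equal(kept, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("I/L variant enumeration and expression comparison", {
  expect_length(eremap:::il_variants("NLVPMVATV"), 1L)   # one I/L position
  expect_length(eremap:::il_variants("AAAGGG"), 0L)
  expect_length(eremap:::il_variants("ILLI"), 15L)       # 2^4 - 1
  prot <- tibble::tibble(
    entry_id = c("can|T1", "can|T2"),
    aa = c("AANIVPMVATVAA", "AAQQQQQQQQQAA"),
    source = "canonical-transcript", read_id = NA_character_, frame = "F1",
    frame_nt = strrep("A", 39), aa_start = 0L,
    transcript_id = c("T1", "T2"), expression = c(50, 1))
  # variant NIVPMVATV present in canonical at higher expression: discard
  res <- il_variant_check("NLVPMVATV", prot, cand_read_support = 5,
                          ere_read_support = function(v) 0L)
  expect_false(res$keep)
  # no I/L: trivially kept
  res2 <- il_variant_check("AAQQWERTY", prot, 5, function(v) 0L)
  expect_true(res2$keep)
  # ERE-side variant at lower read support: kept
  res3 <- il_variant_check("QQQQWWWWI", prot, cand_read_support = 5,
                           ere_read_support = function(v) 2L)
  expect_true(res3$keep)
  # ERE-side variant at higher read support: discarded
  res4 <- il_variant_check("QQQQWWWWI", prot, cand_read_support = 1,
                           ere_read_support = function(v) 4L)
  expect_false(res4$keep)
})

test_that("the orientation decision tree follows all published branches", {
  d <- function(...) orientation_decision(...)
  expect_false(d("CDS", "sense", "sense", 1L)$keep)
  expect_true(d("CDS", "antisense", "sense", 1L)$keep)
  expect_true(d("intergenic", NA, "sense", 1L)$keep)
  expect_true(d("intergenic", NA, "antisense", 1L)$keep)
  # intronic: discard iff gene-sense AND ERE-antisense AND single locus
  expect_false(d("intronic", "sense", "antisense", 1L)$keep)
  expect_true(d("intronic", "sense", "antisense", 3L)$keep)
  expect_true(d("intronic", "sense", "sense", 1L)$keep)
  expect_true(d("intronic", "antisense", "antisense", 1L)$keep)
})

test_that("origin classification finds loci, regions and orientations", {
  rs <- small_readset()
  tr <- rs$truth[rs$truth$intended_verdict == "ereMAP", ]
  for (i in sample(nrow(tr), 6)) {
    cl <- classify_origin(tr$mcs[i], rs$repeats, rs$genes, rs$genome)
    expect_equal(cl$n_ere_loci, tr$n_ere_loci[i])
    expect_true(tr$region[i] %in% cl$loci$region)
    expect_true(tr$orientation_vs_ere[i] %in% cl$loci$sense_vs_ere)
    expect_true(tr$family[i] %in% cl$loci$family)
  }
  # a sequence absent from the genome has no locus
  none <- classify_origin(strrep("ACGT", 7), rs$repeats, rs$genes, rs$genome)
  expect_equal(none$n_loci_total + none$n_ere_loci, 0L)
})

test_that("non-redundant aggregation merges identical and keeps conflicts", {
  rec <- function(pep, sample, region) tibble::tibble(
    peptide = pep, sample = sample, status = "yes", family = "AluY",
    group = "SINE", region = region, orientation_vs_ere = "sense",
    orientation_vs_gene = "sense", n_ere_loci = 1L, n_support_reads = 3L,
    mcs = strrep("ACG", 9))
  records <- dplyr::bind_rows(
    rec("AAAAAAAA", "s1", "intronic"), rec("AAAAAAAA", "s2", "intronic"),
    rec("AAAAAAAA", "s3", "intronic"),
    rec("CCCCCCCC", "s1", "intronic"), rec("CCCCCCCC", "s2", "intergenic"),
    rec("DDDDDDDD", "s1", "intronic"))
  agg <- aggregate_nonredundant(records)
  a <- agg[agg$peptide == "AAAAAAAA", ]
  expect_equal(nrow(a), 1L)
  expect_equal(a$n_samples, 3L)
  expect_equal(a$samples, "s1,s2,s3")
  c2 <- agg[agg$peptide == "CCCCCCCC", ]
  expect_equal(nrow(c2), 2L)                       # conflicting region kept
  expect_equal(unique(c2$n_alternatives), 2L)
  expect_equal(dplyr::n_distinct(agg$peptide), 3L)
})
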