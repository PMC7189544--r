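test_that("flag filter accepts exactly 83/99/147/163 over all 4096 flags", {
  reads <- dplyr::bind_cols(
    tibble::tibble(read_id = sprintf("r%04d", 0:4095), flag = 0:4095,
                   chrom = "chr1", start = 0L, end = 50L, cigar = "50M",
                   sequence = strrep("A", 50)),
    decode_sam_flags(0:4095))
  kept <- filter_alignments(reads)
  expect_setequal(kept$flag, c(83L, 99L, 147L, 163L))
  # every flag intersecting the 3852 mask is rejected
  expect_true(all(bitwAnd(kept$flag, 3852L) == 0L))
})

test_that("read partitioning uses strict containment with canonical priority", {
  repeats <- tibble::tibble(chrom = "chr1", start = 99L, end = 300L, strand = "+",
                            element_name = "AluY#1", family = "AluY", group = "SINE")
  genes <- tibble::tibble(gene_id = "G1", transcript_id = "T1",
                          feature = c("exon", "CDS"),
                          chrom = "chr1", start = c(150L, 160L), end = c(400L, 380L),
                          strand = "+", overlapping_exons = FALSE)
  mk <- function(id, chrom, start) dplyr::bind_cols(
    tibble::tibble(read_id = id, flag = 99L, chrom = chrom, start = start,
                   end = start + 76L, cigar = "76M", sequence = strrep("A", 76)),
    decode_sam_flags(99L))
  reads <- dplyr::bind_rows(
    mk("in_repeat", "chr1", 100L),        # inside repeat, not inside exon
    mk("in_both", "chr1", 160L),          # inside repeat AND exon -> canonical
    mk("straddle", "chr1", 60L),          # half-overlaps the repeat boundary
    mk("in_exon", "chr1", 310L),          # exon only
    mk("nowhere", "chr1", 500L),          # outside annotation
    mk("offcontig", "chrZ", 10L))         # unknown contig
  part <- partition_reads(reads, repeats, genes)
  expect_equal(part$ere$read_id, "in_repeat")
  expect_setequal(part$canonical$read_id, c("in_both", "in_exon"))
  expect_setequal(part$discarded$read_id, c("straddle", "nowhere", "offcontig"))
  expect_equal(part$discarded$reason[part$discarded$read_id == "offcontig"],
               "unknown_contig")
  # disjointness and conservation
  ids <- c(part$ere$read_id, part$canonical$read_id, part$discarded$read_id)
  expect_equal(sort(ids), sort(reads$read_id))
  expect_length(intersect(part$ere$read_id, part$canonical$read_id), 0)
})

test_that("ambiguous-base segmentation returns maximal N-free runs", {
  seg <- segment_ambiguous("ACGTNNACGT")
  expect_equal(seg$segment, c("ACGT", "ACGT"))
  expect_equal(seg$offset, c(0L, 6L))
  expect_equal(segment_ambiguous("ACGT")$segment, "ACGT")
  expect_equal(nrow(segment_ambiguous("NNNN")), 0L)
})

test_that("six-frame translation equals the codon-table oracle", {
  expect_equal(unname(six_frame_translate("ATGAAA")[1]), "MK")
  expect_equal(unname(six_frame_translate("TTTCAT")[4]), "MK")  # revcomp frame
  set.seed(13)
  for (i in 1:50) {
    nt <- paste(sample(c("A", "C", "G", "T"), sample(3:60, 1), replace = TRUE),
                collapse = "")
    expect_equal(six_frame_translate(nt), oracle_six_frames(nt), label = nt)
  }
})

test_that("stop splicing keeps the prefix by default and splits behind a flag", {
  expect_equal(splice_at_stops("MKLVQWERT*AAA")$aa, "MKLVQWERT")
  expect_equal(nrow(splice_at_stops("MKL*VQWERTAAA")), 0L)   # prefix 3 < 8
  expect_equal(splice_at_stops("MKLVQWER")$aa, "MKLVQWER")   # no stop, 8 aa
  sp <- splice_at_stops("MKL*VQWERTAAA*AQWERTYK", mode = "split")
  expect_equal(sp$aa, c("VQWERTAAA", "AQWERTYK"))
  expect_equal(sp$aa_start, c(4L, 14L))
})

test_that("the ERE proteome equals a naive per-read oracle", {
  set.seed(14)
  seqs <- vapply(1:200, function(i) {
    s <- sample(c("A", "C", "G", "T"), sample(50:150, 1), replace = TRUE)
    s[runif(length(s)) < 0.01] <- "N"
    paste(s, collapse = "")
  }, character(1))
  reads <- tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                          sequence = seqs)
  prot <- build_ere_proteome(reads)
  expect_equal(sort(prot$aa), sort(oracle_ere_entries(seqs)))
  expect_false(any(grepl("*", prot$aa, fixed = TRUE)))
  expect_true(all(nchar(prot$aa) >= 8))
  expect_false(anyDuplicated(prot$entry_id) > 0)
  # each entry's frame_nt translates back to a sequence starting with its aa
  idx <- sample(nrow(prot), 20)
  for (i in idx) {
    back <- oracle_translate(prot$frame_nt[i])
    expect_equal(substr(back, prot$aa_start[i] + 1, prot$aa_start[i] + nchar(prot$aa[i])),
                 prot$aa[i])
  }
  # invariant to read input order (compare sorted provenance)
  prot2 <- build_ere_proteome(reads[rev(seq_len(nrow(reads))), ])
  k <- c("read_id", "frame", "aa", "aa_start")
  expect_equal(dplyr::arrange(prot[k], read_id, frame, aa_start),
               dplyr::arrange(prot2[k], read_id, frame, aa_start))
})

test_that("personalized proteome applies variant and expression rules", {
  tx <- tibble::tibble(
    name = c("T1", "T2", "T3"),
    sequence = c("GGGATGAAACCTTGGTAGGG",       # ATG at 4
                 "ATGTTTGGGTGA",               # expressed = 0 -> excluded
                 "ATGCCCAAATTTTAA"))
  tpm <- c(T1 = 5, T2 = 0, T3 = 1)
  prot <- build_personalized_proteome(tx, NULL, tpm)
  expect_setequal(prot$transcript_id, c("T1", "T3"))
  expect_equal(prot$aa[prot$transcript_id == "T1"], "MKPW")  # stops at TAG
  # alt_count < 5 is not applied; >= 5 is; synonymous changes nothing
  vars <- tibble::tibble(transcript_id = "T1", pos = c(7L, 10L),
                         ref = c("A", "C"), alt = c("C", "A"),
                         alt_count = c(4L, 9L))
  prot2 <- build_personalized_proteome(tx, vars, tpm)
  expect_equal(prot2$aa[prot2$transcript_id == "T1"], "MKTW")  # CCT -> ACT
  syn <- tibble::tibble(transcript_id = "T1", pos = 9L, ref = "A", alt = "G",
                        alt_count = 20L)   # AAA -> AAG, both K
  prot3 <- build_personalized_proteome(tx, syn, tpm)
  expect_equal(prot3$aa[prot3$transcript_id == "T1"], "MKPW")
  bad <- tibble::tibble(transcript_id = "T1", pos = 7L, ref = "G", alt = "C",
                        alt_count = 9L)
  expect_error(build_personalized_proteome(tx, bad, tpm), "mismatch")
  # explicit CDS start overrides the first-ATG rule
  prot4 <- build_personalized_proteome(tx["name" == "T1" | TRUE, ][1, ], NULL,
                                       tpm, cds_start = c(T1 = 7L))
  expect_equal(prot4$aa, "KPW")
})

test_that("proteome concatenation rejects id collisions and answers membership", {
  ere <- tibble::tibble(entry_id = "ere|1", aa = "MKLVQWERT", source = "ere-read",
                        read_id = "r1", frame = "F1", frame_nt = strrep("A", 27),
                        aa_start = 0L, transcript_id = NA_character_,
                        expression = NA_real_)
  can <- dplyr::mutate(ere, entry_id = "can|T1", aa = "AAAMKLVQAAA",
                       source = "canonical-transcript", read_id = NA_character_,
                       transcript_id = "T1", expression = 3)
  comb <- concat_proteomes(ere, can)
  expect_error(concat_proteomes(ere, dplyr::mutate(can, entry_id = "ere|1")),
               "collision")
  mem <- proteome_contains(comb, c("MKLVQWER", "MKLVQ", "WWWWWWWW"))
  expect_equal(mem$in_ere, c(TRUE, TRUE, FALSE))
  expect_equal(mem$in_canonical, c(FALSE, TRUE, FALSE))
  # agreement with a naive per-entry substring scan on random queries
  set.seed(15)
  prot <- build_ere_proteome(tibble::tibble(
    read_id = sprintf("r%d", 1:50),
    sequence = vapply(1:50, function(i)
      paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = ""),
      character(1))))
  queries <- c(substring(sample(prot$aa, 25), 1, 8),
               vapply(1:25, function(i)
                 paste(sample(rownames(pam30_matrix()), 8, replace = TRUE),
                       collapse = ""), character(1)))
  mem2 <- proteome_contains(prot, queries)
  naive <- vapply(toupper(queries), function(p)
    any(vapply(prot$aa, function(e) grepl(p, e, fixed = TRUE), logical(1))),
    logical(1), USE.NAMES = FALSE)
  expect_equal(mem2$in_ere, naive)
})
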