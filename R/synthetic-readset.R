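# Synthetic B-LCL-like input bundle: paired-end reads (SAM/FASTQ), a PSM
# table with decoys and binding ranks, and per-peptide planted ground truth
# covering every branch of the validation decision tree.
#
# Planting strategy: peptides are random 8-11-mers, reverse-translated into
# a coding sequence (MCS) that is written into the genome at a chosen locus
# (inside a repeat copy of the required context/orientation, in-frame inside
# a CDS, or both for "maybe" cases); supporting read pairs are then emitted
# so that the first mate covers the whole MCS and the second mate stays
# clear of it, which makes minimal k-mer occurrences exactly equal to the
# planted read counts on loci excluded from background coverage.

#' Generate a synthetic immunopeptidomics read set with planted truth
#'
#' Produces every input the ereMAP pipeline consumes: QC-flagged paired-end
#' alignments (SAM layout), FASTQ mates, a target-decoy PSM table with
#' per-allele binding percentile ranks, transcript sequences and TPM, and a
#' truth table stating the intended verdict of every planted peptide:
#' `n_eremap` true ereMAPs across intergenic/intronic sense/antisense
#' branches, `n_canonical` canonical peptides, `n_ambiguous` "maybe" cases
#' with ERE:canonical k-mer ratios bracketing the 10x rule, `n_oneread`
#' single-read cases, and `n_tree_discard` cases discarded by the
#' orientation decision tree (CDS-sense and intronic gene-sense/
#' ERE-antisense single-locus). Decoys are reversed target sequences at 1:1;
#' planted peptides get binding ranks passing the 2% filter. Reads are
#' error-free (the more-than-one-read rule guards against sequencing
#' errors, so rule behaviour is kept separate from error simulation).
#'
#' @param genome_bundle A `synthetic_genome` from [make_genome()].
#' @param n_eremap,n_canonical,n_ambiguous,n_oneread,n_tree_discard Numbers
#'   of planted cases (defaults 30, 30, 12, 4, 4).
#' @param n_pairs Total read pairs including background (default 50000).
#' @param read_len Read length, >= 26 nt (default 76).
#' @param frag_len Fragment length (default 220).
#' @param sample_id Sample name for the PSM table (default "BLCL01").
#' @param seed Integer seed; same seed, identical outputs.
#' @return List of class `synthetic_readset`: `alignments` (SAM-layout
#'   tibble), `fastq` (list of two tibbles), `psms`, `truth`, `genome`
#'   (post-injection), `repeats`, `genes`, `transcripts`, `tpm`,
#'   `cds_start`, `variants` (empty), `sample_id`, `n_pairs`.
#' @export
make_blcl_readset <- function(genome_bundle, n_eremap = 30, n_canonical = 30,
                              n_ambiguous = 12, n_oneread = 4,
                              n_tree_discard = 4, n_pairs = 50000,
                              read_len = 76, frag_len = 220,
                              sample_id = "BLCL01", seed = 1L) {
  if (read_len < 26) abort("make_blcl_readset: read_len must be >= 26")
  stopifnot(inherits(genome_bundle, "synthetic_genome"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  genome <- genome_bundle$genome
  repeats <- genome_bundle$repeats
  genes <- genome_bundle$genes
  exon1 <- genes |> filter(.data$feature == "exon") |>
    group_by(.data$transcript_id) |> arrange(.data$start, .by_group = TRUE) |>
    dplyr::slice(1) |> ungroup()
  cds <- genes[genes$feature == "CDS", ]

  inject <- function(chrom, start0, nt) {
    ci <- match(chrom, genome$name)
    substr(genome$sequence[ci], start0 + 1L, start0 + nchar(nt)) <<- nt
  }

  # ---- case bookkeeping ----------------------------------------------------
  rep_pool <- repeats |> mutate(.row = dplyr::row_number())
  used <- logical(nrow(rep_pool))
  pick_repeat <- function(ctx, strand = NULL, n = 1, family = NULL) {
    ok <- rep_pool$context == ctx & !used
    if (!is.null(strand)) ok <- ok & rep_pool$strand == strand
    if (!is.null(family)) ok <- ok & rep_pool$family == family
    idx <- which(ok)
    if (length(idx) < n) abort(sprintf("make_blcl_readset: no free %s repeat available", ctx))
    idx <- idx[seq_len(n)]
    used[idx] <<- TRUE
    rep_pool[idx, , drop = FALSE]
  }

  truth <- list(); planted_frags <- list()
  tx_roles <- tibble(transcript_id = unique(exon1$transcript_id))
  tx_roles$role <- "background"

  # Supporting fragments for a planted MCS at [m0, m1). The first mate is
  # anchored so the MCS opens the read's reading frame (read start = m0 for a
  # forward-injected MCS, read end = m1 for a reverse-complemented one):
  # prefix-mode stop splicing then always retains the peptide, because no
  # upstream codon precedes it. Fragment lengths vary so second mates differ.
  plant_cover_frags <- function(chrom, m0, m1, n, lo, hi, forward_mcs = TRUE) {
    f <- if (forward_mcs) rep(as.integer(m0), n) else rep(as.integer(m1 - read_len), n)
    flen <- frag_len + 3L * ((seq_len(n) - 1L) %% 8L)
    flen <- pmin(flen, hi - f)
    stopifnot(all(f >= lo), all(flen >= read_len))
    tibble(chrom = chrom, fstart = f, flen = as.integer(flen))
  }

  peptide_len_cycle <- rep(c(9L, 9L, 8L, 10L, 9L, 11L, 8L, 10L), length.out = 200)
  pep_i <- 0L
  new_peptide <- function() {
    pep_i <<- pep_i + 1L
    random_peptides(1, peptide_len_cycle[pep_i])
  }

  # ---- ereMAP cases --------------------------------------------------------
  n_ig_sense <- ceiling(n_eremap * 0.27)
  n_ig_anti <- floor(n_eremap * 0.2)
  n_multi <- floor(n_eremap * 0.2)
  n_in_sense <- n_eremap - n_ig_sense - n_ig_anti - n_multi
  ere_cases <- c(rep("intergenic_sense", n_ig_sense),
                 rep("intergenic_antisense", n_ig_anti),
                 rep("intronic_sense", n_in_sense),
                 rep("intronic_antisense_multi", n_multi))
  multi_fams <- names(sort(table(rep_pool$family[rep_pool$context == "intronic"]),
                           decreasing = TRUE))
  multi_i <- 0L
  for (case in ere_cases) {
    pep <- new_peptide()
    mcs <- reverse_translate(pep)
    n_sup <- 3L + (pep_i %% 4L)
    if (case == "intronic_antisense_multi") {
      multi_i <- multi_i + 1L
      fam <- multi_fams[(multi_i - 1L) %% length(multi_fams) + 1L]
      hosts <- pick_repeat("intronic", n = 3, family = fam)
      host <- hosts[1, ]
      mcs_strand <- if (host$strand == "+") "-" else "+"
      g <- if (mcs_strand == "+") mcs else revcomp(mcs)
      for (j in 1:3) inject(hosts$chrom[j], hosts$start[j] + 150L, g)
      n_loci <- 3L
      region <- "intronic"; ori_ere <- "antisense"
    } else {
      ctx <- if (startsWith(case, "intergenic")) "intergenic" else "intronic"
      host <- pick_repeat(ctx)
      sense <- !grepl("antisense", case)
      mcs_strand <- if (sense) host$strand else setdiff(c("+", "-"), host$strand)
      g <- if (mcs_strand == "+") mcs else revcomp(mcs)
      inject(host$chrom, host$start + 150L, g)
      n_loci <- 1L
      region <- if (ctx == "intergenic") "intergenic" else "intronic"
      ori_ere <- if (sense) "sense" else "antisense"
    }
    m0 <- host$start + 150L; m1 <- m0 + nchar(mcs)
    planted_frags[[length(planted_frags) + 1]] <- plant_cover_frags(
      host$chrom, m0, m1, n_sup, host$start, host$end, mcs_strand == "+")
    truth[[length(truth) + 1]] <- tibble(
      peptide = pep, case = case, intended_verdict = "ereMAP",
      region = region, orientation_vs_ere = ori_ere, n_ere_loci = n_loci,
      n_reads_ere = n_sup, n_reads_canonical = 0L,
      mcs = mcs, family = host$family, group = host$group)
  }

  # ---- tree-discard cases --------------------------------------------------
  n_cds <- ceiling(n_tree_discard / 2); n_intr <- n_tree_discard - n_cds
  for (i in seq_len(n_cds)) {
    pep <- new_peptide(); mcs <- reverse_translate(pep)
    host <- pick_repeat("straddle")
    # MCS overlapping the CDS end: starts 12 nt before the exon boundary
    boundary <- host$start + 80L   # = exon1 end
    m0 <- boundary - 12L; m1 <- m0 + nchar(mcs)
    inject(host$chrom, m0, mcs)    # forward = gene sense
    planted_frags[[length(planted_frags) + 1]] <- plant_cover_frags(
      host$chrom, m0, m1, 3L, host$start, host$end)
    truth[[length(truth) + 1]] <- tibble(
      peptide = pep, case = "cds_sense", intended_verdict = "discard-tree",
      region = "CDS", orientation_vs_ere = NA_character_, n_ere_loci = 1L,
      n_reads_ere = 3L, n_reads_canonical = 0L,
      mcs = mcs, family = host$family, group = host$group)
  }
  for (i in seq_len(n_intr)) {
    pep <- new_peptide(); mcs <- reverse_translate(pep)
    host <- pick_repeat("intronic", strand = "-")
    inject(host$chrom, host$start + 150L, mcs)   # forward = gene sense, ERE antisense
    m0 <- host$start + 150L; m1 <- m0 + nchar(mcs)
    planted_frags[[length(planted_frags) + 1]] <- plant_cover_frags(
      host$chrom, m0, m1, 3L, host$start, host$end)
    truth[[length(truth) + 1]] <- tibble(
      peptide = pep, case = "intronic_gene_sense_ere_antisense",
      intended_verdict = "discard-tree",
      region = "intronic", orientation_vs_ere = "antisense", n_ere_loci = 1L,
      n_reads_ere = 3L, n_reads_canonical = 0L,
      mcs = mcs, family = host$family, group = host$group)
  }

  # ---- one-read cases ------------------------------------------------------
  oneread_hosts <- list()
  for (i in seq_len(n_oneread)) {
    pep <- new_peptide(); mcs <- reverse_translate(pep)
    host <- pick_repeat("intronic")
    oneread_hosts[[i]] <- host$.row
    inject(host$chrom, host$start + 150L, mcs)   # forward strand
    m0 <- host$start + 150L; m1 <- m0 + nchar(mcs)
    planted_frags[[length(planted_frags) + 1]] <- plant_cover_frags(
      host$chrom, m0, m1, 1L, host$start, host$end)
    truth[[length(truth) + 1]] <- tibble(
      peptide = pep, case = "one_read", intended_verdict = "discard-oneread",
      region = "intronic", orientation_vs_ere = if (host$strand == "+") "sense" else "antisense",
      n_ere_loci = 1L, n_reads_ere = 1L, n_reads_canonical = 0L,
      mcs = mcs, family = host$family, group = host$group)
  }

  # ---- canonical peptides (status "no") ------------------------------------
  bg_tx <- tx_roles$transcript_id
  straddle_genes <- unique(repeats$gene_id[repeats$context == "straddle"])
  straddle_tx <- genes$transcript_id[genes$gene_id %in% straddle_genes]
  can_tx <- setdiff(bg_tx, straddle_tx)
  n_can_tx <- ceiling(n_canonical / 2)
  if (n_can_tx + n_ambiguous + 1 > length(can_tx)) {
    abort("make_blcl_readset: not enough transcripts for the requested plantings")
  }
  can_tx_use <- can_tx[seq_len(n_can_tx)]
  amb_tx_use <- can_tx[n_can_tx + seq_len(n_ambiguous)]
  silent_tx <- can_tx[n_can_tx + n_ambiguous + 1]
  tx_roles$role[tx_roles$transcript_id %in% amb_tx_use] <- "ambiguous"
  tx_roles$role[tx_roles$transcript_id == silent_tx] <- "silent"
  tx_cursor <- setNames(rep(63L, length(can_tx_use)), can_tx_use)
  for (pepn in seq_len(n_canonical)) {
    pep <- new_peptide(); mcs <- reverse_translate(pep)
    tx <- can_tx_use[(pepn - 1L) %/% 2L + 1L]
    e1 <- exon1[exon1$transcript_id == tx, ]
    # back-to-back in frame right after the ATG, so no stop can intervene
    pos <- e1$start + tx_cursor[[tx]]
    tx_cursor[[tx]] <- tx_cursor[[tx]] + nchar(mcs)
    inject(e1$chrom, pos, mcs)
    truth[[length(truth) + 1]] <- tibble(
      peptide = pep, case = "canonical", intended_verdict = "canonical",
      region = "CDS", orientation_vs_ere = NA_character_, n_ere_loci = 0L,
      n_reads_ere = 0L, n_reads_canonical = 0L,
      mcs = mcs, family = NA_character_, group = NA_character_)
  }

  # ---- ambiguous ("maybe") cases bracketing the 10x rule -------------------
  ratios_keep <- list(c(50L, 4L), c(40L, 2L), c(30L, 3L), c(60L, 6L), c(20L, 2L), c(50L, 5L))
  ratios_drop <- list(c(9L, 1L), c(5L, 1L), c(19L, 2L), c(9L, 1L), c(15L, 2L), c(8L, 1L))
  n_keep <- ceiling(n_ambiguous / 2); n_drop <- n_ambiguous - n_keep
  ratios <- c(rep(ratios_keep, length.out = n_keep), rep(ratios_drop, length.out = n_drop))
  verdicts <- c(rep("ambiguous-keep", n_keep), rep("ambiguous-discard", n_drop))
  amb_hosts <- integer(0)
  for (i in seq_len(n_ambiguous)) {
    pep <- new_peptide(); mcs <- reverse_translate(pep)
    ne <- ratios[[i]][1]; nc <- ratios[[i]][2]
    host <- pick_repeat("intronic", strand = "+")   # sense/sense: tree keeps
    amb_hosts <- c(amb_hosts, host$.row)
    inject(host$chrom, host$start + 150L, mcs)
    m0 <- host$start + 150L; m1 <- m0 + nchar(mcs)
    planted_frags[[length(planted_frags) + 1]] <- plant_cover_frags(
      host$chrom, m0, m1, ne, host$start, host$end)
    # canonical side: same MCS in frame after the ATG of a dedicated transcript
    tx <- amb_tx_use[i]
    e1 <- exon1[exon1$transcript_id == tx, ]
    cpos <- e1$start + 63L
    inject(e1$chrom, cpos, mcs)
    planted_frags[[length(planted_frags) + 1]] <- plant_cover_frags(
      e1$chrom, cpos, cpos + nchar(mcs), nc, e1$start, e1$end)
    truth[[length(truth) + 1]] <- tibble(
      peptide = pep, case = sprintf("ambiguous_%d_to_%d", ne, nc),
      intended_verdict = verdicts[i],
      region = "intronic", orientation_vs_ere = "sense", n_ere_loci = 1L,
      n_reads_ere = ne, n_reads_canonical = nc,
      mcs = mcs, family = host$family, group = host$group)
  }
  truth <- bind_rows(truth)

  # verify every planted coding sequence is present where intended
  gset <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  for (i in seq_len(nrow(truth))) {
    n_hit <- sum(Biostrings::vcountPattern(truth$mcs[i], gset)) +
      sum(Biostrings::vcountPattern(revcomp(truth$mcs[i]), gset))
    expected <- truth$n_ere_loci[i] + (truth$n_reads_canonical[i] > 0) +
      (truth$intended_verdict[i] == "canonical")
    if (n_hit != expected) {
      abort(sprintf("planted peptide %s not encodable as intended (%d loci, expected %d)",
                    truth$peptide[i], n_hit, expected))
    }
  }

  # ---- background fragments ------------------------------------------------
  planted <- bind_rows(planted_frags)
  n_bg <- n_pairs - nrow(planted)
  if (n_bg < 0) abort("make_blcl_readset: n_pairs smaller than the planted reads")
  excluded_rows <- c(amb_hosts, unlist(oneread_hosts))
  bg_rep <- rep_pool[!rep_pool$.row %in% excluded_rows, ]
  bg_exons <- genes |>
    filter(.data$feature == "exon",
           !.data$transcript_id %in% c(amb_tx_use, silent_tx))
  src <- sample(c("exon", "repeat", "uniform"), n_bg, replace = TRUE,
                prob = c(0.45, 0.35, 0.20))
  bg <- vector("list", 3)
  n_e <- sum(src == "exon")
  if (n_e) {
    pick <- sample.int(nrow(bg_exons), n_e, replace = TRUE,
                       prob = bg_exons$end - bg_exons$start)
    lo <- bg_exons$start[pick]; hi <- bg_exons$end[pick] - frag_len
    bg[[1]] <- tibble(chrom = bg_exons$chrom[pick],
                      fstart = lo + floor(runif(n_e) * pmax(1, hi - lo + 1)),
                      flen = frag_len)
  }
  n_r <- sum(src == "repeat")
  if (n_r) {
    pick <- sample.int(nrow(bg_rep), n_r, replace = TRUE)
    lo <- bg_rep$start[pick]; hi <- bg_rep$end[pick] - frag_len
    bg[[2]] <- tibble(chrom = bg_rep$chrom[pick],
                      fstart = lo + floor(runif(n_r) * pmax(1, hi - lo + 1)),
                      flen = frag_len)
  }
  n_u <- sum(src == "uniform")
  if (n_u) {
    ui <- sample.int(nrow(genome), n_u, replace = TRUE)
    ubg <- tibble(chrom = genome$name[ui],
                  fstart = floor(runif(n_u) * (nchar(genome$sequence[ui]) - frag_len)),
                  flen = frag_len)
    # keep controlled loci controlled: drop uniform fragments touching the
    # ambiguous/one-read repeats or the ambiguous transcripts' first exons
    excl <- bind_rows(
      rep_pool[rep_pool$.row %in% excluded_rows, c("chrom", "start", "end")],
      exon1[exon1$transcript_id %in% amb_tx_use, c("chrom", "start", "end")])
    bad <- rep(FALSE, nrow(ubg))
    for (i in seq_len(nrow(excl))) {
      bad <- bad | (ubg$chrom == excl$chrom[i] &
                      ubg$fstart < excl$end[i] &
                      ubg$fstart + frag_len > excl$start[i])
    }
    bg[[3]] <- ubg[!bad, , drop = FALSE]
  }
  frags <- bind_rows(planted, bg)
  frags$fstart <- as.integer(frags$fstart)

  # ---- SAM records ---------------------------------------------------------
  n_frag <- nrow(frags)
  chrom_seq <- setNames(genome$sequence, genome$name)
  s1 <- frags$fstart
  s2 <- frags$fstart + frags$flen - read_len
  seq1 <- substring(chrom_seq[frags$chrom], s1 + 1L, s1 + read_len)
  seq2 <- substring(chrom_seq[frags$chrom], s2 + 1L, s2 + read_len)
  orient <- rep(c(TRUE, FALSE), length.out = n_frag)   # TRUE: 99/147, FALSE: 83/163
  flag1 <- ifelse(orient, 99L, 83L)
  flag2 <- ifelse(orient, 147L, 163L)
  rid <- sprintf("frag%06d", seq_len(n_frag))
  aln <- tibble(
    read_id = rep(rid, each = 2),
    flag = as.integer(rbind(flag1, flag2)),
    chrom = rep(frags$chrom, each = 2),
    start = as.integer(rbind(s1, s2)),
    cigar = sprintf("%dM", read_len),
    sequence = as.character(rbind(seq1, seq2)))
  # QC-reject records exercising the flag filter
  n_junk <- 200L
  jpos <- sample.int(min(nchar(chrom_seq)) - read_len, n_junk)
  junk_flags <- rep(c(355L, 1123L, 611L, 2147L, 77L, 67L, 115L), length.out = n_junk)
  junk <- tibble(
    read_id = sprintf("junk%04d", seq_len(n_junk)),
    flag = junk_flags,
    chrom = ifelse(bitwAnd(junk_flags, 4L) > 0, NA_character_, genome$name[1]),
    start = ifelse(bitwAnd(junk_flags, 4L) > 0, NA_integer_, jpos),
    cigar = ifelse(bitwAnd(junk_flags, 4L) > 0, "*", sprintf("%dM", read_len)),
    sequence = substring(chrom_seq[1], jpos + 1L, jpos + read_len))
  aln <- bind_rows(aln, junk)
  aln <- dplyr::bind_cols(aln, decode_sam_flags(aln$flag))
  aln$end <- aln$start + ifelse(aln$cigar == "*", NA_integer_, read_len)

  # FASTQ: raw reads (reverse-flagged mates are reverse-complemented)
  fq1 <- tibble(name = rid, sequence = ifelse(orient, seq1, revcomp(seq1)))
  fq2 <- tibble(name = rid, sequence = ifelse(orient, revcomp(seq2), seq2))

  # ---- PSM table -----------------------------------------------------------
  n_t <- nrow(truth)
  extra <- tibble(   # filtered by length/rank, never reach the proteome stage
    peptide = c(random_peptides(2, 12), random_peptides(2, 9)),
    case = c("too_long", "too_long", "nonbinder", "nonbinder"),
    intended_verdict = "not_called")
  targets <- tibble(
    peptide = c(truth$peptide, extra$peptide),
    sample = sample_id,
    score = round(rnorm(n_t + nrow(extra), 40, 2), 3),
    is_decoy = FALSE,
    rank_A0201 = round(runif(n_t + nrow(extra), 0.1, 1.5), 2),
    rank_B0702 = round(runif(n_t + nrow(extra), 0.5, 4), 2))
  targets$rank_A0201[targets$peptide %in%
                       extra$peptide[extra$case == "nonbinder"]] <- 5
  targets$rank_B0702[targets$peptide %in%
                       extra$peptide[extra$case == "nonbinder"]] <- 7.5
  decoys <- tibble(
    peptide = vapply(strsplit(targets$peptide, ""), function(x)
      paste(rev(x), collapse = ""), character(1)),
    sample = sample_id,
    score = round(rnorm(nrow(targets), 20, 2), 3),
    is_decoy = TRUE,
    rank_A0201 = round(runif(nrow(targets), 0.1, 5), 2),
    rank_B0702 = round(runif(nrow(targets), 0.5, 7), 2))
  psms <- bind_rows(targets, decoys)
  psms$best_rank <- pmin(psms$rank_A0201, psms$rank_B0702)
  truth <- bind_rows(truth,
                     mutate(extra, region = NA_character_,
                            orientation_vs_ere = NA_character_, n_ere_loci = 0L,
                            n_reads_ere = 0L, n_reads_canonical = 0L,
                            mcs = NA_character_, family = NA_character_,
                            group = NA_character_))

  # ---- transcripts and TPM -------------------------------------------------
  transcripts <- extract_transcripts(genome, genes)
  tpm <- setNames(round(runif(nrow(transcripts), 2, 50), 2), transcripts$name)
  tpm[silent_tx] <- 0
  tpm[amb_tx_use] <- 5

  structure(list(
    alignments = aln, fastq = list(r1 = fq1, r2 = fq2), psms = psms,
    truth = truth, genome = genome, repeats = repeats, genes = genes,
    transcripts = transcripts, tpm = tpm,
    cds_start = genome_bundle$cds_start_tx,
    variants = tibble(transcript_id = character(), pos = integer(),
                      ref = character(), alt = character(), alt_count = integer()),
    sample_id = sample_id, n_pairs = n_frag,
    params = list(read_len = read_len, frag_len = frag_len, seed = seed)),
    class = "synthetic_readset")
}

#' @export
print.synthetic_readset <- function(x, ...) {
  cat(sprintf("Synthetic read set: %d pairs, %d PSMs (%d decoys), %d planted cases\n",
              x$n_pairs, nrow(x$psms), sum(x$psms$is_decoy), nrow(x$truth)))
  print(dplyr::count(x$truth, .data$intended_verdict))
  invisible(x)
}
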