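# Synthetic genome with repeat annotations and gene models. The layout is
# deterministic given the seed: genes with intron-hosted repeat slots,
# intergenic repeat slots, a few repeats inside exons, and a few repeats
# straddling a CDS/intron boundary (the geometry the peptide decision tree
# needs). Repeat copies are mutated clones of per-family consensus
# sequences.

DEFAULT_FAMILIES <- c(
  LTR7 = "LTR", `HERVH-int` = "LTR", `HERVK9-int` = "LTR", MER41B = "LTR",
  L1PA3 = "LINE", L1HS = "LINE", L2a = "LINE", L1MB7 = "LINE",
  AluY = "SINE", AluSx = "SINE", MIRb = "SINE", AluJb = "SINE")

mutate_sequence <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < divergence)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with repeats and gene models
#'
#' Builds `n_chrom` chromosomes carrying gene models (4 exons of
#' `exon_len` nt, all on the + strand, with an ATG planted at offset 60 of
#' exon 1 defining the CDS) and repeat copies cloned from per-family
#' consensus sequences at `divergence` substitution rate. Copies are placed
#' in intronic, intergenic and exonic contexts (defaults mirror the
#' genome-wide picture in which about half of repeat copies are intronic),
#' plus `n_straddle` copies overlapping the CDS end of exon 1 and running
#' into intron 1.
#'
#' @param n_chrom Number of chromosomes (default 1).
#' @param repeat_families Named character vector family -> group, or an
#'   integer count (names invented). Default: 12 families, 4 per group.
#' @param copies_per_family Copies per family (default 12).
#' @param divergence Per-base substitution rate of copies vs consensus, in
#'   `[0, 0.3]` (default 0.05).
#' @param intronic_fraction,exonic_fraction Fractions of copies placed in
#'   introns (default 0.51) and inside exons (default 0.03); the remainder
#'   is intergenic.
#' @param n_straddle Number of CDS/intron boundary-straddling copies
#'   (default 4).
#' @param consensus_len Consensus length in nt (default 400).
#' @param exon_len Exon length in nt (default 450).
#' @param min_length Minimum chromosome length; the tail is padded to reach
#'   it (default 0 = no padding).
#' @param seed Integer seed; same seed, byte-identical outputs.
#' @return List of class `synthetic_genome`: `genome` (tibble name/sequence),
#'   `repeats` (annotation tibble with extra columns `context`, `gene_id`),
#'   `genes` (gene-model tibble), `cds_start_tx` (named 1-based ATG offset
#'   within each transcript), `family_groups`, `consensus`, `params`.
#' @export
make_genome <- function(n_chrom = 1, repeat_families = DEFAULT_FAMILIES,
                        copies_per_family = 16, divergence = 0.05,
                        intronic_fraction = 0.51, exonic_fraction = 0.03,
                        n_straddle = 4, consensus_len = 400, exon_len = 450,
                        min_length = 0, seed = 1L) {
  if (divergence < 0 || divergence > 0.3) abort("make_genome: divergence must be in [0, 0.3]")
  if (is.numeric(repeat_families) && is.null(names(repeat_families))) {
    nfam <- as.integer(repeat_families)
    repeat_families <- setNames(rep(c("LTR", "LINE", "SINE"), length.out = nfam),
                                sprintf("FAM%02d", seq_len(nfam)))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  fams <- names(repeat_families)
  consensus <- setNames(random_dna(length(fams), consensus_len), fams)
  n_rep <- length(fams) * copies_per_family
  n_intron <- round(intronic_fraction * n_rep)
  n_exonic <- round(exonic_fraction * n_rep)
  n_intergenic <- n_rep - n_intron - n_exonic
  if (n_intergenic < 0) abort("make_genome: context fractions exceed 1")
  # family of each copy, round-robin so every context sees every family
  copy_fam <- rep(fams, copies_per_family)
  context <- c(rep("intronic", n_intron), rep("intergenic", n_intergenic),
               rep("exonic", n_exonic))
  # alternating strands guarantee both orientations in every context
  # (straddle copies are extra, beyond the n_rep context copies)
  strand <- rep(c("+", "-"), length.out = n_rep + n_straddle)

  introns_per_gene <- 3L
  # straddle genes lose one intronic slot each
  n_genes <- max(ceiling((n_intron + n_straddle) / introns_per_gene), n_straddle, 8L)
  pad <- 300L

  # per-chromosome assembly
  gene_chrom <- rep(seq_len(n_chrom), length.out = n_genes)
  rep_rows <- list(); gene_rows <- list(); chrom_seq <- character(n_chrom)
  cds_start_tx <- integer(0)
  iq <- list(intronic = which(context == "intronic"),
             intergenic = which(context == "intergenic"),
             exonic = which(context == "exonic"))
  take <- function(ctx) {
    if (!length(iq[[ctx]])) return(NA_integer_)
    i <- iq[[ctx]][1]; iq[[ctx]] <<- iq[[ctx]][-1]; i
  }
  straddle_genes <- seq_len(n_straddle)
  copy_counter <- 0L

  for (ch in seq_len(n_chrom)) {
    chrom <- sprintf("chr%d", ch)
    cursor <- 0L
    blocks <- character(0)
    push <- function(len) {
      blocks[[length(blocks) + 1]] <<- random_dna(1, len)
      cursor <<- cursor + as.integer(len)
    }
    add_repeat <- function(idx, start) {
      copy_counter <<- copy_counter + 1L
      rep_rows[[length(rep_rows) + 1]] <<- tibble(
        chrom = chrom, start = as.integer(start),
        end = as.integer(start + consensus_len),
        strand = strand[copy_counter],
        element_name = sprintf("%s#%04d", copy_fam[idx], copy_counter),
        family = copy_fam[idx],
        group = unname(repeat_families[copy_fam[idx]]),
        context = context[idx], gene_id = NA_character_)
    }
    for (g in which(gene_chrom == ch)) {
      gene_id <- sprintf("GENE%03d", g)
      tx_id <- sprintf("TX%03d", g)
      # leading intergenic region, hosting up to 2 intergenic repeats
      for (k in seq_len(2)) {
        idx <- take("intergenic")
        if (!is.na(idx)) {
          push(pad); add_repeat(idx, cursor); push(consensus_len); push(pad)
        }
      }
      push(600L)
      # exon 1 with CDS from the planted ATG
      exon_starts <- integer(4); exon_ends <- integer(4)
      exon_starts[1] <- cursor; push(exon_len); exon_ends[1] <- cursor
      atg <- exon_starts[1] + 60L
      straddle_here <- g %in% straddle_genes
      for (ii in 1:3) {
        if (ii == 1 && straddle_here) {
          # straddling repeat: starts 80 nt before the exon/intron boundary
          copy_counter <- copy_counter + 1L
          sfam <- fams[(g - 1L) %% length(fams) + 1L]
          rep_rows[[length(rep_rows) + 1]] <- tibble(
            chrom = chrom, start = exon_ends[1] - 80L,
            end = exon_ends[1] - 80L + consensus_len,
            strand = strand[copy_counter],
            element_name = sprintf("%s#%04d", sfam, copy_counter),
            family = sfam, group = unname(repeat_families[sfam]),
            context = "straddle", gene_id = gene_id)
          push(consensus_len - 80L + pad)
        } else {
          idx <- take("intronic")
          if (!is.na(idx)) {
            push(pad); add_repeat(idx, cursor); push(consensus_len); push(pad)
          } else {
            push(2L * pad)
          }
        }
        exon_starts[ii + 1] <- cursor; push(exon_len); exon_ends[ii + 1] <- cursor
      }
      # exonic-context repeat inside exon 4 (recorded, sequence overwritten later)
      idx <- take("exonic")
      if (!is.na(idx) && exon_len >= consensus_len + 20) {
        add_repeat(idx, exon_starts[4] + 10L)
      } else if (!is.na(idx)) {
        iq$intergenic <- c(iq$intergenic, idx)  # no room: fall back
      }
      gene_rows[[length(gene_rows) + 1]] <- bind_rows(
        tibble(gene_id = gene_id, transcript_id = tx_id, feature = "exon",
               chrom = chrom, start = exon_starts, end = exon_ends, strand = "+"),
        tibble(gene_id = gene_id, transcript_id = tx_id, feature = "CDS",
               chrom = chrom, start = atg, end = exon_ends[1], strand = "+"))
      cds_start_tx[tx_id] <- 61L   # ATG offset within the transcript, 1-based
    }
    if (ch == n_chrom) {
      # drain remaining intergenic copies into the trailing region
      repeat {
        idx <- take("intergenic")
        if (is.na(idx)) break
        push(pad); add_repeat(idx, cursor); push(consensus_len); push(pad)
      }
    }
    push(600L)
    chrom_seq[ch] <- paste(blocks, collapse = "")
    if (nchar(chrom_seq[ch]) < min_length / n_chrom) {
      chrom_seq[ch] <- paste0(chrom_seq[ch],
                              random_dna(1, ceiling(min_length / n_chrom) - nchar(chrom_seq[ch])))
    }
  }

  repeats <- bind_rows(rep_rows)
  if (length(iq$intergenic) || length(iq$intronic)) {
    abort("make_genome: requested copies exceed available space (increase genes or chromosomes)")
  }
  genes <- bind_rows(gene_rows) |> mutate(overlapping_exons = FALSE)
  genome <- tibble(name = sprintf("chr%d", seq_len(n_chrom)), sequence = chrom_seq)
  # overwrite repeat windows with mutated consensus copies, then the ATGs
  for (i in seq_len(nrow(repeats))) {
    ci <- match(repeats$chrom[i], genome$name)
    copy <- mutate_sequence(consensus[[repeats$family[i]]], divergence)
    if (repeats$strand[i] == "-") copy <- revcomp(copy)
    substr(genome$sequence[ci], repeats$start[i] + 1L, repeats$end[i]) <- copy
  }
  cds <- genes[genes$feature == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    ci <- match(cds$chrom[i], genome$name)
    substr(genome$sequence[ci], cds$start[i] + 1L, cds$start[i] + 3L) <- "ATG"
  }
  structure(list(genome = genome, repeats = repeats, genes = genes,
                 cds_start_tx = cds_start_tx,
                 family_groups = repeat_families, consensus = consensus,
                 params = list(n_chrom = n_chrom, copies_per_family = copies_per_family,
                               divergence = divergence, consensus_len = consensus_len,
                               exon_len = exon_len, seed = seed)),
            class = "synthetic_genome")
}

#' Extract transcript sequences from a (possibly modified) genome
#' @param genome Tibble `name`/`sequence`.
#' @param genes Gene-model tibble (exon rows used; + strand assumed).
#' @return Tibble `name` (transcript id), `sequence`.
#' @export
extract_transcripts <- function(genome, genes) {
  ex <- genes[genes$feature == "exon", ] |> arrange(.data$transcript_id, .data$start)
  ex |>
    group_by(.data$transcript_id, .data$chrom) |>
    summarise(sequence = paste(substring(genome$sequence[match(.data$chrom[1], genome$name)],
                                         .data$start + 1L, .data$end), collapse = ""),
              .groups = "drop") |>
    dplyr::transmute(name = .data$transcript_id, sequence = .data$sequence)
}
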