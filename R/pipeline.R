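# End-to-end ereMAP calling: wires the proteogenomics and validation modules
# into the full filter cascade, with a per-candidate audit trail.

#' Call ereMAPs from PSMs, alignments and annotations
#'
#' Runs the complete cascade: target-decoy FDR on peptide scores, the
#' 8-11-mer binding-rank filter, read QC and ERE/canonical partitioning,
#' six-frame ERE proteome and personalized canonical proteome construction,
#' ERE-status assignment, read-support and canonical 24-mer arbitration (10x
#' rule) for "maybe" peptides, the I/L variant check, exact-match locus
#' classification, and the orientation decision tree. Every candidate
#' carries at most one terminal discard reason in the audit table.
#'
#' @param psms PSM tibble ([read_psm_table()] layout with `best_rank`).
#' @param alignments Read tibble ([read_sam_min()] layout).
#' @param repeats Repeat tibble ([read_repeatmasker()]).
#' @param genes Gene-model tibble ([read_gtf()]).
#' @param genome Tibble `name`/`sequence` or a named `DNAStringSet`.
#' @param transcripts Transcript tibble (`name`, `sequence`) for the
#'   canonical proteome.
#' @param tpm Named numeric vector of transcript TPM.
#' @param variants Optional variant tibble ([read_variants()]).
#' @param cds_start Optional named 1-based start positions within transcripts.
#' @param fdr_q FDR level (default 0.05).
#' @param rank_max Binding-rank ceiling in percent (default 2).
#' @param kmer_k Arbitration word length (default 24).
#' @param ratio_min ERE:canonical abundance ratio (default 10).
#' @param min_reads Minimum supporting reads (default 2; applied to every
#'   ERE candidate, "yes" or "maybe", as the rule guards against sequencing
#'   errors regardless of status).
#' @param splice_mode Stop-splicing mode for the ERE proteome.
#' @return Object of class `eremap_calls`: list with `records` (one row per
#'   kept (peptide, sample, characteristic-alternative)), `audit` (one row
#'   per candidate with terminal stage/reason), `partition`, `proteome`,
#'   `kmer_tables`, and the configuration.
#' @export
call_eremaps <- function(psms, alignments, repeats, genes, genome,
                         transcripts, tpm, variants = NULL, cds_start = NULL,
                         fdr_q = 0.05, rank_max = 2, kmer_k = 24,
                         ratio_min = 10, min_reads = 2,
                         splice_mode = c("prefix", "split")) {
  splice_mode <- match.arg(splice_mode)
  gset <- if (methods::is(genome, "DNAStringSet")) genome else
    Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))

  audit <- list()
  note <- function(peptide, sample, stage, outcome, reason = NA_character_) {
    tibble(peptide = peptide, sample = sample, stage = stage,
           outcome = outcome, reason = reason)
  }

  # 1. FDR ---------------------------------------------------------------
  passed_fdr <- apply_fdr(psms, q = fdr_q)
  dropped <- dplyr::anti_join(psms[!psms$is_decoy, ], passed_fdr,
                              by = c("peptide", "sample"))
  audit$fdr <- note(dropped$peptide, dropped$sample, "fdr", "discard", "below_fdr_threshold")

  # 2. binder filter ------------------------------------------------------
  binders <- filter_binders(passed_fdr, rank_max = rank_max)
  dropped <- dplyr::anti_join(passed_fdr, binders, by = c("peptide", "sample"))
  audit$binder <- note(dropped$peptide, dropped$sample, "binder", "discard", "length_or_rank")

  # 3. reads -> proteomes -------------------------------------------------
  qc <- filter_alignments(alignments)
  part <- partition_reads(qc, repeats, genes)
  ere_prot <- build_ere_proteome(part$ere, mode = splice_mode)
  can_read_prot <- build_ere_proteome(part$canonical, mode = splice_mode)
  can_read_prot$source <- "canonical-read"
  can_read_prot$entry_id <- sub("^ere", "canr", can_read_prot$entry_id)
  can_prot <- build_personalized_proteome(transcripts, variants, tpm, cds_start)
  proteome <- concat_proteomes(ere_prot, can_prot)

  # 4. status -------------------------------------------------------------
  membership <- assign_status(proteome_contains(proteome, unique(binders$peptide)))
  binders <- left_join(binders, membership[, c("peptide", "status")], by = "peptide")
  not_ere <- binders[binders$status %in% c("no", "undetermined"), ]
  audit$status <- note(not_ere$peptide, not_ere$sample, "status", "discard",
                       ifelse(not_ere$status == "no", "canonical_only", "not_in_proteomes"))
  cands <- binders[binders$status %in% c("yes", "maybe"), , drop = FALSE]

  # 5. MCS recovery and k-mer tables --------------------------------------
  read_prot <- bind_rows(ere_prot, can_read_prot)
  mcs_all <- find_peptide_mcs(read_prot, cands$peptide)
  ere_tab <- build_kmer_table(part$ere, k = kmer_k)
  can_tab <- build_kmer_table(part$canonical, k = kmer_k)
  support_of <- function(p) {
    dplyr::n_distinct(mcs_all$read_id[mcs_all$peptide == p & mcs_all$source == "ere-read"])
  }

  records <- list()
  for (i in seq_len(nrow(cands))) {
    p <- cands$peptide[i]; smp <- cands$sample[i]; st <- cands$status[i]
    pm <- mcs_all[mcs_all$peptide == p, , drop = FALSE]
    n_sup <- support_of(p)
    mcs_set <- unique(pm$mcs)
    if (!length(mcs_set)) {
      audit[[length(audit) + 1]] <- note(p, smp, "mcs", "discard", "no_mcs_recovered")
      next
    }
    # read-support rule for every candidate; full arbitration for "maybe"
    if (st == "maybe") {
      arb <- resolve_maybe(mcs_set, ere_tab, can_tab, n_support_reads = n_sup,
                           ratio_min = ratio_min, min_reads = min_reads)
      if (!arb$keep) {
        audit[[length(audit) + 1]] <- note(p, smp, "kmer_arbitration", "discard", arb$reason)
        next
      }
      mcs_use <- arb$top_mcs
    } else {
      if (n_sup < min_reads) {
        audit[[length(audit) + 1]] <- note(p, smp, "read_support", "discard", "insufficient_reads")
        next
      }
      mcs_use <- unique(pm$mcs[pm$source == "ere-read"])
    }
    # I/L indistinguishability
    il <- il_variant_check(p, proteome, cand_read_support = n_sup,
                           ere_read_support = function(v) {
                             hits <- find_peptide_mcs(ere_prot, v)
                             dplyr::n_distinct(hits$read_id)
                           })
    if (!il$keep) {
      audit[[length(audit) + 1]] <- note(p, smp, "il_variant", "discard", il$reason)
      next
    }
    # locus classification + orientation tree over the candidate's MCS
    kept_loci <- list()
    any_ere_locus <- FALSE
    for (m in mcs_use) {
      cl <- classify_origin(m, repeats, genes, gset)
      if (is.null(cl$loci) || !nrow(cl$loci)) next
      any_ere_locus <- TRUE
      for (j in seq_len(nrow(cl$loci))) {
        lo <- cl$loci[j, ]
        dec <- orientation_decision(lo$region, lo$sense_vs_gene, lo$sense_vs_ere,
                                    cl$n_ere_loci)
        if (dec$keep) {
          kept_loci[[length(kept_loci) + 1]] <- mutate(
            lo, mcs = m, n_ere_loci = cl$n_ere_loci)
        } else {
          kept_loci[[length(kept_loci) + 1]] <- mutate(
            lo, mcs = m, n_ere_loci = cl$n_ere_loci, .discard = dec$reason)
        }
      }
    }
    loci_tbl <- bind_rows(kept_loci)
    if (!any_ere_locus || !nrow(loci_tbl)) {
      audit[[length(audit) + 1]] <- note(p, smp, "locus", "discard", "no_clear_locus")
      next
    }
    if (!".discard" %in% names(loci_tbl)) loci_tbl$.discard <- NA_character_
    ok <- is.na(loci_tbl$.discard)
    if (!any(ok)) {
      audit[[length(audit) + 1]] <- note(p, smp, "orientation", "discard",
                                         loci_tbl$.discard[1])
      next
    }
    keep_tbl <- loci_tbl[ok, , drop = FALSE] |>
      distinct(.data$family, .data$group, .data$region, .data$sense_vs_ere,
               .data$sense_vs_gene, .keep_all = TRUE)
    audit[[length(audit) + 1]] <- note(p, smp, "final", "keep")
    records[[length(records) + 1]] <- tibble(
      peptide = p, sample = smp, status = st,
      family = keep_tbl$family, group = keep_tbl$group,
      region = keep_tbl$region,
      orientation_vs_ere = keep_tbl$sense_vs_ere,
      orientation_vs_gene = keep_tbl$sense_vs_gene,
      n_ere_loci = keep_tbl$n_ere_loci,
      n_support_reads = n_sup,
      mcs = keep_tbl$mcs)
  }

  records <- bind_rows(records)
  if (!nrow(records)) {
    records <- tibble(peptide = character(), sample = character(), status = character(),
                      family = character(), group = character(), region = character(),
                      orientation_vs_ere = character(), orientation_vs_gene = character(),
                      n_ere_loci = integer(), n_support_reads = integer(), mcs = character())
  }
  structure(list(records = records,
                 audit = bind_rows(audit),
                 partition = part,
                 proteome = proteome,
                 kmer_tables = list(ere = ere_tab, canonical = can_tab),
                 config = list(fdr_q = fdr_q, rank_max = rank_max, kmer_k = kmer_k,
                               ratio_min = ratio_min, min_reads = min_reads,
                               splice_mode = splice_mode)),
            class = "eremap_calls")
}

#' @export
print.eremap_calls <- function(x, ...) {
  cat(sprintf("ereMAP calls: %d records (%d unique peptides); %d candidates audited\n",
              nrow(x$records), dplyr::n_distinct(x$records$peptide),
              dplyr::n_distinct(x$audit$peptide)))
  invisible(x)
}

#' @export
tidy.eremap_calls <- function(x, ...) x$records

#' @export
glance.eremap_calls <- function(x, ...) {
  tibble(n_records = nrow(x$records),
         n_peptides = dplyr::n_distinct(x$records$peptide),
         n_candidates = dplyr::n_distinct(x$audit$peptide),
         n_ere_reads = nrow(x$partition$ere),
         n_canonical_reads = nrow(x$partition$canonical))
}

#' Aggregate per-sample ereMAP records into non-redundant peptides
#'
#' Groups by peptide sequence: identical characteristics across samples are
#' merged (the sample list is retained); conflicting characteristics are
#' preserved as multiple alternative rows per peptide.
#'
#' @param records Record tibble from `eremap_calls$records`.
#' @return Tibble with one row per (peptide, characteristic alternative),
#'   plus `samples` (comma-joined), `n_samples`, `n_alternatives`.
#' @export
aggregate_nonredundant <- function(records) {
  if (!nrow(records)) return(mutate(records, samples = character(0),
                                    n_samples = integer(0), n_alternatives = integer(0)))
  samples <- records |>
    group_by(.data$peptide) |>
    summarise(samples = paste(sort(unique(.data$sample)), collapse = ","),
              n_samples = dplyr::n_distinct(.data$sample), .groups = "drop")
  alts <- records |>
    distinct(.data$peptide, .data$family, .data$group, .data$region,
             .data$orientation_vs_ere, .data$orientation_vs_gene, .data$n_ere_loci)
  alts |>
    left_join(samples, by = "peptide") |>
    group_by(.data$peptide) |>
    mutate(n_alternatives = n()) |>
    ungroup()
}

#' Cohort-level characterization of ereMAPs
#'
#' Computes the LINE/LTR/SINE proportions at the genome (repeat base share),
#' transcriptome (per-sample group TPM share averaged over samples) and
#' immunopeptidome (called peptides) levels with chi-squared comparisons;
#' the intergenic/intronic/CDS distribution of ereMAP coding loci against
#' the background distribution of repeat intervals; the Kendall tau between
#' per-family ereMAP counts and genomic copy numbers; and the
#' source-versus-non-source family expression comparison (Mann-Whitney on
#' mean log10(TPM + 1)).
#'
#' @param records Non-redundant record tibble ([aggregate_nonredundant()]).
#' @param repeats Repeat tibble.
#' @param genes Gene-model tibble (for the region background).
#' @param family_expression Optional family-level expression tibble
#'   (features x samples, TPM) for the transcriptome level and the
#'   source/non-source test.
#' @return Object of class `eremap_cohort` (a list of summaries).
#' @export
characterize_cohort <- function(records, repeats, genes, family_expression = NULL) {
  if (!nrow(records)) abort("characterize_cohort: no records")
  main <- c("LINE", "LTR", "SINE")
  # immunopeptidome proportions (one vote per peptide x group)
  imm <- records |> distinct(.data$peptide, .data$group) |> filter(.data$group %in% main)
  imm_counts <- vapply(main, function(g) sum(imm$group == g), numeric(1))
  # genome proportions: repeat base share by group
  rep_main <- repeats[repeats$group %in% main, , drop = FALSE]
  bases <- vapply(main, function(g) {
    sum((rep_main$end - rep_main$start)[rep_main$group == g])
  }, numeric(1))
  genome_prop <- bases / sum(bases)
  group_test <- chi_squared(imm_counts, genome_prop)
  # transcriptome proportions
  trans_prop <- NULL
  if (!is.null(family_expression)) {
    fam_group <- repeats |> distinct(.data$family, .data$group)
    grp <- setNames(fam_group$group, fam_group$family)[family_expression$feature_id]
    m <- expr_matrix(family_expression)
    keep <- grp %in% main
    shares <- vapply(main, function(g) {
      colSums(m[keep & grp == g, , drop = FALSE]) / colSums(m[keep, , drop = FALSE])
    }, numeric(ncol(m)))
    if (is.null(dim(shares))) shares <- matrix(shares, nrow = 1, dimnames = list(NULL, main))
    trans_prop <- colMeans(shares)
  }
  # region distribution of ereMAP loci vs all repeat intervals
  rep_region <- classify_repeat_regions(repeats, genes)
  bg_counts <- table(factor(rep_region, levels = c("CDS", "intronic", "intergenic")))
  obs_counts <- table(factor(records$region, levels = c("CDS", "intronic", "intergenic")))
  region_test <- tryCatch(
    chi_squared(as.numeric(obs_counts), as.numeric(bg_counts) / sum(bg_counts)),
    error = function(e) NULL)
  # copy number vs ereMAP counts
  copies <- repeats |> dplyr::count(.data$family, name = "copies")
  per_family <- records |> distinct(.data$peptide, .data$family) |>
    dplyr::count(.data$family, name = "n_eremaps")
  cn <- copies |> left_join(per_family, by = "family") |>
    mutate(n_eremaps = dplyr::coalesce(.data$n_eremaps, 0L))
  copy_cor <- tryCatch(kendall_tau(cn$copies, cn$n_eremaps), error = function(e) NULL)
  # source vs non-source family expression
  source_test <- NULL
  if (!is.null(family_expression)) {
    mean_log <- rowMeans(log10(expr_matrix(family_expression) + 1))
    is_source <- family_expression$feature_id %in% records$family
    if (any(is_source) && any(!is_source)) {
      source_test <- mann_whitney_exact(mean_log[is_source], mean_log[!is_source])
    }
  }
  structure(list(
    group_proportions = tibble(
      group = main,
      genome = genome_prop,
      transcriptome = if (is.null(trans_prop)) NA_real_ else unname(trans_prop),
      immunopeptidome = imm_counts / sum(imm_counts)),
    group_test = group_test,
    region_proportions = tibble(
      region = c("CDS", "intronic", "intergenic"),
      repeats = as.numeric(bg_counts) / sum(bg_counts),
      eremaps = as.numeric(obs_counts) / sum(obs_counts)),
    region_test = region_test,
    copy_number = list(data = cn, test = copy_cor),
    source_expression_test = source_test),
    class = "eremap_cohort")
}

# region of each repeat interval, CDS > intronic > intergenic precedence
classify_repeat_regions <- function(repeats, genes) {
  rgr <- intervals_granges(repeats)
  region <- rep("intergenic", nrow(repeats))
  spans <- gene_spans(genes)
  if (nrow(spans)) {
    sg <- GenomicRanges::GRanges(spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end))
    region[GenomicRanges::countOverlaps(rgr, sg, ignore.strand = TRUE) > 0] <- "intronic"
  }
  cds <- genes[genes$feature == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    cg <- intervals_granges(cds)
    region[GenomicRanges::countOverlaps(rgr, cg, ignore.strand = TRUE) > 0] <- "CDS"
  }
  region
}

#' @export
print.eremap_cohort <- function(x, ...) {
  cat("ereMAP cohort characterization\n")
  print(x$group_proportions)
  print(x$region_proportions)
  invisible(x)
}
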