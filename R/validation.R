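# The ereMAP filter cascade: target-decoy FDR, binder filter, proteome
# status, k-mer arbitration of coding sequences (the 10x rule), I/L variant
# check, genomic locus classification and the orientation decision tree.

# ---- FDR and binder filters ------------------------------------------------

#' Target-decoy FDR filter on peptide scores
#'
#' Chooses the minimal score threshold t such that
#' `#(decoys >= t) / #(targets >= t) <= q` and returns the targets at or
#' above it (the maximal set with estimated FDR <= q). Decoys are removed
#' from the output.
#'
#' @param candidates Tibble with columns `score`, `is_decoy`.
#' @param q FDR level (default 0.05).
#' @return The passing target rows; the chosen threshold is in the
#'   `score_threshold` attribute (`Inf` when nothing passes).
#' @export
apply_fdr <- function(candidates, q = 0.05) {
  if (!any(candidates$is_decoy)) abort("apply_fdr: no decoys present, FDR undefined")
  ord <- order(candidates$score, decreasing = TRUE)
  sc <- candidates$score[ord]
  dec <- candidates$is_decoy[ord]
  # counts at or above each distinct threshold (last index of each tie run)
  last <- which(!duplicated(sc, fromLast = TRUE))
  n_d <- cumsum(dec)[last]
  n_t <- cumsum(!dec)[last]
  pass <- n_t > 0 & n_d / n_t <= q
  t_star <- if (any(pass)) sc[last[max(which(pass))]] else Inf
  out <- candidates[!candidates$is_decoy & candidates$score >= t_star, , drop = FALSE]
  attr(out, "score_threshold") <- t_star
  out
}

#' Length and MHC binding-rank filter
#'
#' Keeps 8-11-amino-acid peptides whose best percentile rank over the
#' sample's HLA alleles is at or below `rank_max` (default 2, read
#' inclusively). Missing ranks for some alleles are ignored.
#'
#' @param candidates Tibble with columns `peptide`, `best_rank`.
#' @param rank_max Maximum percentile rank (default 2).
#' @param min_len,max_len Allowed peptide lengths (defaults 8 and 11).
#' @return The passing rows.
#' @export
filter_binders <- function(candidates, rank_max = 2, min_len = 8, max_len = 11) {
  len <- nchar(candidates$peptide)
  keep <- len >= min_len & len <= max_len &
    !is.na(candidates$best_rank) & candidates$best_rank <= rank_max
  candidates[keep, , drop = FALSE]
}

#' ERE status from proteome membership
#'
#' `yes` = seen only in the ERE proteome, `no` = only in the canonical
#' proteome, `maybe` = both, `undetermined` = neither (a search/proteome
#' mismatch; excluded downstream with a reason).
#'
#' @param membership Tibble from [proteome_contains()] (columns `peptide`,
#'   `in_ere`, `in_canonical`).
#' @return The tibble with a `status` column added.
#' @export
assign_status <- function(membership) {
  membership$status <- dplyr::case_when(
    membership$in_ere & !membership$in_canonical ~ "yes",
    !membership$in_ere & membership$in_canonical ~ "no",
    membership$in_ere & membership$in_canonical ~ "maybe",
    TRUE ~ "undetermined")
  membership
}

# ---- MCS recovery ----------------------------------------------------------

#' Recover peptide-coding sequences (MCS) from translated read entries
#'
#' Locates each peptide in the amino-acid entries of a read-derived proteome
#' and maps every occurrence back to the nucleotide subsequence that encodes
#' it (via the entry's stored frame sequence).
#'
#' @param proteome Proteome tibble whose entries carry `frame_nt`/`aa_start`
#'   (ERE and/or canonical-read entries).
#' @param peptides Character vector of peptides.
#' @return Tibble with columns `peptide`, `entry_id`, `read_id`, `source`,
#'   `mcs`.
#' @export
find_peptide_mcs <- function(proteome, peptides) {
  peptides <- unique(check_peptides(peptides))
  rows <- purrr::map(peptides, function(p) {
    hit <- which(grepl(p, proteome$aa, fixed = TRUE))
    if (!length(hit)) return(NULL)
    sub <- proteome[hit, , drop = FALSE]
    occ <- gregexpr(p, sub$aa, fixed = TRUE)
    n_occ <- lengths(occ)
    pos <- unlist(occ)                       # 1-based aa position in entry
    idx <- rep(seq_len(nrow(sub)), n_occ)
    nt_from <- 3L * (sub$aa_start[idx] + pos - 1L) + 1L
    tibble(peptide = p,
           entry_id = sub$entry_id[idx],
           read_id = sub$read_id[idx],
           source = sub$source[idx],
           mcs = substr(sub$frame_nt[idx], nt_from, nt_from + 3L * nchar(p) - 1L))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(peptide = character(), entry_id = character(),
                  read_id = character(), source = character(), mcs = character())
  }
  out
}

# ---- k-mer arbitration -----------------------------------------------------

#' Arbitrate a "maybe" peptide between the ERE and canonical read datasets
#'
#' Implements the coding-sequence rules: a peptide is discarded if any of its
#' MCS is seen only in the canonical read dataset (ERE minimal occurrence 0
#' with canonical minimal occurrence > 0), discarded unless supported by more
#' than one read, and otherwise kept iff the most abundant MCS (by ERE
#' minimal k-mer occurrence; ties broken by canonical occurrence ascending,
#' then lexicographically) has ERE minimal occurrence at least `ratio_min`
#' times its canonical minimal occurrence.
#'
#' @param mcs Character vector of the candidate's coding sequences (each
#'   >= k nucleotides).
#' @param ere_table,canonical_table `kmer_table`s of the ERE and canonical
#'   read datasets.
#' @param n_support_reads Number of distinct reads encoding the peptide.
#' @param ratio_min The abundance ratio (default 10, inclusive).
#' @param min_reads Minimum read support (default 2, i.e. "more than one").
#' @return List with `keep` (logical), `reason` (`NA` when kept), `mcs_table`
#'   (per-MCS minimal occurrences), `top_mcs`.
#' @export
resolve_maybe <- function(mcs, ere_table, canonical_table, n_support_reads,
                          ratio_min = 10, min_reads = 2) {
  mcs <- unique(toupper(mcs))
  if (!length(mcs)) abort("resolve_maybe: empty MCS set")
  min_ere <- kmer_min_count(ere_table, mcs)
  min_can <- kmer_min_count(canonical_table, mcs)
  tbl <- tibble(mcs = mcs, min_ere = min_ere, min_can = min_can) |>
    arrange(dplyr::desc(.data$min_ere), .data$min_can, .data$mcs)
  verdict <- function(keep, reason) {
    list(keep = keep, reason = reason, mcs_table = tbl, top_mcs = tbl$mcs[1])
  }
  if (any(tbl$min_ere == 0 & tbl$min_can > 0)) {
    return(verdict(FALSE, "mcs_canonical_only"))
  }
  if (n_support_reads < min_reads) {
    return(verdict(FALSE, "insufficient_reads"))
  }
  if (tbl$min_ere[1] >= ratio_min * tbl$min_can[1]) verdict(TRUE, NA_character_)
  else verdict(FALSE, "ratio_below_10x")
}

# ---- I/L variant check -----------------------------------------------------

il_variants <- function(peptide) {
  pos <- which(strsplit(peptide, "")[[1]] %in% c("I", "L"))
  if (length(pos) > 20) abort("il_variants: more than 20 I/L positions")
  if (!length(pos)) return(character(0))
  grid <- expand.grid(rep(list(c("I", "L")), length(pos)), stringsAsFactors = FALSE)
  out <- vapply(seq_len(nrow(grid)), function(i) {
    v <- peptide
    for (j in seq_along(pos)) substr(v, pos[j], pos[j]) <- grid[i, j]
    v
  }, character(1))
  setdiff(unique(out), peptide)
}

#' Isoleucine/leucine indistinguishability check
#'
#' MS cannot distinguish I from L, so every I/L variant of a candidate is
#' searched in the personalized proteome; the candidate is discarded when a
#' variant is present with higher expression than the candidate's own
#' source. Canonical entries are compared on transcript TPM and ERE entries
#' on supporting-read counts; since the two scales are not commensurable, a
#' variant found in the canonical proteome when the candidate has no
#' canonical presence is treated as higher-expressed (conservative) and the
#' conflict is flagged.
#'
#' @param peptide Candidate peptide.
#' @param proteome Combined proteome tibble.
#' @param cand_read_support Candidate's ERE supporting-read count.
#' @param ere_read_support Function mapping a peptide to its ERE
#'   supporting-read count (used for variants).
#' @return List with `keep`, `reason` (`NA` when kept), `conflict` (logical:
#'   cross-scale comparison was used).
#' @export
il_variant_check <- function(peptide, proteome, cand_read_support, ere_read_support) {
  vars <- il_variants(peptide)
  if (!length(vars)) return(list(keep = TRUE, reason = NA_character_, conflict = FALSE))
  can <- proteome[proteome$source == "canonical-transcript", , drop = FALSE]
  hay_can <- paste(can$aa, collapse = "#")
  cand_can_tpm <- {
    hit <- vapply(seq_len(nrow(can)), function(i) grepl(peptide, can$aa[i], fixed = TRUE), logical(1))
    if (any(hit)) max(can$expression[hit]) else NA_real_
  }
  for (v in vars) {
    in_can <- grepl(v, hay_can, fixed = TRUE)
    if (in_can) {
      hit <- vapply(seq_len(nrow(can)), function(i) grepl(v, can$aa[i], fixed = TRUE), logical(1))
      v_tpm <- max(can$expression[hit])
      if (!is.na(cand_can_tpm)) {
        if (v_tpm > cand_can_tpm) {
          return(list(keep = FALSE, reason = "il_variant_higher_expression", conflict = FALSE))
        }
      } else {
        # candidate has no canonical presence: canonical evidence for the
        # variant takes precedence over read-count evidence
        return(list(keep = FALSE, reason = "il_variant_higher_expression", conflict = TRUE))
      }
    }
    v_reads <- ere_read_support(v)
    if (v_reads > cand_read_support) {
      return(list(keep = FALSE, reason = "il_variant_higher_expression", conflict = FALSE))
    }
  }
  list(keep = TRUE, reason = NA_character_, conflict = FALSE)
}

# ---- genomic locus classification -----------------------------------------

# exon-union span per gene (gene body used for intron classification)
gene_spans <- function(genes) {
  genes |>
    filter(.data$feature == "exon") |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
}

#' Locate and classify the genomic origin of a coding sequence
#'
#' Finds all exact-match loci of the MCS in the genome (both strands). Loci
#' contained in a repeat interval define the candidate's ERE origin; each is
#' classified by region with precedence CDS > intronic > intergenic (CDS =
#' overlap with an annotated CDS; intronic = inside a gene body without CDS
#' overlap; intergenic otherwise) and by orientation relative to the repeat
#' and to the gene.
#'
#' @param mcs The coding sequence (nucleotides).
#' @param repeats Repeat tibble.
#' @param genes Gene-model tibble.
#' @param genome Tibble with columns `name`, `sequence`, or a named
#'   `DNAStringSet`.
#' @return List with `loci` (tibble: one row per (ERE locus, containing
#'   repeat): `chrom`, `start`, `end`, `mcs_strand`, `family`, `group`,
#'   `region`, `sense_vs_ere`, `sense_vs_gene`, `gene_id`), `n_ere_loci`
#'   (distinct repeat intervals containing a locus), `n_loci_total` (all
#'   exact matches).
#' @export
classify_origin <- function(mcs, repeats, genes, genome) {
  mcs <- check_nt(mcs)
  gset <- if (methods::is(genome, "DNAStringSet")) genome else
    Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  hit_strand <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, gset)
    n <- lengths(m)
    if (!sum(n)) return(NULL)
    tibble(chrom = rep(names(gset), n),
           start = unlist(lapply(m, IRanges::start)) - 1L,
           end = unlist(lapply(m, IRanges::end)),
           mcs_strand = strand)
  }
  loci <- bind_rows(hit_strand(mcs, "+"), hit_strand(revcomp(mcs), "-"))
  if (is.null(loci) || !nrow(loci)) {
    return(list(loci = NULL, n_ere_loci = 0L, n_loci_total = 0L))
  }
  lgr <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end))
  rgr <- intervals_granges(repeats)
  ov <- GenomicRanges::findOverlaps(lgr, rgr, type = "within", ignore.strand = TRUE)
  n_ere_loci <- length(unique(S4Vectors::subjectHits(ov)))
  if (!length(ov)) {
    return(list(loci = loci[0, ], n_ere_loci = 0L, n_loci_total = nrow(loci)))
  }
  li <- S4Vectors::queryHits(ov); ri <- S4Vectors::subjectHits(ov)
  out <- loci[li, , drop = FALSE]
  out$family <- repeats$family[ri]
  out$group <- repeats$group[ri]
  out$sense_vs_ere <- ifelse(out$mcs_strand == repeats$strand[ri], "sense", "antisense")
  # region classification with CDS > intronic > intergenic precedence
  cds <- genes[genes$feature == "CDS", , drop = FALSE]
  spans <- gene_spans(genes)
  ogr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start + 1L, out$end))
  region <- rep("intergenic", nrow(out))
  gene_strand <- rep(NA_character_, nrow(out))
  gene_id <- rep(NA_character_, nrow(out))
  if (nrow(spans)) {
    sg <- GenomicRanges::GRanges(spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end))
    ovs <- GenomicRanges::findOverlaps(ogr, sg, ignore.strand = TRUE)
    first <- !duplicated(S4Vectors::queryHits(ovs))
    qi <- S4Vectors::queryHits(ovs)[first]; si <- S4Vectors::subjectHits(ovs)[first]
    region[qi] <- "intronic"
    gene_strand[qi] <- spans$strand[si]
    gene_id[qi] <- spans$gene_id[si]
  }
  if (nrow(cds)) {
    cg <- intervals_granges(cds)
    ovc <- GenomicRanges::findOverlaps(ogr, cg, ignore.strand = TRUE)
    first <- !duplicated(S4Vectors::queryHits(ovc))
    qi <- S4Vectors::queryHits(ovc)[first]; ci <- S4Vectors::subjectHits(ovc)[first]
    region[qi] <- "CDS"
    gene_strand[qi] <- cds$strand[ci]
    gene_id[qi] <- cds$gene_id[ci]
  }
  out$region <- region
  out$gene_id <- gene_id
  out$sense_vs_gene <- ifelse(is.na(gene_strand), NA_character_,
                              ifelse(out$mcs_strand == gene_strand, "sense", "antisense"))
  list(loci = out, n_ere_loci = n_ere_loci, n_loci_total = nrow(loci))
}

#' Orientation decision tree for ereMAP candidates
#'
#' A candidate whose coding sequence maps in the sense of a gene coding
#' sequence is discarded; intergenic candidates are kept no matter their
#' orientation; intronic candidates are discarded iff they map in the sense
#' of the intron's gene, in the antisense of the ERE, and in no other ERE
#' sequence (single ERE locus).
#'
#' @param region `"CDS"`, `"intronic"` or `"intergenic"`.
#' @param sense_vs_gene `"sense"`, `"antisense"` or `NA`.
#' @param sense_vs_ere `"sense"` or `"antisense"`.
#' @param n_ere_loci Number of distinct repeat intervals carrying the MCS.
#' @return List with `keep` (logical) and `reason` (`NA` when kept).
#' @export
orientation_decision <- function(region, sense_vs_gene, sense_vs_ere, n_ere_loci) {
  if (region == "CDS" && identical(sense_vs_gene, "sense")) {
    return(list(keep = FALSE, reason = "cds_sense"))
  }
  if (region == "intronic" && identical(sense_vs_gene, "sense") &&
      identical(sense_vs_ere, "antisense") && n_ere_loci == 1L) {
    return(list(keep = FALSE, reason = "intronic_gene_sense_ere_antisense_single_locus"))
  }
  list(keep = TRUE, reason = NA_character_)
}
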