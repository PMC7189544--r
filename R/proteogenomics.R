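# Per-sample proteome construction: QC-filter aligned reads, partition them
# into ERE and canonical datasets by annotation containment, six-frame
# translate the ERE reads into a theoretical ERE proteome, and build the
# personalized canonical proteome from expressed transcripts with variants.

# ---- alignment filtering ---------------------------------------------------

# FLAG bits that disqualify a record: unmapped, mate unmapped, secondary,
# QC-fail, duplicate, supplementary (mask 3852)
SAM_REJECT_MASK <- 4L + 8L + 256L + 512L + 1024L + 2048L

#' Filter aligned reads to proper primary pairs
#'
#' Keeps reads that are mapped, properly paired, primary, non-supplementary,
#' non-duplicate, not QC-fail, with the mate mapped, and in one of the two
#' standard FR pair orientations. This accepts exactly the four FLAG values
#' 83, 99, 147 and 163 and rejects any record intersecting the mask 3852.
#'
#' @param reads Tibble from [read_sam_min()] (decoded flag columns present).
#' @return The kept rows.
#' @export
filter_alignments <- function(reads) {
  keep <- reads$is_paired & reads$is_proper_pair &
    xor(reads$is_reverse, reads$mate_reverse) &
    xor(reads$is_first, reads$is_second) &
    bitwAnd(reads$flag, SAM_REJECT_MASK) == 0L
  reads[keep, , drop = FALSE]
}

# ---- read partitioning -----------------------------------------------------

reads_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(start = reads$start + 1L, end = reads$end))
}

intervals_granges <- function(tbl) {
  GenomicRanges::GRanges(tbl$chrom,
                         IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
                         strand = tbl$strand %||% "*")
}

contained_in <- function(read_gr, ann_gr) {
  if (!length(ann_gr)) return(rep(FALSE, length(read_gr)))
  GenomicRanges::countOverlaps(read_gr, ann_gr, type = "within",
                               ignore.strand = TRUE) > 0
}

#' Partition reads into ERE and canonical datasets
#'
#' A read is ERE-eligible iff its reference span is entirely contained in at
#' least one repeat interval, and canonical iff entirely contained in at
#' least one exon/CDS interval of the gene models. A read seen in the
#' canonical dataset is discarded from the ERE dataset (containment in both
#' puts it in canonical only); reads contained in neither are discarded with
#' a reason.
#'
#' @param reads QC-filtered read tibble (see [filter_alignments()]).
#' @param repeats Repeat tibble ([read_repeatmasker()]).
#' @param genes Gene-model tibble ([read_gtf()]); its `exon` and `CDS` rows
#'   define canonical containment.
#' @return List of class `read_partition` with tibbles `ere`, `canonical`,
#'   `discarded` (extra column `reason`).
#' @export
partition_reads <- function(reads, repeats, genes) {
  if (!nrow(reads)) {
    return(structure(list(ere = reads, canonical = reads,
                          discarded = mutate(reads, reason = character(0))),
                     class = "read_partition"))
  }
  gr <- reads_granges(reads)
  exonic <- genes[genes$feature %in% c("exon", "CDS"), , drop = FALSE]
  in_repeat <- contained_in(gr, intervals_granges(repeats))
  in_exon <- contained_in(gr, intervals_granges(exonic))
  known_contig <- reads$chrom %in% union(repeats$chrom, exonic$chrom)
  ere <- in_repeat & !in_exon
  canonical <- in_exon
  disc <- !ere & !canonical
  discarded <- reads[disc, , drop = FALSE]
  discarded$reason <- ifelse(known_contig[disc], "outside_annotation", "unknown_contig")
  structure(list(ere = reads[ere, , drop = FALSE],
                 canonical = reads[canonical, , drop = FALSE],
                 discarded = discarded),
            class = "read_partition")
}

#' @export
print.read_partition <- function(x, ...) {
  cat(sprintf("Read partition: %d ERE, %d canonical, %d discarded\n",
              nrow(x$ere), nrow(x$canonical), nrow(x$discarded)))
  invisible(x)
}

# ---- translation -----------------------------------------------------------

#' Split a read sequence at ambiguous bases
#'
#' @param sequence A nucleotide string over `{A,C,G,T,N}`.
#' @return Tibble with columns `segment` (N-free subsequences) and `offset`
#'   (0-based position of the segment in the input).
#' @export
segment_ambiguous <- function(sequence) {
  sequence <- check_nt(sequence)
  if (!nzchar(sequence)) return(tibble(segment = character(), offset = integer()))
  hits <- gregexpr("[ACGT]+", sequence)[[1]]
  if (hits[1] == -1) return(tibble(segment = character(), offset = integer()))
  tibble(segment = regmatches(sequence, gregexpr("[ACGT]+", sequence))[[1]],
         offset = as.integer(hits) - 1L)
}

# vectorised translation of N-free nucleotide strings (trailing partial codon
# dropped); returns "" for inputs shorter than one codon
translate_nt <- function(x) {
  out <- rep("", length(x))
  len <- (nchar(x) %/% 3L) * 3L
  ok <- len >= 3L
  if (any(ok)) {
    trimmed <- substr(x[ok], 1L, len[ok])
    out[ok] <- as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                                                  no.init.codon = TRUE))
  }
  out
}

#' Six-frame translation
#'
#' Translates an N-free nucleotide sequence in frames +1, +2, +3 and in the
#' same three frames of its reverse complement, under the standard genetic
#' code, stop codons as `"*"`, trailing partial codons dropped.
#'
#' @param nt_sequence Nucleotide string over `{A,C,G,T}`, length >= 3.
#' @return Character vector of 6 amino-acid strings, named `F1,F2,F3,R1,R2,R3`
#'   (empty strings when a frame is shorter than one codon).
#' @export
six_frame_translate <- function(nt_sequence) {
  nt_sequence <- check_nt(nt_sequence)
  if (grepl("N", nt_sequence)) abort("six_frame_translate: sequence must be N-free")
  if (nchar(nt_sequence) < 3) {
    return(setNames(rep("", 6), c("F1", "F2", "F3", "R1", "R2", "R3")))
  }
  rc <- revcomp(nt_sequence)
  frames <- c(substr(nt_sequence, 1, nchar(nt_sequence)),
              substr(nt_sequence, 2, nchar(nt_sequence)),
              substr(nt_sequence, 3, nchar(nt_sequence)),
              substr(rc, 1, nchar(rc)), substr(rc, 2, nchar(rc)), substr(rc, 3, nchar(rc)))
  setNames(translate_nt(frames), c("F1", "F2", "F3", "R1", "R2", "R3"))
}

#' Remove sequence following stop codons
#'
#' Default mode keeps only the prefix preceding the first stop (the literal
#' reading of splicing out "sequences following stop codons"); mode
#' `"split"` cuts at every stop and keeps all resulting segments. Either
#' way only segments of at least `min_len` residues survive.
#'
#' @param aa_with_stops Amino-acid string possibly containing `"*"`.
#' @param min_len Minimum retained length (default 8).
#' @param mode `"prefix"` (default) or `"split"`.
#' @return Tibble with columns `aa` and `aa_start` (0-based residue offset of
#'   the segment within the input).
#' @export
splice_at_stops <- function(aa_with_stops, min_len = 8, mode = c("prefix", "split")) {
  mode <- match.arg(mode)
  if (mode == "prefix") {
    seg <- sub("\\*.*$", "", aa_with_stops)
    out <- tibble(aa = seg, aa_start = 0L)
  } else {
    hits <- gregexpr("[^*]+", aa_with_stops)[[1]]
    if (hits[1] == -1) return(tibble(aa = character(), aa_start = integer()))
    out <- tibble(aa = regmatches(aa_with_stops, gregexpr("[^*]+", aa_with_stops))[[1]],
                  aa_start = as.integer(hits) - 1L)
  }
  out[nchar(out$aa) >= min_len, , drop = FALSE]
}

# ---- ERE proteome ----------------------------------------------------------

#' Build the theoretical ERE proteome from ERE reads
#'
#' For every ERE read: trim at ambiguous bases, translate every N-free
#' segment in all six frames, splice at stop codons, and keep sequences of
#' at least `min_len` amino acids, each under a unique sequential entry id.
#' Duplicate amino-acid sequences are retained as separate entries with
#' distinct provenance. Each entry carries `frame_nt`, the nucleotide
#' sequence whose direct translation is the frame, so peptide hits can be
#' mapped back to their coding sequences.
#'
#' @param reads Tibble with columns `read_id`, `sequence` (e.g. the `ere`
#'   element of [partition_reads()]).
#' @param min_len Minimum entry length in amino acids (default 8).
#' @param mode Stop-splicing mode, see [splice_at_stops()].
#' @return Proteome tibble with columns `entry_id`, `aa`, `source`
#'   (`"ere-read"`), `read_id`, `frame`, `frame_nt`, `aa_start`,
#'   `transcript_id` (`NA`), `expression` (`NA`).
#' @export
build_ere_proteome <- function(reads, min_len = 8, mode = c("prefix", "split")) {
  mode <- match.arg(mode)
  empty <- tibble(entry_id = character(), aa = character(), source = character(),
                  read_id = character(), frame = character(), frame_nt = character(),
                  aa_start = integer(), transcript_id = character(),
                  expression = numeric())
  if (!nrow(reads)) return(empty)
  seqs <- check_nt(reads$sequence)
  # explode reads into N-free segments (vectorised)
  seg_hits <- gregexpr("[ACGT]+", seqs)
  seg_list <- regmatches(seqs, seg_hits)
  n_seg <- lengths(seg_list)
  has <- n_seg > 0 & vapply(seg_list, function(s) length(s) > 0 && s[1] != "", logical(1))
  read_idx <- rep(seq_along(seqs), n_seg)
  segments <- unlist(seg_list, use.names = FALSE)
  keep <- nchar(segments) >= 3 * min_len
  segments <- segments[keep]
  read_idx <- read_idx[keep]
  if (!length(segments)) return(empty)
  # six frames per segment
  rc <- revcomp(segments)
  frame_names <- c("F1", "F2", "F3", "R1", "R2", "R3")
  rows <- vector("list", 6)
  for (f in 1:6) {
    base <- if (f <= 3) segments else rc
    off <- (f - 1) %% 3
    frame_nt <- substr(base, 1 + off, nchar(base))
    len <- (nchar(frame_nt) %/% 3L) * 3L
    frame_nt <- substr(frame_nt, 1, len)
    aa_full <- translate_nt(frame_nt)
    spl <- if (mode == "prefix") {
      tibble(i = seq_along(aa_full), aa = sub("\\*.*$", "", aa_full), aa_start = 0L)
    } else {
      hits <- gregexpr("[^*]+", aa_full)
      segs <- regmatches(aa_full, hits)   # character(0) when no match
      ns <- lengths(segs)
      starts <- unlist(lapply(hits, function(h) if (h[1] == -1) integer(0) else as.integer(h) - 1L))
      tibble(i = rep(seq_along(aa_full), ns),
             aa = unlist(segs, use.names = FALSE) %||% character(0),
             aa_start = starts %||% integer(0))
    }
    spl <- spl[nchar(spl$aa) >= min_len, , drop = FALSE]
    if (!nrow(spl)) next
    rows[[f]] <- tibble(
      aa = spl$aa, read_idx = read_idx[spl$i],
      frame = frame_names[f], frame_nt = frame_nt[spl$i], aa_start = spl$aa_start)
  }
  out <- bind_rows(rows)
  if (!nrow(out)) return(empty)
  out <- out |> arrange(.data$read_idx, .data$frame, .data$aa_start)
  tibble(
    entry_id = sprintf("ere|%06d", seq_len(nrow(out))),
    aa = out$aa, source = "ere-read",
    read_id = reads$read_id[out$read_idx],
    frame = out$frame, frame_nt = out$frame_nt, aa_start = out$aa_start,
    transcript_id = NA_character_, expression = NA_real_)
}

# ---- personalized canonical proteome --------------------------------------

#' Build the personalized canonical proteome
#'
#' Applies single-nucleotide variants with `alt_count >= 5` to transcript
#' sequences, then translates every transcript with TPM > 0 in its annotated
#' frame from its annotated start (first AUG when no CDS start is given),
#' stopping at the first stop codon.
#'
#' @param transcripts Tibble with columns `name`, `sequence` (transcript
#'   coordinates, 5'->3').
#' @param variants Tibble as from [read_variants()], or `NULL`.
#' @param tpm Named numeric vector of transcript TPM.
#' @param cds_start Optional named integer vector: 1-based position of the
#'   annotated start codon within each transcript.
#' @param min_alt_count Minimum alternate count to apply a variant (default 5).
#' @return Proteome tibble in the layout of [build_ere_proteome()], with
#'   `source = "canonical-transcript"` and `expression` = TPM.
#' @export
build_personalized_proteome <- function(transcripts, variants = NULL, tpm,
                                        cds_start = NULL, min_alt_count = 5) {
  seqs <- setNames(check_nt(transcripts$sequence), transcripts$name)
  if (!is.null(variants) && nrow(variants)) {
    use <- variants[variants$alt_count >= min_alt_count &
                      nchar(variants$ref) == 1 & nchar(variants$alt) == 1, , drop = FALSE]
    for (i in seq_len(nrow(use))) {
      tx <- use$transcript_id[i]; pos <- use$pos[i]
      if (!tx %in% names(seqs)) abort(sprintf("variant for unknown transcript %s", tx))
      if (substr(seqs[[tx]], pos, pos) != use$ref[i]) {
        abort(sprintf("variant ref mismatch in %s at position %d", tx, pos))
      }
      substr(seqs[[tx]], pos, pos) <- use$alt[i]
    }
  }
  expressed <- names(seqs)[!is.na(tpm[names(seqs)]) & tpm[names(seqs)] > 0]
  rows <- purrr::map(expressed, function(tx) {
    s <- seqs[[tx]]
    start <- if (!is.null(cds_start) && tx %in% names(cds_start)) cds_start[[tx]]
             else as.integer(regexpr("ATG", s, fixed = TRUE))
    if (is.na(start) || start < 1) return(NULL)
    frame_nt <- substr(s, start, nchar(s))
    frame_nt <- substr(frame_nt, 1, (nchar(frame_nt) %/% 3L) * 3L)
    if (nchar(frame_nt) < 3) return(NULL)
    aa_full <- translate_nt(frame_nt)
    aa <- sub("\\*.*$", "", aa_full)
    if (!nzchar(aa)) return(NULL)
    tibble(entry_id = paste0("can|", tx), aa = aa, source = "canonical-transcript",
           read_id = NA_character_, frame = "F1",
           frame_nt = substr(frame_nt, 1, 3 * nchar(aa)), aa_start = 0L,
           transcript_id = tx, expression = unname(tpm[[tx]]))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(entry_id = character(), aa = character(), source = character(),
                  read_id = character(), frame = character(), frame_nt = character(),
                  aa_start = integer(), transcript_id = character(), expression = numeric())
  }
  out
}

#' Concatenate ERE and canonical proteomes
#'
#' @param ere,canonical Proteome tibbles.
#' @return The combined proteome; duplicate entry ids are an error.
#' @export
concat_proteomes <- function(ere, canonical) {
  out <- bind_rows(ere, canonical)
  if (anyDuplicated(out$entry_id)) abort("entry id collision between proteomes")
  out
}

#' Query exact-substring membership of peptides in a proteome
#'
#' @param proteome Combined proteome tibble.
#' @param peptides Character vector of 8-11-mer peptides.
#' @return Tibble with columns `peptide`, `in_ere`, `in_canonical`.
#' @export
proteome_contains <- function(proteome, peptides) {
  peptides <- check_peptides(peptides)
  hay_ere <- paste(proteome$aa[proteome$source == "ere-read"], collapse = "#")
  hay_can <- paste(proteome$aa[proteome$source == "canonical-transcript"], collapse = "#")
  tibble(peptide = peptides,
         in_ere = vapply(peptides, function(p) grepl(p, hay_ere, fixed = TRUE),
                         logical(1), USE.NAMES = FALSE),
         in_canonical = vapply(peptides, function(p) grepl(p, hay_can, fixed = TRUE),
                               logical(1), USE.NAMES = FALSE))
}

#' Write a proteome as FASTA with provenance-encoding headers
#' @param proteome Proteome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  hdr <- sprintf("%s|%s|%s|%s", proteome$entry_id, proteome$source,
                 dplyr::coalesce(proteome$read_id, proteome$transcript_id),
                 proteome$frame)
  write_fasta(tibble(name = hdr, sequence = proteome$aa), path)
}
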