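# Readers and writers for the formats the pipeline touches.
#
# One coordinate convention rules everywhere inside the package: 0-based,
# half-open `[start, end)`, strand in {+, -}. Conversion to and from the
# 1-based closed conventions of RepeatMasker .out and GTF happens only here,
# at the parse/serialise boundary.

# ---- coordinate conversion -------------------------------------------------

# 1-based closed -> 0-based half-open
closed_to_internal <- function(begin, end) list(start = begin - 1L, end = as.integer(end))

# 0-based half-open -> 1-based closed
internal_to_closed <- function(start, end) list(begin = as.integer(start) + 1L, end = as.integer(end))

check_strand <- function(strand, where = "input") {
  ok <- strand %in% c("+", "-")
  if (!all(ok)) {
    abort(sprintf("unknown strand symbol %s in %s",
                  paste(unique(strand[!ok]), collapse = ", "), where))
  }
  strand
}

# ---- repeats ---------------------------------------------------------------

#' Read repeat annotations (RepeatMasker .out or BED)
#'
#' Parses a RepeatMasker `.out` table (1-based closed coordinates) or a
#' 6-column BED file (already 0-based half-open) into a tibble of repeat
#' records on the internal 0-based half-open convention. Repeat families are
#' mapped to one of the three main ERE groups (LINE, LTR, SINE) through
#' `family_group_map`; families absent from the map get group `"other"` and
#' are excluded from group-proportion analyses downstream.
#'
#' @param path Path to the annotation file.
#' @param family_group_map Named character vector, family -> group
#'   (e.g. `c(AluY = "SINE", L1HS = "LINE")`). May be `NULL` (all `"other"`).
#' @param format `"auto"` (default, sniffed from content), `"out"` or `"bed"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `element_name`, `family`, `group`.
#' @export
read_repeatmasker <- function(path, family_group_map = NULL, format = c("auto", "out", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (format == "auto") {
    # .out files open with a "SW score" banner; BED lines start with a contig
    format <- if (length(lines) && grepl("^\\s*SW", lines[[1]])) "out" else "bed"
  }
  if (format == "out") {
    hdr <- grepl("^\\s*(SW|score)", lines)
    lineno <- lineno[!hdr]
    lines <- lines[!hdr]
  }
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), element_name = character(),
                  family = character(), group = character()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  if (format == "out") {
    rec <- purrr::map2(fields, seq_along(fields), function(f, i) {
      if (length(f) < 11) {
        abort(sprintf("malformed RepeatMasker line %d: expected >= 11 fields, got %d",
                      lineno[[i]], length(f)))
      }
      begin <- suppressWarnings(as.integer(f[[6]]))
      end <- suppressWarnings(as.integer(f[[7]]))
      if (is.na(begin) || is.na(end)) {
        abort(sprintf("malformed RepeatMasker line %d: non-numeric coordinates", lineno[[i]]))
      }
      strand <- f[[9]]
      if (strand == "C") strand <- "-"
      list(chrom = f[[5]], begin = begin, end = end, strand = strand,
           family = f[[10]],
           element_name = if (length(f) >= 15) paste0(f[[10]], "#", f[[15]]) else
             paste0(f[[10]], "#", i))
    })
    chrom <- purrr::map_chr(rec, "chrom")
    conv <- closed_to_internal(purrr::map_int(rec, "begin"), purrr::map_int(rec, "end"))
    out <- tibble(chrom = chrom, start = conv$start, end = conv$end,
                  strand = check_strand(purrr::map_chr(rec, "strand"), path),
                  element_name = purrr::map_chr(rec, "element_name"),
                  family = purrr::map_chr(rec, "family"))
  } else {
    nf <- lengths(fields)
    if (any(nf < 6)) {
      abort(sprintf("malformed BED line %d: expected >= 6 fields",
                    lineno[[which(nf < 6)[1]]]))
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:6))
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    if (anyNA(start) || anyNA(end)) {
      abort(sprintf("malformed BED line %d: non-numeric coordinates",
                    lineno[[which(is.na(start) | is.na(end))[1]]]))
    }
    out <- tibble(chrom = m[, 1], start = start, end = end,
                  strand = check_strand(m[, 6], path),
                  element_name = paste0(m[, 4], "#", seq_len(nrow(m))),
                  family = m[, 4])
  }
  if (any(out$start < 0 | out$start >= out$end)) {
    abort("repeat interval with start < 0 or start >= end")
  }
  if (any(!nzchar(out$family))) abort("empty repeat family name")
  out$group <- map_family_group(out$family, family_group_map)
  out
}

map_family_group <- function(family, family_group_map) {
  if (is.null(family_group_map)) return(rep("other", length(family)))
  g <- unname(family_group_map[family])
  g[is.na(g)] <- "other"
  bad <- !g %in% c("LINE", "LTR", "SINE", "other")
  if (any(bad)) abort(sprintf("unknown ERE group: %s", paste(unique(g[bad]), collapse = ", ")))
  g
}

#' Write repeat records as BED
#' @param repeats Tibble as returned by [read_repeatmasker()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(repeats, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", repeats$chrom, repeats$start,
                     repeats$end, repeats$family, repeats$strand), path)
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

#' Read gene models from GTF
#'
#' Keeps `exon` and `CDS` features, groups transcripts under genes, and
#' converts 1-based closed GTF coordinates to the internal 0-based half-open
#' convention. Transcripts whose exons overlap each other after sorting are
#' retained but flagged in the `overlapping_exons` column.
#'
#' @param path Path to a GTF file with `gene_id`/`transcript_id` attributes.
#' @return A tibble with columns `gene_id`, `transcript_id`, `feature`
#'   (`"exon"` or `"CDS"`), `chrom`, `start`, `end`, `strand`,
#'   `overlapping_exons`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- tibble(gene_id = character(), transcript_id = character(),
                  feature = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  overlapping_exons = logical())
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) {
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields",
                  which(lengths(f) < 9)[1]))
  }
  m <- do.call(rbind, f)
  feature <- m[, 3]
  keep <- feature %in% c("exon", "CDS")
  if (!any(keep)) return(empty)
  m <- m[keep, , drop = FALSE]
  attr_field <- m[, 9]
  get_attr <- function(key) {
    hit <- regmatches(attr_field, regexpr(sprintf('%s "[^"]*"', key), attr_field))
    out <- rep(NA_character_, length(attr_field))
    has <- grepl(sprintf('%s "', key), attr_field, fixed = TRUE)
    out[has] <- sub(sprintf('%s "([^"]*)"', key), "\\1", hit)
    out
  }
  gene_id <- get_attr("gene_id")
  transcript_id <- get_attr("transcript_id")
  if (anyNA(gene_id)) abort("GTF feature without gene_id attribute")
  cds_orphan <- m[, 3] == "CDS" & is.na(transcript_id)
  if (any(cds_orphan)) abort("CDS feature without parent transcript_id")
  conv <- closed_to_internal(as.integer(m[, 4]), as.integer(m[, 5]))
  out <- tibble(
    gene_id = gene_id, transcript_id = transcript_id, feature = m[, 3],
    chrom = m[, 1], start = conv$start, end = conv$end,
    strand = check_strand(m[, 7], path)
  )
  # flag transcripts whose exons overlap after sorting (interval sweep)
  flag <- out |>
    filter(.data$feature == "exon") |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(overlapping_exons = n() > 1 && any(head(.data$end, -1) > tail(.data$start, -1)),
              .groups = "drop")
  out |>
    left_join(flag, by = "transcript_id") |>
    mutate(overlapping_exons = dplyr::coalesce(.data$overlapping_exons, FALSE))
}

#' Write gene models as GTF
#' @param genes Tibble as returned by [read_gtf()] (columns `gene_id`,
#'   `transcript_id`, `feature`, `chrom`, `start`, `end`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  cc <- internal_to_closed(genes$start, genes$end)
  writeLines(sprintf(
    '%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    genes$chrom, genes$feature, cc$begin, cc$end, genes$strand,
    genes$gene_id, genes$transcript_id), path)
  invisible(path)
}

# ---- FASTA / FASTQ ---------------------------------------------------------

#' Read a FASTA file into a tibble
#' @param path Path to an (uncompressed) FASTA file.
#' @return Tibble with columns `name`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(name = names(x), sequence = unname(as.character(x)))
}

#' Write a tibble of sequences as FASTA
#' @param seqs Tibble with columns `name`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#' @param path Path to an (uncompressed) FASTQ file.
#' @return Tibble with columns `name`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(name = names(x), sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write reads as FASTQ
#' @param reads Tibble with columns `name`, `sequence` and optionally `quality`
#'   (defaults to "I" across the read).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$name, "\n", reads$sequence, "\n+\n", qual), path)
  invisible(path)
}

# ---- SAM -------------------------------------------------------------------

SAM_FLAG_BITS <- c(
  is_paired = 1L, is_proper_pair = 2L, is_unmapped = 4L, mate_unmapped = 8L,
  is_reverse = 16L, mate_reverse = 32L, is_first = 64L, is_second = 128L,
  is_secondary = 256L, qc_fail = 512L, is_duplicate = 1024L,
  is_supplementary = 2048L
)

#' Decode SAM FLAG integers into booleans
#'
#' @param flag Integer vector of SAM FLAG values (0-4095).
#' @return Tibble with one logical column per flag bit (`is_paired`,
#'   `is_proper_pair`, `is_unmapped`, `mate_unmapped`, `is_reverse`,
#'   `mate_reverse`, `is_first`, `is_second`, `is_secondary`, `qc_fail`,
#'   `is_duplicate`, `is_supplementary`).
#' @export
decode_sam_flags <- function(flag) {
  flag <- as.integer(flag)
  out <- lapply(SAM_FLAG_BITS, function(bit) bitwAnd(flag, bit) != 0L)
  as_tibble(out)
}

# reference span consumed by a CIGAR string (M, D, N, =, X advance the ref)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a minimal text SAM file
#'
#' Minimal support: QNAME, FLAG, RNAME, POS, CIGAR, SEQ, with the FLAG field
#' decoded into booleans and the CIGAR used only to compute the reference
#' span. Positions are converted to the internal 0-based half-open
#' convention (`start`, `end`); unmapped records get `NA` coordinates.
#'
#' @param path Path to an (uncompressed) SAM file.
#' @return Tibble with columns `read_id`, `flag`, `chrom`, `start`, `end`,
#'   `cigar`, `sequence`, plus the decoded flag columns of
#'   [decode_sam_flags()].
#' @export
read_sam_min <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines)) {
    return(dplyr::bind_cols(
      tibble(read_id = character(), flag = integer(), chrom = character(),
             start = integer(), end = integer(), cigar = character(),
             sequence = character()),
      decode_sam_flags(integer())))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 11
  if (any(short)) abort(sprintf("malformed SAM line %d: fewer than 11 fields", which(short)[1]))
  m <- do.call(rbind, lapply(f, `[`, c(1, 2, 3, 4, 6, 10)))
  flag <- as.integer(m[, 2])
  dec <- decode_sam_flags(flag)
  start <- as.integer(m[, 4]) - 1L
  span <- cigar_ref_span(m[, 5])
  start[dec$is_unmapped] <- NA_integer_
  chrom <- m[, 3]
  chrom[dec$is_unmapped | chrom == "*"] <- NA_character_
  dplyr::bind_cols(
    tibble(read_id = m[, 1], flag = flag, chrom = chrom, start = start,
           end = start + span, cigar = m[, 5], sequence = check_nt(m[, 6])),
    dec)
}

#' Write a minimal SAM file
#' @param reads Tibble with columns `read_id`, `flag`, `chrom`, `start`
#'   (0-based), `cigar`, `sequence`; unmapped rows may carry `NA` chrom/start.
#' @param path Output path.
#' @param seqlengths Named integer vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam_min <- function(reads, path, seqlengths = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(seqlengths)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  reads$read_id, reads$flag,
                  ifelse(is.na(reads$chrom), "*", reads$chrom),
                  ifelse(is.na(reads$start), 0L, reads$start + 1L),
                  reads$cigar %||% paste0(nchar(reads$sequence), "M"),
                  reads$sequence, strrep("I", nchar(reads$sequence)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- PSM tables ------------------------------------------------------------

#' Read a peptide-spectrum-match table
#'
#' Expects a TSV with columns `peptide`, `sample`, `score`, `is_decoy` and
#' one `rank_<allele>` column per HLA allele (percentile ranks). Peptides are
#' uppercased and validated; duplicate `(peptide, sample)` rows keep the
#' max-score instance; `best_rank` is the minimum rank over available alleles
#' (missing ranks ignored).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `peptide`, `sample`, `score`, `is_decoy`,
#'   the `rank_*` columns, and `best_rank`.
#' @export
read_psm_table <- function(path) {
  tbl <- as_tibble(data.table::fread(path, sep = "\t", header = TRUE))
  req <- c("peptide", "sample", "score", "is_decoy")
  if (!all(req %in% names(tbl))) {
    abort(sprintf("PSM table missing columns: %s",
                  paste(setdiff(req, names(tbl)), collapse = ", ")))
  }
  tbl$peptide <- check_peptides(tbl$peptide)
  tbl$is_decoy <- as.logical(tbl$is_decoy)
  rank_cols <- grep("^rank_", names(tbl), value = TRUE)
  if (!length(rank_cols)) abort("PSM table has no rank_<allele> column")
  tbl$best_rank <- do.call(pmin, c(unname(tbl[rank_cols]), list(na.rm = TRUE)))
  tbl |>
    group_by(.data$peptide, .data$sample) |>
    slice_max(.data$score, n = 1, with_ties = FALSE) |>
    ungroup()
}

#' Write a PSM table
#' @param psms Tibble in the layout read by [read_psm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  psms <- psms[setdiff(names(psms), "best_rank")]
  data.table::fwrite(psms, path, sep = "\t")
  invisible(path)
}

# ---- expression matrices ---------------------------------------------------

#' Read / write expression tables (features x samples TSV)
#'
#' An expression table is a tibble whose first column `feature_id` names
#' features and whose remaining numeric columns are samples; the expression
#' unit (`"TPM"`, `"rphm"`, `"raw"`, `"zscore"`) travels in the `unit`
#' attribute. Writing then reading reproduces values exactly.
#'
#' @param path Path to the TSV file.
#' @param unit Unit tag for the values.
#' @return `read_tsv_matrix()`: the expression tibble. `write_tsv_matrix()`:
#'   `path`, invisibly.
#' @export
read_tsv_matrix <- function(path, unit = "TPM") {
  tbl <- as_tibble(data.table::fread(path, sep = "\t", header = TRUE))
  names(tbl)[1] <- "feature_id"
  validate_expression_table(tbl, unit)
}

#' @rdname read_tsv_matrix
#' @param table Expression tibble (first column `feature_id`).
#' @export
write_tsv_matrix <- function(table, path, unit = expr_unit(table)) {
  # full-precision doubles so the round trip is exact
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

expr_unit <- function(table) attr(table, "unit") %||% "raw"

validate_expression_table <- function(tbl, unit) {
  if (anyDuplicated(tbl$feature_id)) abort("duplicate feature ids in expression table")
  if (anyDuplicated(names(tbl))) abort("duplicate sample ids in expression table")
  vals <- as.matrix(tbl[-1])
  if (unit != "zscore" && any(vals < 0, na.rm = TRUE)) {
    abort(sprintf("negative values in a %s expression table", unit))
  }
  attr(tbl, "unit") <- unit
  tbl
}

# features x samples numeric matrix from an expression tibble
expr_matrix <- function(table) {
  m <- as.matrix(table[-1])
  rownames(m) <- table$feature_id
  storage.mode(m) <- "double"
  m
}

matrix_to_expr <- function(m, unit = "raw") {
  tbl <- dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
  validate_expression_table(tbl, unit)
}

# ---- methylation and variants ---------------------------------------------

#' Read a methylation probe table
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (0-based) and one beta column
#' per sample.
#'
#' @param path Path to the TSV file.
#' @return Tibble in the same layout.
#' @export
read_methylation <- function(path) {
  tbl <- as_tibble(data.table::fread(path, sep = "\t", header = TRUE))
  req <- c("probe_id", "chrom", "pos")
  if (!all(req %in% names(tbl))) abort("methylation table needs probe_id, chrom, pos")
  tbl
}

#' Read a transcript variant table
#'
#' Variants arrive as a simple TSV: `transcript_id`, `pos` (1-based position
#' in the transcript), `ref`, `alt`, `alt_count`.
#'
#' @param path Path to the TSV file.
#' @return Tibble in the same layout.
#' @export
read_variants <- function(path) {
  tbl <- as_tibble(data.table::fread(path, sep = "\t", header = TRUE))
  req <- c("transcript_id", "pos", "ref", "alt", "alt_count")
  if (!all(req %in% names(tbl))) {
    abort("variant table needs transcript_id, pos, ref, alt, alt_count")
  }
  tbl
}
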