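# Atlas-level expression computations: aggregation of transcript TPM to
# families/genes, per-tissue median profiles, row Z-scores, quintile ranking
# and inter-individual dispersion.

#' Aggregate transcript expression into families or genes
#'
#' Sums per-sample values of member transcripts into their group (ERE family
#' or gene), mirroring family-level TPM aggregation over repeat and gene
#' annotations. Transcripts absent from `member_map` are collected and
#' reported via the `unmapped` attribute (and a warning), not silently
#' dropped into groups.
#'
#' @param table Expression tibble (first column `feature_id`, sample columns).
#' @param member_map Named character vector, transcript id -> group id.
#' @return Expression tibble with one row per group, same unit; attribute
#'   `unmapped` lists transcript ids that had no mapping.
#' @export
aggregate_expression <- function(table, member_map) {
  unit <- expr_unit(table)
  if (anyDuplicated(names(member_map))) abort("member_map maps a transcript twice")
  grp <- unname(member_map[table$feature_id])
  unmapped <- table$feature_id[is.na(grp)]
  if (length(unmapped)) {
    warn(sprintf("%d transcript ids missing from member_map (dropped)", length(unmapped)))
  }
  m <- expr_matrix(table)[!is.na(grp), , drop = FALSE]
  agg <- rowsum(m, group = grp[!is.na(grp)])
  out <- matrix_to_expr(agg, unit = unit)
  attr(out, "unmapped") <- unmapped
  out
}

#' Per-tissue median expression profile
#'
#' Collapses a samples-level expression table to a features x tissues profile
#' by taking, per feature, the median across the samples of each tissue
#' (even counts: mean of the two central values).
#'
#' @param table Expression tibble.
#' @param sample_to_tissue Named character vector, sample id -> tissue.
#' @return Expression tibble with tissue columns (unit preserved); the
#'   mapping is retained in the `sample_to_tissue` attribute.
#' @export
median_profile <- function(table, sample_to_tissue) {
  samples <- names(table)[-1]
  missing <- setdiff(samples, names(sample_to_tissue))
  if (length(missing)) {
    abort(sprintf("samples without tissue assignment: %s", paste(head(missing, 3), collapse = ", ")))
  }
  tis <- unname(sample_to_tissue[samples])
  m <- expr_matrix(table)
  tissues <- unique(tis)
  prof <- vapply(tissues, function(tt) {
    cols <- which(tis == tt)
    if (!length(cols)) abort(sprintf("tissue %s has zero samples", tt))
    apply(m[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(m)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = nrow(m), dimnames = list(rownames(m), tissues))
  out <- matrix_to_expr(prof, unit = expr_unit(table))
  attr(out, "sample_to_tissue") <- sample_to_tissue
  out
}

#' Row Z-scores of a tissue profile
#'
#' Centers and scales each feature row to mean 0, SD 1 (denominator n - 1),
#' the "numbers of standard deviations from the mean" transform. Constant
#' rows become all-zero and are flagged.
#'
#' @param profile Expression tibble (features x tissues).
#' @return Expression tibble with unit `"zscore"`; attributes `row_means`,
#'   `row_sds` (for exact un-scaling) and `constant_rows`.
#' @export
row_zscore <- function(profile) {
  m <- expr_matrix(profile)
  if (ncol(m) < 2) abort("row_zscore: need >= 2 tissues")
  mu <- rowMeans(m)
  sds <- apply(m, 1, sd)
  constant <- sds == 0
  z <- (m - mu) / ifelse(constant, 1, sds)
  z[constant, ] <- 0
  out <- matrix_to_expr(z, unit = "zscore")
  attr(out, "row_means") <- mu
  attr(out, "row_sds") <- sds
  attr(out, "constant_rows") <- rownames(m)[constant]
  out
}

#' Quintile ranking of tissues by family expression
#'
#' Per feature, ranks tissues by median expression (ascending) and cuts them
#' into five quintile bins; for 32 tissues the bin sizes are exactly
#' 6, 6, 8, 6, 6 (lowest to highest). For other tissue counts each bin gets
#' `floor(N/5)` tissues and the remainder goes to the middle bin, which
#' reproduces the 32-tissue scheme as a special case. Ties are broken by
#' stable tissue-id order and flagged.
#'
#' @param profile Expression tibble (features x tissues), N >= 5 tissues.
#' @return A list with `tally`: tibble of per-tissue counts of fifth-quintile
#'   (highest) membership, sorted decreasing; `assignments`: feature x tissue
#'   tibble of quintile numbers (1 = lowest); `bin_sizes`; `ties`: features
#'   where a tie crossed a bin boundary.
#' @export
quintile_rank <- function(profile) {
  m <- expr_matrix(profile)
  N <- ncol(m)
  if (N < 5) abort("quintile_rank: need >= 5 tissues")
  sizes <- quintile_sizes(N)
  qu <- rep(seq_len(5), times = sizes)
  tissues <- colnames(m)
  assign <- matrix(NA_integer_, nrow(m), N, dimnames = dimnames(m))
  tied <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ord <- order(m[i, ], tissues)   # ascending; ties by tissue id
    assign[i, ord] <- qu
    # a tie crossing a bin boundary makes the cut order-dependent: flag it
    v <- m[i, ord]
    boundary <- cumsum(sizes)[-5]
    tied[i] <- any(v[boundary] == v[boundary + 1])
  }
  top_counts <- colSums(assign == 5L)
  tally <- tibble(tissue = tissues, n_top_quintile = as.integer(top_counts)) |>
    arrange(dplyr::desc(.data$n_top_quintile), .data$tissue)
  list(tally = tally,
       assignments = dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(assign)),
       bin_sizes = sizes,
       ties = rownames(m)[tied])
}

quintile_sizes <- function(N) {
  base <- N %/% 5L
  sizes <- rep(base, 5)
  sizes[3] <- sizes[3] + N %% 5L
  sizes
}

#' Inter-individual dispersion of family expression within tissues
#'
#' Sample standard deviation (denominator n - 1) of each feature across the
#' samples of each tissue; tissues with a single sample yield `NA`.
#'
#' @param table Expression tibble (samples level).
#' @param sample_to_tissue Named character vector, sample id -> tissue.
#' @return Tibble features x tissues of SDs.
#' @export
interindividual_sd <- function(table, sample_to_tissue) {
  samples <- names(table)[-1]
  tis <- unname(sample_to_tissue[samples])
  m <- expr_matrix(table)
  tissues <- unique(tis)
  out <- vapply(tissues, function(tt) {
    cols <- which(tis == tt)
    if (length(cols) < 2) return(rep(NA_real_, nrow(m)))
    apply(m[, cols, drop = FALSE], 1, sd)
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), tissues))
  dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(out))
}
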