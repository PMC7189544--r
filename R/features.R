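# Downstream peptide analytics: rphm expression profiling of ereMAP coding
# sequences across tissues, methylation correlation, amino-acid composition,
# and viral-homology testing by exact Smith-Waterman with a bootstrap null.

# ---- rphm ------------------------------------------------------------------

#' rphm expression profile of a peptide's coding sequence
#'
#' For each sample, `r_overlap` is the minimal occurrence of the coding
#' sequence's 24-mer set in the sample's k-mer table (0 as soon as any
#' window is absent), and `rphm = r_overlap / total_reads * 1e8` (reads per
#' hundred million sequenced). The tissue value is the mean of
#' `log10(rphm + 1)` over the tissue's samples, and a tissue is flagged
#' significant when its average expression exceeds 10 rphm, i.e. when the
#' mean log value exceeds `log10(10 + 1)` (a linear-scale alternative is
#' available via `scale = "linear"`).
#'
#' @param mcs The peptide's coding sequence(s); with several, the per-sample
#'   maximum `r_overlap` is used.
#' @param kmer_tables Named list of per-sample `kmer_table`s.
#' @param total_reads Named numeric vector of per-sample total read counts.
#' @param sample_to_tissue Named character vector, sample -> tissue.
#' @param rphm_threshold Significance threshold in rphm (default 10).
#' @param scale `"log"` (default; compares mean log10(rphm + 1)) or
#'   `"linear"` (compares mean rphm).
#' @return List of class `rphm_profile` with `samples` (tibble: sample,
#'   tissue, r_overlap, rphm), `tissues` (tibble: tissue, mean_log_rphm,
#'   significant).
#' @export
rphm_profile <- function(mcs, kmer_tables, total_reads, sample_to_tissue,
                         rphm_threshold = 10, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!length(kmer_tables)) abort("rphm_profile: empty k-mer table set")
  samples <- names(kmer_tables)
  if (any(total_reads[samples] <= 0)) abort("rphm_profile: non-positive total read count")
  r_overlap <- vapply(samples, function(s) {
    max(kmer_min_count(kmer_tables[[s]], mcs))
  }, integer(1))
  rphm <- r_overlap * 1e8 / total_reads[samples]
  st <- tibble(sample = samples, tissue = unname(sample_to_tissue[samples]),
               r_overlap = unname(r_overlap), rphm = unname(rphm))
  tis <- st |>
    group_by(.data$tissue) |>
    summarise(mean_log_rphm = mean(log10(.data$rphm + 1)),
              mean_rphm = mean(.data$rphm), .groups = "drop") |>
    mutate(significant = if (scale == "log") {
      .data$mean_log_rphm > log10(rphm_threshold + 1)
    } else {
      .data$mean_rphm > rphm_threshold
    })
  structure(list(samples = st, tissues = tis, threshold = rphm_threshold,
                 scale = scale),
            class = "rphm_profile")
}

#' @export
print.rphm_profile <- function(x, ...) {
  cat(sprintf("rphm profile over %d samples, %d tissues (%d significant at > %g rphm)\n",
              nrow(x$samples), nrow(x$tissues), sum(x$tissues$significant), x$threshold))
  invisible(x)
}

#' @export
tidy.rphm_profile <- function(x, ...) x$tissues

#' Correlate a peptide's rphm expression with nearby methylation
#'
#' Restricts probes to a window of `window` nucleotides from either end of
#' the coding locus and computes a Pearson correlation per probe between the
#' per-sample rphm values and the probe's betas.
#'
#' @param rphm Named numeric vector of per-sample rphm.
#' @param probes Methylation tibble ([read_methylation()]): `probe_id`,
#'   `chrom`, `pos` plus one beta column per sample.
#' @param locus List or one-row tibble with `chrom`, `start`, `end` (0-based
#'   half-open) of the coding locus.
#' @param window Window size in nucleotides (default 5000).
#' @return Tibble with columns `probe_id`, `distance`, `r`, `n`; empty (not
#'   an error) when no probe falls in the window.
#' @export
methylation_correlation <- function(rphm, probes, locus, window = 5000) {
  samples <- intersect(names(rphm), names(probes))
  if (length(samples) < 3) abort("methylation_correlation: need >= 3 samples with both measurements")
  dist <- ifelse(probes$chrom != locus$chrom, Inf,
                 pmax(0, pmax(locus$start - probes$pos, probes$pos - (locus$end - 1))))
  inwin <- which(dist <= window)
  rows <- purrr::map(inwin, function(i) {
    betas <- as.numeric(probes[i, samples])
    r <- tryCatch(pearson(rphm[samples], betas), error = function(e) NA_real_)
    tibble(probe_id = probes$probe_id[i], distance = dist[i], r = r,
           n = length(samples))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) out <- tibble(probe_id = character(), distance = numeric(),
                                r = numeric(), n = integer())
  out
}

# ---- amino-acid composition ------------------------------------------------

#' Overall amino-acid usage frequencies of a peptide set
#'
#' @param peptides Non-empty character vector of peptides.
#' @return Tibble with columns `aa`, `count`, `frequency` (frequencies sum
#'   to 1 over the 20 standard amino acids).
#' @export
aa_frequencies <- function(peptides) {
  if (!length(peptides)) abort("aa_frequencies: empty peptide set")
  peptides <- check_peptides(peptides)
  chars <- unlist(strsplit(peptides, ""))
  counts <- unname(vapply(AA20, function(a) sum(chars == a), numeric(1)))
  tibble(aa = AA20, count = as.integer(counts), frequency = counts / length(chars))
}

#' Positional amino-acid frequencies by peptide length
#'
#' Bins peptides by length and computes, for each retained length, the
#' amino-acid frequency at every position (each position sums to 1). Length
#' bins with fewer than `min_count` peptides are dropped and reported in the
#' `dropped_lengths` attribute.
#'
#' @param peptides Character vector of peptides.
#' @param lengths Lengths to consider (default 8:11).
#' @param min_count Minimum peptides per length bin (default 3).
#' @return Tibble with columns `length`, `position`, `aa`, `frequency`,
#'   `n_peptides`.
#' @export
positional_aa_frequencies <- function(peptides, lengths = 8:11, min_count = 3) {
  peptides <- check_peptides(peptides)
  rows <- list()
  dropped <- integer(0)
  for (L in lengths) {
    set <- peptides[nchar(peptides) == L]
    if (length(set) < min_count) {
      if (length(set)) dropped <- c(dropped, L)
      next
    }
    mat <- do.call(rbind, strsplit(set, ""))
    for (p in seq_len(L)) {
      counts <- unname(vapply(AA20, function(a) sum(mat[, p] == a), numeric(1)))
      rows[[length(rows) + 1]] <- tibble(length = L, position = p, aa = AA20,
                                         frequency = counts / length(set),
                                         n_peptides = length(set))
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) out <- tibble(length = integer(), position = integer(),
                                aa = character(), frequency = numeric(),
                                n_peptides = integer())
  attr(out, "dropped_lengths") <- dropped
  out
}

# ---- local alignment -------------------------------------------------------

#' Exact Smith-Waterman local alignment of two peptides
#'
#' Optimal local alignment under an affine gap model (a gap of length g
#' costs `gap_open + gap_extend * g`) with the PAM30 substitution matrix by
#' default. Exact dynamic programming replaces heuristic word-seeded search:
#' at 8-11-mer scale the DP is strictly more complete. An all-negative
#' scoring situation yields the empty alignment with score 0.
#'
#' @param query,subject Peptide strings (length >= 1).
#' @param matrix Substitution matrix (default [pam30_matrix()]).
#' @param gap_open,gap_extend Affine gap parameters (defaults 5 and 2).
#' @return List with `score`, `alignment_length` (columns, gaps included),
#'   `matches` (identical aligned positions), `query_aligned`,
#'   `subject_aligned`.
#' @export
local_align <- function(query, subject, matrix = pam30_matrix(),
                        gap_open = 5, gap_extend = 2) {
  q <- strsplit(check_peptides(query), "")[[1]]
  s <- strsplit(check_peptides(subject), "")[[1]]
  m <- length(q); n <- length(s)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)     # best score ending in a match/mismatch
  X <- matrix(NEG, m + 1, n + 1)   # ending in a gap in subject (query consumed)
  Y <- matrix(NEG, m + 1, n + 1)   # ending in a gap in query (subject consumed)
  best <- 0; bi <- 0; bj <- 0; bmat <- "M"
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- matrix[q[i], s[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j; bmat <- "M"
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, alignment_length = 0L, matches = 0L,
                query_aligned = "", subject_aligned = ""))
  }
  # traceback
  qa <- character(0); sa <- character(0)
  i <- bi; j <- bj; state <- bmat
  repeat {
    if (state == "M") {
      qa <- c(q[i], qa); sa <- c(s[j], sa)
      prev <- c(0, M[i, j], X[i, j], Y[i, j])
      pick <- which.max(prev)
      cur <- M[i + 1, j + 1] - matrix[q[i], s[j]]
      i <- i - 1; j <- j - 1
      if (pick == 1 || cur <= 0) break
      state <- c("", "M", "X", "Y")[pick]
    } else if (state == "X") {
      qa <- c(q[i], qa); sa <- c("-", sa)
      from_m <- M[i, j + 1] - gap_open - gap_extend
      state <- if (X[i + 1, j + 1] == from_m) "M" else "X"
      i <- i - 1
    } else {
      qa <- c("-", qa); sa <- c(s[j], sa)
      from_m <- M[i + 1, j] - gap_open - gap_extend
      state <- if (Y[i + 1, j + 1] == from_m) "M" else "Y"
      j <- j - 1
    }
  }
  list(score = best,
       alignment_length = length(qa),
       matches = sum(qa == sa & qa != "-"),
       query_aligned = paste(qa, collapse = ""),
       subject_aligned = paste(sa, collapse = ""))
}

#' Percent identity of a peptide against a viral peptide database
#'
#' For each database subject the best local alignment is computed and scored
#' as identity normalised by peptide length:
#' `(matches / L_a) * (L_a / L_p) * 100 = matches / L_p * 100`, where `L_a`
#' is the alignment length and `L_p` the query peptide length. The reported
#' value is the maximum over subjects, so an exact full-length database
#' member scores 100. `mmax_as_percentage = TRUE` reproduces the literal
#' published formula in which the identity term is already a percentage
#' (values then scale up by 100).
#'
#' @param query Peptide string.
#' @param viral_db Non-empty character vector of database peptides.
#' @param by `"identity"` (default: subject maximising matches / L_p) or
#'   `"score"` (subject maximising alignment score).
#' @param mmax_as_percentage Use the literal formula scaling (default FALSE).
#' @inheritParams local_align
#' @return The percent identity (0 when no positive-scoring alignment
#'   exists).
#' @export
percent_identity <- function(query, viral_db, matrix = pam30_matrix(),
                             gap_open = 5, gap_extend = 2,
                             by = c("identity", "score"),
                             mmax_as_percentage = FALSE) {
  by <- match.arg(by)
  if (!length(viral_db)) abort("percent_identity: empty viral database")
  lp <- nchar(query)
  vals <- numeric(length(viral_db))
  scores <- numeric(length(viral_db))
  for (i in seq_along(viral_db)) {
    al <- local_align(query, viral_db[[i]], matrix, gap_open, gap_extend)
    vals[i] <- if (al$alignment_length == 0) 0 else al$matches / lp * 100
    scores[i] <- al$score
  }
  out <- if (by == "identity") max(vals) else vals[which.max(scores)]
  if (mmax_as_percentage) out * 100 else out
}

#' Viral-homology bootstrap test
#'
#' Compares the mean percent identity of a query MAP set (the ereMAPs)
#' against a bootstrap distribution built from `n_boot` equally sized groups
#' sampled from a canonical MAP pool (without replacement within each
#' group). The p-value is the fraction of bootstrap groups whose mean
#' percent identity exceeds the observed mean.
#'
#' @param eremaps Character vector of query peptides.
#' @param canonical_maps Character vector of pool peptides
#'   (`length >= length(eremaps)`).
#' @param viral_db Character vector of viral database peptides.
#' @param n_boot Number of bootstrap groups (default 10000).
#' @param seed Integer seed.
#' @param replace Sample within groups with replacement (default FALSE).
#' @inheritParams percent_identity
#' @return Object of class `viral_homology`: list with `observed_mean`,
#'   `boot_means`, `p`, `per_peptide` (query %I values), `n_boot`.
#' @export
viral_homology_test <- function(eremaps, canonical_maps, viral_db,
                                n_boot = 10000, seed = 1L, replace = FALSE,
                                matrix = pam30_matrix(), gap_open = 5,
                                gap_extend = 2, by = c("identity", "score"),
                                mmax_as_percentage = FALSE) {
  by <- match.arg(by)
  if (n_boot < 1) abort("viral_homology_test: n_boot must be >= 1")
  if (length(canonical_maps) < length(eremaps)) {
    abort("viral_homology_test: canonical pool smaller than the query set")
  }
  pid <- function(p) percent_identity(p, viral_db, matrix, gap_open, gap_extend,
                                      by = by, mmax_as_percentage = mmax_as_percentage)
  obs <- vapply(eremaps, pid, numeric(1))
  pool <- vapply(canonical_maps, pid, numeric(1))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  k <- length(eremaps)
  boot_means <- vapply(seq_len(n_boot), function(b) {
    mean(pool[sample.int(length(pool), k, replace = replace)])
  }, numeric(1))
  observed_mean <- mean(obs)
  structure(list(observed_mean = observed_mean, boot_means = boot_means,
                 p = sum(boot_means > observed_mean) / n_boot,
                 per_peptide = obs, pool = pool, n_boot = n_boot),
            class = "viral_homology")
}

#' @export
print.viral_homology <- function(x, ...) {
  p_lab <- if (x$p == 0) sprintf("< %g", 1 / x$n_boot) else sprintf("= %g", x$p)
  cat(sprintf("Viral homology: observed mean %%I = %.2f over %d peptides; bootstrap p %s (%d iterations)\n",
              x$observed_mean, length(x$per_peptide), p_lab, x$n_boot))
  invisible(x)
}

#' @export
glance.viral_homology <- function(x, ...) {
  tibble(observed_mean = x$observed_mean, p = x$p, n_boot = x$n_boot,
         n_query = length(x$per_peptide),
         boot_mean = mean(x$boot_means), boot_sd = sd(x$boot_means))
}

#' @export
tidy.viral_homology <- function(x, ...) {
  tibble(peptide = names(x$per_peptide), percent_identity = unname(x$per_peptide))
}
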