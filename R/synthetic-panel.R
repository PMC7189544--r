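# Synthetic multi-tissue expression panel, methylation probes, and PSM score
# generators with planted ground truth.

#' Generate a multi-tissue family expression panel with planted truth
#'
#' Emulates a tissue atlas: `n_families - n_restricted` housekeeping
#' families express a family-specific baseline in every tissue, and
#' `n_restricted` families are overexpressed `ratio`-fold in
#' `n_over_tissues` tissue(s) relative to their residual level elsewhere.
#' Per-sample values carry lognormal noise (`sdlog`), and each sample column
#' is renormalised to sum to 1e6 (a TPM-like unit). The default panel is 32
#' tissues, the atlas size of a 30-tissue + 2-cell-type survey; the default
#' `sdlog = 0.2` (~20% coefficient of variation between individuals) keeps
#' housekeeping profiles in the tau <= 0.4 regime that defines
#' housekeeping-like expression, while `ratio = 20` puts restricted families
#' well above the tau >= 0.8 call threshold.
#'
#' @param n_tissues Number of tissues (default 32).
#' @param n_families Number of repeat families (default 200).
#' @param n_restricted Number of tissue-restricted families (default 20).
#' @param samples_per_tissue Samples per tissue (default 5, >= 1).
#' @param ratio Overexpression ratio of restricted families (default 20).
#' @param sdlog Lognormal noise sd on the log scale (default 0.2).
#' @param n_over_tissues Tissues a restricted family is overexpressed in
#'   (default 1).
#' @param seed Integer seed.
#' @return List of class `tissue_panel`: `expression` (feature x sample
#'   tibble, unit TPM), `truth` (tibble: family, type, tissues list-column,
#'   over_mean, off_mean), `sample_to_tissue`, `params`.
#' @export
make_tissue_panel <- function(n_tissues = 32, n_families = 200,
                              n_restricted = 20, samples_per_tissue = 5,
                              ratio = 20, sdlog = 0.2, n_over_tissues = 1,
                              seed = 1L) {
  if (samples_per_tissue < 1) abort("make_tissue_panel: samples_per_tissue must be >= 1")
  if (n_restricted > n_families) abort("make_tissue_panel: n_restricted > n_families")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  fams <- sprintf("FAM%04d", seq_len(n_families))
  restricted <- if (n_restricted) sample(fams, n_restricted) else character(0)
  samples <- as.vector(vapply(tissues, function(t)
    sprintf("%s_s%d", t, seq_len(samples_per_tissue)), character(samples_per_tissue)))
  sample_to_tissue <- setNames(rep(tissues, each = samples_per_tissue), samples)

  mean_mat <- matrix(0, n_families, n_tissues, dimnames = list(fams, tissues))
  over_tis <- vector("list", n_families); names(over_tis) <- fams
  base <- rlnorm(n_families, meanlog = log(50), sdlog = 0.8)
  off <- rlnorm(n_families, meanlog = log(5), sdlog = 0.5)
  for (i in seq_len(n_families)) {
    if (fams[i] %in% restricted) {
      tset <- sample(tissues, n_over_tissues)
      over_tis[[i]] <- tset
      mean_mat[i, ] <- off[i]
      mean_mat[i, tset] <- off[i] * ratio
    } else {
      over_tis[[i]] <- character(0)
      mean_mat[i, ] <- base[i]
    }
  }
  m <- matrix(0, n_families, length(samples), dimnames = list(fams, samples))
  for (j in seq_along(samples)) {
    mu <- mean_mat[, sample_to_tissue[samples[j]]]
    m[, j] <- mu * rlnorm(n_families, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  m <- sweep(m, 2, colSums(m), "/") * 1e6
  truth <- tibble(
    family = fams,
    type = ifelse(fams %in% restricted, "restricted", "housekeeping"),
    tissues = unname(over_tis),
    over_mean = ifelse(fams %in% restricted, off * ratio, NA_real_),
    off_mean = ifelse(fams %in% restricted, off, base))
  structure(list(expression = matrix_to_expr(m, unit = "TPM"),
                 truth = truth, sample_to_tissue = sample_to_tissue,
                 params = list(n_tissues = n_tissues, n_families = n_families,
                               n_restricted = n_restricted,
                               samples_per_tissue = samples_per_tissue,
                               ratio = ratio, sdlog = sdlog,
                               n_over_tissues = n_over_tissues, seed = seed)),
            class = "tissue_panel")
}

#' @export
print.tissue_panel <- function(x, ...) {
  p <- x$params
  cat(sprintf("Tissue panel: %d families (%d restricted) x %d tissues x %d samples\n",
              p$n_families, p$n_restricted, p$n_tissues, p$samples_per_tissue))
  invisible(x)
}

#' Generate methylation probes correlated with peptide expression
#'
#' Draws per-sample beta values with a target Pearson correlation `rho` to
#' the supplied rphm vector (exact at `|rho| = 1`), for probes placed inside
#' and outside the downstream 5000-nt analysis window of the locus.
#'
#' @param locus List or one-row tibble with `chrom`, `start`, `end`.
#' @param rphm Named numeric vector of per-sample rphm (>= 3 samples).
#' @param rho Target correlation in `[-1, 1]`.
#' @param window Window size (default 5000).
#' @param n_in,n_out Probes inside / outside the window (defaults 3 and 2).
#' @param seed Integer seed.
#' @return Methylation tibble ([read_methylation()] layout).
#' @export
make_methylation <- function(locus, rphm, rho, window = 5000, n_in = 3,
                             n_out = 2, seed = 1L) {
  if (length(rphm) < 3) abort("make_methylation: need >= 3 samples")
  if (abs(rho) > 1) abort("make_methylation: rho must be in [-1, 1]")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- as.numeric(scale(rphm))
  pos_in <- locus$start - sample(seq_len(window - 1), n_in)
  pos_out <- locus$end - 1 + window + sample(1:2000, n_out)
  pos <- c(pos_in, pos_out)
  rows <- purrr::map(seq_along(pos), function(i) {
    mix <- rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(length(z))
    beta <- pmin(1, pmax(0, 0.5 + 0.12 * mix))
    out <- tibble(probe_id = sprintf("cg%06d", i), chrom = locus$chrom,
                  pos = as.integer(pos[i]))
    out[names(rphm)] <- as.list(beta)
    out
  })
  bind_rows(rows)
}

#' Simulate PSM scores with known correct/incorrect labels
#'
#' Target scores are a mixture of correct identifications
#' (`N(mu_correct, 1)`) and incorrect ones (`N(0, 1)`, fraction `pi0`).
#' Decoy scores are drawn from the incorrect-score distribution,
#' equinumerous with the incorrect targets: the target-decoy premise is
#' that random matches accumulate at the same rate in the target and decoy
#' databases, so the decoy count estimates the incorrect-target count.
#' Used to measure the realized false-discovery proportion of
#' [apply_fdr()].
#'
#' @param n_psms Number of target PSMs (default 10000).
#' @param pi0 Fraction of incorrect targets (default 0.3).
#' @param mu_correct Mean score of correct targets (default 3.5).
#' @param seed Integer seed.
#' @return Tibble with columns `peptide`, `sample`, `score`, `is_decoy`,
#'   `is_correct` (`NA` for decoys), `best_rank`.
#' @export
simulate_psm_scores <- function(n_psms = 10000, pi0 = 0.3, mu_correct = 3.5,
                                seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  correct <- runif(n_psms) > pi0
  n_decoy <- sum(!correct)
  tibble(
    peptide = sprintf("PEP%06d", seq_len(n_psms + n_decoy)),
    sample = "sim",
    score = c(ifelse(correct, rnorm(n_psms, mu_correct), rnorm(n_psms)),
              rnorm(n_decoy)),
    is_decoy = rep(c(FALSE, TRUE), c(n_psms, n_decoy)),
    is_correct = c(correct, rep(NA, n_decoy)),
    best_rank = 1)
}
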