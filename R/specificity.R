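# Tissue specificity: the tau index, max-gap binarization and
# tissue-restricted calling with ERE-group enrichment.

#' Tau index of tissue specificity
#'
#' For a per-tissue expression profile with values `v_i` over N tissues,
#' `x_i = v_i / max(v)` and `tau = sum(1 - x_i) / (N - 1)`. Tau is 0 for a
#' uniform profile and 1 when expression is confined to a single tissue;
#' housekeeping-like profiles sit at or below ~0.4 and tissue-restricted
#' profiles at or above 0.8.
#'
#' @param profile Numeric vector of per-tissue expression (N >= 2).
#' @return Tau in `[0, 1]`. An all-zero profile is an error (tau is
#'   undefined, not 0).
#' @export
tau_index <- function(profile) {
  N <- length(profile)
  if (N < 2) abort("tau_index: need >= 2 tissues")
  mx <- max(profile)
  if (mx <= 0) abort("tau_index: undefined for an all-zero profile")
  sum(1 - profile / mx) / (N - 1)
}

#' Max-gap binary expression pattern
#'
#' Sorts tissues by expression (descending), finds the maximal difference
#' ("gap") between neighbouring sorted values, and marks tissues strictly
#' above the gap as overexpressing (1), the rest 0. When two gaps are
#' equally maximal the one closer to the top of the ranking is used (the
#' conservative choice: fewer overexpressing tissues).
#'
#' @param profile Named numeric vector of per-tissue expression (>= 2
#'   tissues, not all equal).
#' @return List with `pattern` (named 0/1 integer vector in input order),
#'   `overexpressing` (tissue names), `gap` (the gap size) and `gap_after`
#'   (number of tissues above the gap).
#' @export
binary_pattern <- function(profile) {
  if (length(profile) < 2) abort("binary_pattern: need >= 2 tissues")
  if (diff(range(profile)) == 0) abort("binary_pattern: all values equal, no gap")
  nm <- names(profile) %||% as.character(seq_along(profile))
  ord <- order(profile, decreasing = TRUE)
  v <- profile[ord]
  gaps <- -diff(v)                       # >= 0, length N-1
  k <- which.max(gaps)                   # first (topmost) maximal gap
  pattern <- setNames(rep(0L, length(profile)), nm)
  pattern[ord[seq_len(k)]] <- 1L
  list(pattern = pattern,
       overexpressing = nm[ord[seq_len(k)]],
       gap = unname(gaps[k]),
       gap_after = k)
}

#' Call tissue-restricted features
#'
#' Computes tau for every feature of a tissue profile and returns those at or
#' above the threshold, each with its max-gap binary pattern and
#' overexpressing-tissue set. Features whose maximal expression falls below
#' `floor` are excluded: tau is scale-free and noise-dominated at trace
#' expression (set `floor = 0` to disable).
#'
#' @param profile Expression tibble (features x tissues, >= 2 tissues).
#' @param tau_threshold Restriction threshold (default 0.8).
#' @param floor Minimum maximal expression required to call (default 1).
#' @return Tibble of class `specificity_calls` with columns `feature_id`,
#'   `tau`, `n_overexpressing`, `overexpressing` (list column),
#'   `tissue_specific` (exactly one overexpressing tissue), `pattern`
#'   (list column). The `all_tau` attribute carries tau for every scoreable
#'   feature.
#' @export
call_restricted <- function(profile, tau_threshold = 0.8, floor = 1) {
  m <- expr_matrix(profile)
  if (ncol(m) < 2) abort("call_restricted: need >= 2 tissues")
  mx <- apply(m, 1, max)
  scoreable <- mx > 0
  taus <- rep(NA_real_, nrow(m))
  taus[scoreable] <- apply(m[scoreable, , drop = FALSE], 1, tau_index)
  all_tau <- tibble(feature_id = rownames(m), tau = taus, max_expr = mx)
  called <- which(scoreable & mx >= floor & taus >= tau_threshold &
                    apply(m, 1, function(v) diff(range(v)) > 0))
  res <- purrr::map(called, function(i) {
    bp <- binary_pattern(m[i, ])
    tibble(feature_id = rownames(m)[i], tau = taus[i],
           n_overexpressing = length(bp$overexpressing),
           overexpressing = list(bp$overexpressing),
           tissue_specific = length(bp$overexpressing) == 1L,
           pattern = list(bp$pattern))
  })
  out <- if (length(res)) bind_rows(res) else
    tibble(feature_id = character(), tau = numeric(),
           n_overexpressing = integer(), overexpressing = list(),
           tissue_specific = logical(), pattern = list())
  attr(out, "all_tau") <- all_tau
  attr(out, "tau_threshold") <- tau_threshold
  attr(out, "floor") <- floor
  class(out) <- c("specificity_calls", class(out))
  out
}

#' ERE-group enrichment among tissue-restricted families
#'
#' Compares the observed LINE/LTR/SINE composition of the restricted set
#' with its expected composition under the background family proportions,
#' via a goodness-of-fit chi-squared test. Families of group `"other"` are
#' excluded from both sides.
#'
#' @param restricted A `specificity_calls` tibble (or any tibble with a
#'   `feature_id` column of family names).
#' @param all_families Tibble with columns `family`, `group` covering the
#'   background (one row per family; duplicated families are collapsed).
#' @return List with `observed` (counts), `expected`, `proportions`
#'   (observed vs background), and `test` (the [chi_squared()] result).
#' @export
group_enrichment <- function(restricted, all_families) {
  fam <- dplyr::distinct(all_families[, c("family", "group")])
  fam <- fam[fam$group %in% c("LINE", "LTR", "SINE"), ]
  if (length(unique(fam$group)) < 2) abort("group_enrichment: degenerate single-group background")
  hit <- fam[fam$family %in% restricted$feature_id, ]
  if (!nrow(hit)) abort("group_enrichment: empty restricted set")
  groups <- sort(unique(fam$group))
  observed <- vapply(groups, function(g) sum(hit$group == g), numeric(1))
  bg_prop <- vapply(groups, function(g) mean(fam$group == g), numeric(1))
  test <- chi_squared(observed, bg_prop)
  list(observed = observed,
       expected = test$expected,
       proportions = tibble(group = groups,
                            restricted = observed / sum(observed),
                            background = bg_prop),
       test = test)
}

#' @export
tidy.specificity_calls <- function(x, ...) {
  tibble(feature_id = x$feature_id, tau = x$tau,
         n_overexpressing = x$n_overexpressing,
         tissue_specific = x$tissue_specific,
         overexpressing = purrr::map_chr(x$overexpressing, paste, collapse = ","))
}

#' @export
glance.specificity_calls <- function(x, ...) {
  all_tau <- attr(x, "all_tau")
  tibble(n_restricted = nrow(x),
         n_tissue_specific = sum(x$tissue_specific),
         n_scored = sum(!is.na(all_tau$tau)),
         tau_threshold = attr(x, "tau_threshold"),
         floor = attr(x, "floor"))
}
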