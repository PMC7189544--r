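# ggplot2 views of the main result types.

#' Heatmap of a tissue Z-score (or median) profile
#'
#' @param profile Expression tibble (features x tissues).
#' @param max_features Subsample cap for readability (default 100).
#' @return A ggplot object.
#' @export
plot_tissue_heatmap <- function(profile, max_features = 100) {
  long <- profile |>
    dplyr::slice_head(n = max_features) |>
    tidyr::pivot_longer(-"feature_id", names_to = "tissue", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$feature_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = expr_unit(profile)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.specificity_calls <- function(object, ...) {
  all_tau <- attr(object, "all_tau")
  ggplot2::ggplot(all_tau[!is.na(all_tau$tau), ], ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = attr(object, "tau_threshold"),
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = expression(tau), y = "families",
                  title = sprintf("%d tissue-restricted features", nrow(object))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ere_clust <- function(object, ...) {
  support <- object$support
  ggplot2::ggplot(support, ggplot2::aes(x = .data$n_members, y = .data$support)) +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "cluster size", y = "bootstrap support") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rphm_profile <- function(object, ...) {
  ggplot2::ggplot(object$tissues,
                  ggplot2::aes(x = .data$tissue, y = .data$mean_log_rphm,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = log10(object$threshold + 1),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean log10(rphm + 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.viral_homology <- function(object, ...) {
  df <- tibble(boot = object$boot_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$boot)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_mean, colour = "#b2182b") +
    ggplot2::labs(x = "bootstrap mean %identity", y = "groups") +
    ggplot2::theme_minimal()
}

#' Amino-acid composition comparison plot
#'
#' @param ... Named peptide sets (character vectors).
#' @return A ggplot object comparing overall amino-acid frequencies.
#' @export
plot_aa_composition <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("plot_aa_composition: all peptide sets must be named")
  }
  df <- purrr::imap(sets, function(p, nm) mutate(aa_frequencies(p), set = nm)) |>
    bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$frequency,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "amino acid", y = "frequency", fill = NULL) +
    ggplot2::theme_minimal()
}
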