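# Hierarchical clustering of tissues on row Z-scores, with plain bootstrap
# support over feature resampling.

#' Cluster tissues on a Z-score matrix with bootstrap support
#'
#' Agglomerative clustering of tissue columns on Euclidean distance, with
#' per-cluster support computed as the fraction of feature-resampled
#' bootstrap trees (default 1000 iterations) that contain the same tissue
#' subset. Columns are put in lexicographic order first so that ties in the
#' distance matrix are broken deterministically.
#'
#' @param zmatrix Expression tibble of row Z-scores (features x tissues),
#'   >= 3 tissues.
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param seed Integer seed for the feature resampling.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `ere_clust`: list with `hclust`, `support`
#'   (tibble: node, members, support), `n_boot`, `linkage`.
#' @export
cluster_tissues <- function(zmatrix, n_boot = 1000, seed = 1L, linkage = "average") {
  if (n_boot < 1) abort("cluster_tissues: n_boot must be >= 1")
  m <- expr_matrix(zmatrix)
  if (ncol(m) < 3) abort("cluster_tissues: need >= 3 tissues")
  m <- m[, order(colnames(m)), drop = FALSE]
  hc <- hclust(dist(t(m)), method = linkage)
  ref_sets <- cluster_sets(hc)
  counts <- setNames(numeric(length(ref_sets)), ref_sets)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    hb <- hclust(dist(t(m[idx, , drop = FALSE])), method = linkage)
    hits <- intersect(ref_sets, cluster_sets(hb))
    counts[hits] <- counts[hits] + 1
  }
  support <- tibble(
    node = seq_along(ref_sets),
    members = ref_sets,
    n_members = lengths(strsplit(ref_sets, "|", fixed = TRUE)),
    support = unname(counts) / n_boot
  )
  structure(list(hclust = hc, support = support, n_boot = n_boot, linkage = linkage),
            class = "ere_clust")
}

# membership set (sorted, "|"-joined labels) of every internal node
cluster_sets <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    members <- integer(0)
    for (j in 1:2) {
      v <- hc$merge[k, j]
      members <- c(members, if (v < 0) -v else sets[[v]])
    }
    sets[[k]] <- members
  }
  vapply(sets, function(i) paste(sort(labs[i]), collapse = "|"), character(1))
}

#' @export
print.ere_clust <- function(x, ...) {
  cat(sprintf("Tissue clustering (%s linkage, %d tissues, %d bootstrap iterations)\n",
              x$linkage, length(x$hclust$labels), x$n_boot))
  print(x$support, n = 10)
  invisible(x)
}

#' Serialise an `ere_clust` dendrogram as newick text
#' @param x An `ere_clust` object.
#' @return A newick string (branch lengths from merge heights).
#' @export
as_newick <- function(x) {
  stopifnot(inherits(x, "ere_clust"))
  if (requireNamespace("ape", quietly = TRUE)) {
    return(ape::write.tree(ape::as.phylo(x$hclust)))
  }
  # minimal fallback: topology only
  hc <- x$hclust
  rec <- function(k) {
    if (k < 0) return(hc$labels[-k])
    sprintf("(%s,%s)", rec(hc$merge[k, 1]), rec(hc$merge[k, 2]))
  }
  paste0(rec(nrow(hc$merge)), ";")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.ere_clust <- function(x, ...) x$support

#' @export
glance.ere_clust <- function(x, ...) {
  tibble(n_tissues = length(x$hclust$labels), n_boot = x$n_boot,
         linkage = x$linkage, min_support = min(x$support$support),
         median_support = median(x$support$support))
}
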