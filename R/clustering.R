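# Complete-linkage clustering of cell-cycle fingerprints and the Z-scored
# heatmap matrix. Distances are computed on the raw percentages; the Z-score
# transform is a display normalisation only.

#' Euclidean distance matrix between fingerprints
#'
#' Pairwise Euclidean distances on the raw phase percentages (not Z-scored).
#'
#' @param fingerprints Data frame with percent columns `g1`, `s`, `g2m`,
#'   `subg1` and optionally `compound` (used as labels).
#' @return A `dist` object labelled by compound.
#' @export
fingerprint_dist <- function(fingerprints) {
  check_fingerprints(fingerprints)
  if (nrow(fingerprints) < 2) {
    stop("need at least 2 fingerprints to compute distances", call. = FALSE)
  }
  m <- as.matrix(fingerprints[, PHASES])
  rownames(m) <- if ("compound" %in% names(fingerprints)) {
    fingerprints$compound
  } else {
    as.character(seq_len(nrow(fingerprints)))
  }
  stats::dist(m, method = "euclidean")
}

#' Complete-linkage agglomerative clustering
#'
#' Standard agglomerative scheme where the distance between two clusters is
#' the maximum pairwise distance between their members; merge heights are
#' therefore non-decreasing. Computed with [stats::hclust()].
#'
#' @param dist A `dist` object or a symmetric non-negative matrix.
#' @return An object of class `"cc_tree"`: list with `hclust` (the underlying
#'   fit), `merges` (tibble `a`, `b`, `height`; negative ids are leaves,
#'   positive ids earlier merges, as in `hclust$merge`), `leaf_order`
#'   (left-to-right dendrogram order) and `labels`.
#' @export
complete_linkage <- function(dist) {
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist))) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    if (any(dist < 0)) stop("distances must be non-negative", call. = FALSE)
    dist <- stats::as.dist(dist)
  }
  stopifnot(inherits(dist, "dist"))
  hc <- stats::hclust(dist, method = "complete")
  out <- list(
    hclust = hc,
    merges = tibble::tibble(a = hc$merge[, 1], b = hc$merge[, 2],
                            height = hc$height),
    leaf_order = hc$order,
    labels = if (is.null(hc$labels)) as.character(seq_len(attr(dist, "Size")))
             else hc$labels
  )
  class(out) <- "cc_tree"
  out
}

#' @export
print.cc_tree <- function(x, ...) {
  cat("<cc_tree> complete-linkage tree over", length(x$leaf_order),
      "fingerprints;", nrow(x$merges), "merges, max height",
      format(max(x$merges$height), digits = 4), "\n")
  invisible(x)
}

#' Cluster a fingerprint table by its cell-cycle profile
#'
#' Convenience wrapper: [fingerprint_dist()] then [complete_linkage()].
#'
#' @inheritParams fingerprint_dist
#' @return A `"cc_tree"`.
#' @export
cluster_fingerprints <- function(fingerprints) {
  complete_linkage(fingerprint_dist(fingerprints))
}

#' Z-score transform across the four phases
#'
#' Centers and scales each fingerprint (row) by its own mean and sample
#' standard deviation across the four phase values — the heatmap display
#' normalisation. Zero-variance rows map to all zeros with a warning.
#' `margin = "column"` scales each phase across drugs instead.
#'
#' @param x Data frame with phase columns (plus optional `compound`), or a
#'   numeric matrix.
#' @param margin `"row"` (within-fingerprint, default) or `"column"`.
#' @return Same shape as the input with phase values replaced by Z-scores.
#' @export
zscore_transform <- function(x, margin = c("row", "column")) {
  margin <- match.arg(margin)
  is_df <- is.data.frame(x)
  if (is_df) {
    check_fingerprints(x)
    m <- as.matrix(x[, PHASES])
  } else {
    m <- as.matrix(x)
  }
  if (margin == "column") {
    z <- t(zscore_rows(t(m)))
  } else {
    z <- zscore_rows(m)
  }
  if (is_df) {
    out <- tibble::as_tibble(x)
    out[, PHASES] <- as.data.frame(z)
    out
  } else {
    z
  }
}

zscore_rows <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 values per row to Z-score", call. = FALSE)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) mapped to all-zero Z-scores")
    sdv[zero] <- 1
  }
  sweep(sweep(m, 1, mu, "-"), 1, sdv, "/")
}

#' Reorder a fingerprint matrix by the dendrogram leaf order
#'
#' @param tree A `"cc_tree"`.
#' @param z Data frame (with `compound` + phase columns) or matrix whose rows
#'   correspond to the tree's leaves, in the original input order.
#' @return The rows permuted into `tree$leaf_order` — the testable numeric
#'   matrix behind the heatmap.
#' @export
ordered_matrix <- function(tree, z) {
  stopifnot(inherits(tree, "cc_tree"))
  n <- length(tree$leaf_order)
  if (nrow(z) != n) {
    stop("dimension mismatch: tree has ", n, " leaves but `z` has ", nrow(z),
         " rows", call. = FALSE)
  }
  z[tree$leaf_order, , drop = FALSE]
}

#' Clustered fingerprint heatmap
#'
#' Rows (compounds) in dendrogram leaf order, phases as columns, fill on a
#' diverging red (low) to blue (high) scale. Returns the ggplot; the ordered
#' numeric matrix is available via [ordered_matrix()].
#'
#' @param tree A `"cc_tree"` from [cluster_fingerprints()].
#' @param z Z-scored fingerprint table (see [zscore_transform()]) in the same
#'   row order that produced the tree.
#' @return A ggplot object.
#' @export
plot_fingerprint_heatmap <- function(tree, z) {
  ord <- ordered_matrix(tree, z)
  if (!"compound" %in% names(ord)) ord$compound <- tree$labels[tree$leaf_order]
  long <- tidyr::pivot_longer(ord, cols = dplyr::all_of(PHASES),
                              names_to = "phase", values_to = "z")
  long$compound <- factor(long$compound, levels = rev(ord$compound))
  long$phase <- factor(long$phase, levels = PHASES,
                       labels = c("G1", "S", "G2/M", "subG1"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$compound,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  name = "Z-score") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cell-cycle fingerprints (complete linkage order)") +
    ggplot2::theme_minimal()
}

#' Write a dendrogram as Newick
#'
#' @param tree A `"cc_tree"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cc_tree"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  }
  hc <- tree$hclust
  if (is.null(hc$labels)) hc$labels <- tree$labels
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write the merge list of a cluster tree as CSV
#'
#' @inheritParams write_newick
#' @export
write_merges <- function(tree, path) {
  stopifnot(inherits(tree, "cc_tree"))
  readr::write_csv(tree$merges, path)
  invisible(path)
}
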