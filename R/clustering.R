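## Hierarchical clustering of prediction profiles, with Newick export.

#' Hierarchically cluster prediction profiles
#'
#' Agglomerative clustering of profile rows. The default distance is
#' correlation (`1 - Pearson`) with average linkage: prediction profiles
#' carry their functional-similarity signal in their shape rather than
#' their scale. Correlation distance is undefined for constant rows; those
#' raise an error naming the offending rows.
#'
#' @param profiles A `tml_profiles` object or a numeric matrix (rows are
#'   clustered).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @return An object of class `tml_dendrogram` wrapping the `hclust` merge
#'   history (heights are non-decreasing for these linkages; n - 1 merges
#'   for n leaves).
#' @export
hierarchical_cluster <- function(profiles,
                                 distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  M <- if (inherits(profiles, "tml_profiles")) profiles$matrix
       else as.matrix(profiles)
  tml_assert(nrow(M) >= 2, "tml_config_error",
             "clustering needs at least 2 rows")
  if (is.null(rownames(M))) rownames(M) <- paste0("row_", seq_len(nrow(M)))
  if (distance == "correlation") {
    sds <- apply(M, 1, stats::sd)
    bad <- rownames(M)[sds == 0]
    tml_assert(length(bad) == 0, "tml_config_error",
               "correlation distance undefined for constant rows: %s",
               paste(bad, collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(M)))
  } else {
    d <- stats::dist(M)
  }
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2"
                                  else linkage)
  structure(list(hclust = hc, leaf_ids = rownames(M), linkage = linkage,
                 distance = distance),
            class = "tml_dendrogram")
}

#' @export
print.tml_dendrogram <- function(x, ...) {
  cat(sprintf("<tml_dendrogram> %d leaves (%s distance, %s linkage)\n",
              length(x$leaf_ids), x$distance, x$linkage))
  invisible(x)
}

#' Cut a dendrogram into flat clusters
#'
#' Exactly one of `k` (number of clusters) or `height` (cut level) must be
#' given. Cluster labels are deterministic: clusters are numbered by their
#' smallest contained leaf index.
#'
#' @param tree A `tml_dendrogram`.
#' @param k Number of clusters (1 to number of leaves).
#' @param height Cut height (>= 0).
#' @return Named integer vector: leaf id -> cluster label.
#' @export
cut_clusters <- function(tree, k = NULL, height = NULL) {
  stopifnot(inherits(tree, "tml_dendrogram"))
  tml_assert(xor(is.null(k), is.null(height)), "tml_config_error",
             "give exactly one of k or height")
  if (!is.null(k)) {
    tml_assert(k >= 1 && k <= length(tree$leaf_ids), "tml_config_error",
               "k must lie in [1, %d]", length(tree$leaf_ids))
    labels <- stats::cutree(tree$hclust, k = k)
  } else {
    tml_assert(height >= 0, "tml_config_error", "height must be >= 0")
    labels <- stats::cutree(tree$hclust, h = height)
  }
  ## renumber so cluster 1 contains leaf index 1, etc.
  first_seen <- unique(labels[order(seq_along(labels))])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  out <- relabel[as.character(labels)]
  stats::setNames(as.integer(out), tree$leaf_ids)
}

#' Export a dendrogram to Newick
#'
#' Leaf names are the profile row ids; branch lengths are merge-height
#' increments.
#'
#' @param tree A `tml_dendrogram`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "tml_dendrogram"))
  phylo <- ape::as.phylo(tree$hclust)
  nwk <- ape::write.tree(phylo)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
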