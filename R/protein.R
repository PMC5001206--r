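#' Protein-profile similarity between cell lines and tumors
#'
#' Pearson correlation of (phospho-)protein abundance profiles over the
#' proteins shared by the two RPPA matrices. With `subtype_map`, only pairs
#' sharing a subtype label are computed (the subtype-matched variant);
#' non-matching pairs are reported as missing rather than dropped, so the
#' table keeps its full shape.
#'
#' @param cells numeric matrix, proteins x cell lines.
#' @param tumors numeric matrix, proteins x tumors.
#' @param subtype_map optional tibble with `sample_id`, `final_label`.
#' @param min_obs minimum pairwise-complete proteins per pair.
#' @returns Long correlation tibble as from [pairwise_correlation()].
#' @export
protein_similarity <- function(cells, tumors, subtype_map = NULL, min_obs = 3) {
  tab <- pairwise_correlation(cells, tumors, min_obs = min_obs,
                              layer = "protein")
  if (!is.null(subtype_map)) {
    lab <- stats::setNames(subtype_map$final_label, subtype_map$sample_id)
    same <- !is.na(lab[tab$cell_id]) & !is.na(lab[tab$tumor_id]) &
      lab[tab$cell_id] == lab[tab$tumor_id]
    tab$r[!same] <- NA_real_
  }
  tab
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters the columns of a features x samples matrix, by default under
#' correlation distance (1 - Pearson) with average linkage — the usual
#' choices for expression/RPPA sample clustering, where profile shape rather
#' than absolute level should drive the grouping.
#'
#' @param m numeric matrix, features x samples (>= 2 of each).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param distance `"one_minus_pearson"` (default) or `"euclidean"`.
#' @returns An object of class `portrait_clust` wrapping the merge tree;
#'   supports [cut_clusters()], [generics::tidy()], [generics::glance()],
#'   `plot()` and [write_dendrogram_newick()].
#' @export
hierarchical_cluster <- function(m,
                                 linkage = c("average", "complete", "single"),
                                 distance = c("one_minus_pearson", "euclidean")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  stopifnot(is.matrix(m), ncol(m) >= 2, nrow(m) >= 2)
  if (distance == "one_minus_pearson") {
    sds <- apply(m, 2, stats::sd, na.rm = TRUE)
    if (any(is.na(sds) | sds == 0)) {
      bad <- colnames(m)[which(is.na(sds) | sds == 0)[1]]
      stop(sprintf("constant profile for sample '%s'; correlation distance undefined",
                   bad), call. = FALSE)
    }
    d <- stats::as.dist(1 - stats::cor(m, use = "pairwise.complete.obs"))
  } else {
    d <- stats::dist(t(m))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(hclust = hc, linkage = linkage, distance = distance,
         n_features = nrow(m)),
    class = "portrait_clust"
  )
}

#' Cut a sample dendrogram into k clusters
#'
#' Removes the k - 1 highest merges of the tree, yielding the k-cluster
#' partition.
#'
#' @param tree `portrait_clust` object from [hierarchical_cluster()].
#' @param k number of clusters, between 1 and the leaf count.
#' @returns Tibble with `sample_id`, `cluster` (integer ids 1..k).
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "portrait_clust"))
  n <- length(tree$hclust$labels)
  if (!(k >= 1 && k <= n)) {
    stop(sprintf("k must lie in [1, %d]", n), call. = FALSE)
  }
  cl <- stats::cutree(tree$hclust, k = k)
  tibble::tibble(sample_id = names(cl), cluster = as.integer(cl))
}

#' Export a sample dendrogram in Newick format
#'
#' Branch lengths are differences of merge heights, so root-to-leaf path
#' lengths reproduce the merge heights of the tree.
#'
#' @param tree `portrait_clust` object.
#' @param path output path.
#' @returns `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  stopifnot(inherits(tree, "portrait_clust"))
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}

#' @export
print.portrait_clust <- function(x, ...) {
  cat(sprintf(
    "Hierarchical clustering of %d samples (%s linkage, %s distance, %d features)\n",
    length(x$hclust$labels), x$linkage,
    ifelse(x$distance == "one_minus_pearson", "1 - Pearson", x$distance),
    x$n_features
  ))
  invisible(x)
}

#' @export
plot.portrait_clust <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", ...)
  invisible(x)
}

#' Tidy the merge steps of a clustering
#'
#' @param x `portrait_clust` object.
#' @param ... unused.
#' @returns Tibble with one row per merge: `step`, `height`, and the two
#'   merged items (negative values index leaves, positive values earlier
#'   merges, following the `stats::hclust` convention).
#' @method tidy portrait_clust
#' @export
tidy.portrait_clust <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    item1 = hc$merge[, 1], item2 = hc$merge[, 2],
    height = hc$height
  )
}

#' One-line summary of a clustering
#'
#' @param x `portrait_clust` object.
#' @param ... unused.
#' @returns One-row tibble with `n_samples`, `n_features`, `linkage`,
#'   `distance`, `max_height`.
#' @method glance portrait_clust
#' @export
glance.portrait_clust <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$hclust$labels),
    n_features = x$n_features,
    linkage = x$linkage,
    distance = x$distance,
    max_height = max(x$hclust$height)
  )
}
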