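# Single-linkage hierarchical clustering of fingerprint similarity matrices,
# and per-cluster mean similarity (the "MFS" summaries of the reference
# analysis). The agglomeration itself is delegated to stats::hclust.

#' Single-linkage clustering of a similarity matrix
#'
#' Distances are `1 - similarity`; the dendrogram is cut to `n_clusters`
#' groups. Labels are invariant (up to renaming) under input permutation.
#'
#' @param matrix a `similarity_matrix` (or symmetric numeric matrix with unit
#'   diagonal and dimnames).
#' @param n_clusters number of clusters, between 1 and the number of
#'   compounds.
#' @return a `cluster_assignment`: list with `labels` (named integer vector),
#'   `merge_heights` (non-decreasing linkage distances) and the underlying
#'   `hclust` object.
#' @export
single_linkage_cluster <- function(matrix, n_clusters) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  n <- nrow(matrix)
  if (n_clusters < 1L || n_clusters > n) {
    stop("n_clusters must be between 1 and ", n, call. = FALSE)
  }
  ids <- rownames(matrix) %||% as.character(seq_len(n))
  if (n == 1L) {
    out <- list(labels = stats::setNames(1L, ids), merge_heights = numeric(0),
                hclust = NULL)
    class(out) <- "cluster_assignment"
    return(out)
  }
  d <- stats::as.dist(1 - matrix)
  hc <- stats::hclust(d, method = "single")
  labels <- stats::cutree(hc, k = n_clusters)
  names(labels) <- ids
  out <- list(labels = labels, merge_heights = hc$height, hclust = hc)
  class(out) <- "cluster_assignment"
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d compounds in %d clusters>\n",
              length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Mean within-cluster pairwise similarity
#'
#' For each cluster with at least two members, the mean of the off-diagonal
#' pairwise similarities; singleton clusters are omitted (their mean is
#' undefined).
#'
#' @param assignment a `cluster_assignment`.
#' @param matrix the `similarity_matrix` the assignment was computed from.
#' @return named numeric vector, one entry per non-singleton cluster.
#' @export
cluster_mean_similarity <- function(assignment, matrix) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ids <- names(assignment$labels)
  if (is.null(rownames(matrix)) || !setequal(ids, rownames(matrix))) {
    stop("assignment and similarity matrix ids do not match", call. = FALSE)
  }
  out <- numeric(0)
  for (cl in sort(unique(assignment$labels))) {
    members <- ids[assignment$labels == cl]
    if (length(members) < 2L) next
    sub <- matrix[members, members, drop = FALSE]
    out[as.character(cl)] <- mean(sub[upper.tri(sub)])
  }
  out
}

#' Write a similarity matrix to CSV
#' @param matrix a `similarity_matrix`.
#' @param path output file.
#' @export
write_similarity_matrix <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cluster assignment to CSV
#' @param assignment a `cluster_assignment`.
#' @param path output file.
#' @export
write_cluster_assignment <- function(assignment, path) {
  df <- data.frame(id = names(assignment$labels),
                   cluster = unname(assignment$labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
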