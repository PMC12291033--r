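#' Correlation dissimilarity between feature intensity profiles
#'
#' `d_ij = |1 - r_ij|` where `r_ij` is the correlation between the i-th and
#' j-th feature columns.  Note the absolute value makes perfectly
#' anti-correlated features maximally distant (d = 2), unlike `1 - |r|`.
#'
#' @param X numeric N x M intensity matrix (M >= 2), columns named by
#'   feature id; no constant columns.
#' @param method correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return symmetric M x M matrix with exact zero diagonal.
#' @export
correlation_dissimilarity <- function(X, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 features")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature column(s): ",
         paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", "))
  d <- abs(1 - stats::cor(X, method = method))
  diag(d) <- 0
  d
}

#' Cluster features on a precomputed dissimilarity
#'
#' Agglomerative hierarchical clustering with complete (farthest point)
#' linkage; the tree is flattened at each candidate cluster count and the
#' count with the highest mean silhouette width (computed from the same
#' dissimilarity matrix) is returned.  Silhouette ties break toward fewer
#' clusters.  With fewer than 3 features no silhouette scan is possible and
#' a single cluster is returned with `degenerate = TRUE`.
#'
#' @param dissimilarity symmetric matrix from
#'   [correlation_dissimilarity()].
#' @param k_range candidate cluster counts; default `2:min(M - 1, 30)`.
#' @return list of class `"cluster_result"`: `dissimilarity`, `linkage`
#'   (an `hclust` tree, `NULL` when degenerate), `k`, `labels` (named
#'   integer vector), `silhouette_by_k`, `degenerate`.
#' @export
cluster_features <- function(dissimilarity, k_range = NULL) {
  d <- as.matrix(dissimilarity)
  M <- ncol(d)
  ids <- colnames(d)
  if (M < 3) {
    labels <- rep(1L, M)
    names(labels) <- ids
    return(structure(list(dissimilarity = d, linkage = NULL, k = 1L,
                          labels = labels, silhouette_by_k = numeric(0),
                          degenerate = TRUE),
                     class = "cluster_result"))
  }
  if (is.null(k_range)) k_range <- 2:min(M - 1, 30)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > M - 1))
    stop("k_range must lie within [2, M-1]")
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  sil <- vapply(k_range, function(k) {
    labels <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(labels, dmatrix = d)[, "sil_width"])
  }, 1.0)
  names(sil) <- k_range
  k <- k_range[which.max(sil)]   # which.max takes the first (smallest k) tie
  labels <- stats::cutree(hc, k = k)
  names(labels) <- ids
  structure(list(dissimilarity = d, linkage = hc, k = k, labels = labels,
                 silhouette_by_k = sil, degenerate = FALSE),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$labels), "features, k =", x$k,
      if (x$degenerate) "(degenerate)\n" else
        sprintf("(mean silhouette %.3f)\n", x$silhouette_by_k[as.character(x$k)]))
  invisible(x)
}

#' Export cluster assignments as a CSV table
#' @param result a `"cluster_result"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(result, path) {
  utils::write.table(data.frame(feature_id = names(result$labels),
                                cluster = unname(result$labels)),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
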