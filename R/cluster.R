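#' Sample-to-sample Euclidean distance matrix
#'
#' Pairwise Euclidean distance between sample columns of the common-protein
#' matrix, by default on log2 ratios so up- and down-regulation are treated
#' symmetrically.
#'
#' @param x a complete \code{ProteomeSet} (or plain proteins x samples
#'   matrix).
#' @param logTransform compute distances on log2-transformed ratios
#'   (default TRUE).
#' @return symmetric distance matrix with zero diagonal.
#' @export
sampleDistanceMatrix <- function(x, logTransform = TRUE) {
  v <- if (is(x, "ProteomeSet")) assay(x, "ratio") else x
  if (anyNA(v)) stop("distance computation requires a complete matrix")
  if (logTransform) v <- log2(v)
  as.matrix(dist(t(v), method = "euclidean"))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample distance matrix; the resulting
#' dendrogram determines the heatmap sample order. Linkage defaults to
#' complete.
#'
#' @param d symmetric distance matrix (or \code{dist}).
#' @param linkage one of \code{"complete"}, \code{"average"},
#'   \code{"single"}.
#' @return an \code{hclust} object.
#' @export
hierarchicalCluster <- function(d, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) {
    if (nrow(d) != ncol(d)) stop("distance matrix must be square")
    d <- as.dist(d)
  }
  if (attr(d, "Size") < 2L) stop("need at least 2 samples to cluster")
  hclust(d, method = linkage)
}

#' Purity of a k-cluster cut with respect to sample groups
#'
#' Cuts the dendrogram into k clusters and reports the fraction of samples
#' belonging to the majority group of their cluster; 1 means clusters
#' cosegregate entirely by sample type.
#'
#' @param dend an \code{hclust} over the samples.
#' @param groups named sample -> group vector (e.g. \code{sampleGroups(x)}).
#' @param k number of clusters; must not exceed the sample count.
#' @return purity in [0, 1].
#' @export
groupPurity <- function(dend, groups, k) {
  cl <- cutree(dend, k = k)
  g <- groups[names(cl)]
  sum(vapply(split(g, cl), function(v) max(table(v)), numeric(1))) / length(cl)
}

#' Serialise a dendrogram as Newick
#'
#' Sample ids become leaves; branch lengths derive from the merge heights.
#'
#' @param dend an \code{hclust}.
#' @param path output path.
#' @export
writeDendrogramNewick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
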