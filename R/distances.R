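#' Sample-relationship diagnostics from leading log2 fold changes
#'
#' Computes pairwise sample distances as the root mean square of the top-k
#' largest absolute log2 expression differences between each pair of samples
#' (the "leading log2 fold change"), then summarises them by average-linkage
#' hierarchical clustering and classical two-dimensional multidimensional
#' scaling.
#'
#' @param logged Log2 expression matrix, genes x samples (e.g. the
#'   \code{logged} component of [transform_and_weight()]).
#' @param top_k Number of most divergent genes per pair (default 500;
#'   clamped to the gene count with a warning).
#' @return A list of class \code{sample_distances}: \code{dist} (matrix),
#'   \code{hclust}, \code{mds} (samples x 2), \code{newick} (the clustering
#'   tree as a Newick string), \code{top_k}.
#' @export
sample_distances <- function(logged, top_k = 500) {
  logged <- as.matrix(logged)
  n <- ncol(logged)
  if (n < 2L) stop("need at least 2 samples")
  if (top_k > nrow(logged)) {
    warning("top_k larger than gene count; clamped to ", nrow(logged))
    top_k <- nrow(logged)
  }
  d <- matrix(0, n, n, dimnames = list(colnames(logged), colnames(logged)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dif2 <- (logged[, i] - logged[, j])^2
    top <- sort(dif2, decreasing = TRUE)[seq_len(top_k)]
    d[i, j] <- d[j, i] <- sqrt(mean(top))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  mds <- stats::cmdscale(stats::as.dist(d), k = 2)
  colnames(mds) <- c("dim1", "dim2")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  out <- list(dist = d, hclust = hc, mds = mds, newick = nwk, top_k = top_k)
  class(out) <- "sample_distances"
  out
}
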