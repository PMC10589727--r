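# Ordering and clustering structures: the three-step hierarchical-
# clustering heatmap order and SNN-Leiden consensus clustering.

# 10-d neighborhood embedding of a precomputed distance matrix. UMAP is
# used when the instance is large enough for its neighbor graph to be
# meaningful; tiny instances fall back to classical MDS on the same
# distances.
embed_dist <- function(d, n_dim = 10L, seed = 1L) {
  n <- nrow(d)
  n_dim <- max(1L, min(n_dim, n - 2L))
  if (n < 10L) {
    em <- stats::cmdscale(stats::as.dist(d), k = n_dim)
    return(matrix(em, nrow = n))
  }
  with_seed(stream_seed(seed, "embed"), {
    uwot::umap(stats::as.dist(d), n_components = n_dim,
               n_neighbors = min(15L, n - 1L), min_dist = 0.1,
               n_threads = 1, n_sgd_threads = 1)
  })
}

#' Three-step hierarchical ordering of items
#'
#' Step 1 embeds the items into a low-dimensional neighborhood space under
#' the requested metric (so Ward linkage and k-means, which assume
#' euclidean geometry, can be applied to any metric). Step 2, only when
#' there are more than `kmeans_cap` items, groups very similar points with
#' k-means into at most `kmeans_cap` centroids. Step 3 runs Ward
#' hierarchical clustering on the centroids; the final item order is the
#' dendrogram leaf order with items sorted by index within each centroid
#' group.
#'
#' @param x items x features matrix (binary for yule / sorensen-dice).
#' @param metric one of "yule", "sorensen-dice", "pearson-correlation",
#'   "euclidean".
#' @param kmeans_cap maximum number of points fed to Ward linkage.
#' @param n_dim embedding dimensionality (default 10).
#' @param seed integer seed.
#' @return list with `order` (item indices), `hc` (the hclust tree over
#'   centroids), `embedding`, and `centroid_of` (item -> centroid map).
#' @export
three_step_hc <- function(x, metric = "euclidean", kmeans_cap = 50000L,
                          n_dim = 10L, seed = 1L) {
  d <- metric_dist(x, metric)
  n <- nrow(d)
  em <- embed_dist(d, n_dim = n_dim, seed = seed)
  if (n > kmeans_cap) {
    km <- with_seed(stream_seed(seed, "kmeans"), {
      stats::kmeans(em, centers = kmeans_cap, iter.max = 50L, nstart = 1L)
    })
    centers <- km$centers
    centroid_of <- km$cluster
  } else {
    centers <- em
    centroid_of <- seq_len(n)
  }
  hc <- stats::hclust(stats::dist(centers), method = "ward.D2")
  ord <- unlist(lapply(hc$order, function(cc) sort(which(centroid_of == cc))))
  list(order = ord, hc = hc, embedding = em, centroid_of = centroid_of)
}

# Exact k-nearest-neighbor indices from a distance matrix (self excluded).
knn_from_dist <- function(d, k) {
  n <- nrow(d)
  k <- min(k, n - 1L)
  idx <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    ord <- ord[ord != i] # ties at distance zero must not keep self
    ord[seq_len(k)]
  })
  matrix(unlist(idx), nrow = n, byrow = TRUE)
}

#' Shared-nearest-neighbor Leiden clustering
#'
#' Builds a k-nearest-neighbor graph under the requested metric (exact
#' neighbors below `exact_below` items, approximate via the 10-d embedding
#' otherwise), weights each edge by the number of shared neighbors, and
#' partitions the graph with the Leiden algorithm (modularity objective).
#' The number of clusters is data-driven.
#'
#' @param x items x features matrix.
#' @param metric distance metric (see [three_step_hc()]).
#' @param k_neighbors neighborhood size (default 30).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer seed.
#' @param exact_below use exact neighbors below this many items.
#' @return integer cluster labels 0..C-1, one per item.
#' @export
snn_leiden <- function(x, metric = "euclidean", k_neighbors = 30L,
                       resolution = 1, seed = 1L, exact_below = 5000L) {
  n <- nrow(x)
  stopifnot(n >= 2L)
  k <- min(k_neighbors, n - 1L)
  if (n <= exact_below) {
    d <- metric_dist(x, metric)
    nn <- knn_from_dist(d, k)
  } else {
    em <- embed_dist(metric_dist(x, metric), n_dim = 10L, seed = seed)
    nn <- RANN_or_exact(em, k)
  }
  # neighborhood membership matrix (including self, as in SNN practice)
  B <- matrix(FALSE, n, n)
  B[cbind(rep(seq_len(n), each = ncol(nn)), as.vector(t(nn)))] <- TRUE
  diag(B) <- TRUE
  shared <- tcrossprod(B * 1)
  adj <- (B | t(B)) & shared > 0
  diag(adj) <- FALSE
  W <- shared * adj
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- with_seed(stream_seed(seed, "leiden"), {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5L)
  })
  igraph::membership(cl) - 1L
}

RANN_or_exact <- function(em, k) {
  if (requireNamespace("RANN", quietly = TRUE)) {
    RANN::nn2(em, k = k + 1L)$nn.idx[, -1, drop = FALSE]
  } else {
    knn_from_dist(as.matrix(stats::dist(em)), k)
  }
}

#' Export a dendrogram as Newick-like text
#' @param hc an hclust object.
#' @return a single character string.
#' @export
dendrogram_newick <- function(hc) {
  lab <- if (is.null(hc$labels)) as.character(seq_along(hc$order)) else hc$labels
  node <- function(i) {
    if (i < 0) return(lab[-i])
    m <- hc$merge[i, ]
    sprintf("(%s,%s):%.4g", node(m[1]), node(m[2]), hc$height[i])
  }
  root <- nrow(hc$merge)
  m <- hc$merge[root, ]
  sprintf("(%s,%s);", node(m[1]), node(m[2]))
}
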