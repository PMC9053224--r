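# Minimum-variance (Ward) agglomerative clustering via the Lance-Williams
# recurrence on squared dissimilarities -- the same convention as scipy's
# `linkage(..., method = "ward")` and stats::hclust(method = "ward.D2"),
# with a deterministic tie-break by lowest label index.

#' Ward minimum-variance hierarchical clustering
#'
#' Agglomerates the items of a dissimilarity matrix under the Ward update
#' `d2(k, i+j) = ((n_i + n_k) d2(k,i) + (n_j + n_k) d2(k,j) - n_k d2(i,j))
#' / (n_i + n_j + n_k)` applied to squared input dissimilarities; merge
#' heights are square roots of the minimized criterion. Ties are broken by
#' the lowest pair of label indices, so the tree is deterministic.
#'
#' @param dist symmetric dissimilarity matrix (or `dist` object) with zero
#'   diagonal; all entries must be finite.
#' @return object of classes `linkage_tree` and `hclust`: `merge`
#'   (hclust convention: negative = leaf), `height`, `order`, `labels`.
#' @export
ward_cluster <- function(dist) {
  D <- if (inherits(dist, "dist")) as.matrix(dist) else as.matrix(dist)
  if (any(!is.finite(D))) {
    stop("ward_cluster: non-finite distances", call. = FALSE)
  }
  n <- nrow(D)
  stopifnot(n >= 2, isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D2 <- D^2
  diag(D2) <- Inf
  active <- seq_len(n)
  size <- rep(1L, n)
  node_id <- -seq_len(n)          # hclust convention
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    sub <- D2[active, active, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # lowest (row, col) index pair wins ties; use i < j ordering
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
    i <- active[best[1L]]
    j <- active[best[2L]]
    hij <- D2[i, j]
    height[step] <- sqrt(hij)
    merge[step, ] <- sort(c(node_id[i], node_id[j]))
    others <- setdiff(active, c(i, j))
    if (length(others) > 0L) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      newd <- ((ni + nk) * D2[i, others] + (nj + nk) * D2[j, others] -
                 nk * hij) / (ni + nj + nk)
      D2[i, others] <- newd
      D2[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    node_id[i] <- step
    active <- setdiff(active, j)
  }
  order <- tree_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "ward",
                 call = match.call(), dist.method = "precomputed"),
            class = c("linkage_tree", "hclust"))
}

# leaf order by depth-first traversal of the merge tree
tree_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a linkage tree and score cluster purity by a leaf annotation
#'
#' Cuts the tree into `k` clusters and returns, for each cluster, the
#' fraction of leaves carrying that cluster's most common annotation value
#' (e.g. the side-effect id of each medication x side-effect column).
#'
#' @param tree a `linkage_tree`.
#' @param k number of clusters.
#' @param annotation character vector aligned with the tree's leaves.
#' @return data.frame with cluster id, size, majority annotation and purity.
#' @export
cluster_purity <- function(tree, k, annotation) {
  stopifnot(length(annotation) == length(tree$labels))
  cl <- stats::cutree(tree, k = k)
  do.call(rbind, lapply(sort(unique(cl)), function(g) {
    ann <- annotation[cl == g]
    tab <- sort(table(ann), decreasing = TRUE)
    data.frame(cluster = g, size = length(ann),
               majority = names(tab)[1L],
               purity = as.numeric(tab[1L]) / length(ann),
               stringsAsFactors = FALSE)
  }))
}
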