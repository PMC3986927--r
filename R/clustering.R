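#' Centred Pearson distance between phenotypic profiles
#'
#' Distance between matrix rows defined as 1 - r, where r is the
#' (mean-centred) Pearson correlation across conditions, computed over
#' pairwise-complete columns. Distances lie in [0, 2]: 0 for perfectly
#' correlated profiles, 2 for perfectly anti-correlated ones. Rows with
#' zero variance carry no profile shape; their correlation is treated as 0
#' (distance 1 to everything) and they are flagged.
#'
#' @param mat Numeric matrix (e.g. a [log_ratio_matrix()]), >= 2 rows; every
#'   row needs >= 2 non-missing columns shared with each other row.
#' @return A symmetric matrix of class `pm_dist` with zero diagonal and
#'   attribute `zero_variance` (row names flagged).
#' @export
centred_pearson_distance <- function(mat) {
  mat <- unclass(mat)
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop("need a matrix with at least 2 rows")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  usable <- rowSums(is.finite(mat))
  if (any(usable < 2L))
    stop("row(s) with fewer than 2 usable columns: ",
         paste(rownames(mat)[usable < 2L], collapse = ", "))
  shared <- tcrossprod(is.finite(mat) * 1)
  if (any(shared < 2L))
    stop("row pair with fewer than 2 shared columns")
  suppressWarnings(
    r <- stats::cor(t(mat), use = "pairwise.complete.obs")
  )
  zv <- rownames(mat)[apply(mat, 1L, function(x) {
    x <- x[is.finite(x)]
    stats::sd(x) == 0
  })]
  r[!is.finite(r)] <- 0   # zero-variance rows: undefined r treated as 0
  d <- 1 - r
  diag(d) <- 0
  d <- (d + t(d)) / 2     # enforce exact symmetry
  structure(d, class = c("pm_dist", class(d)), zero_variance = zv)
}

#' UPGMA (average-linkage) agglomerative clustering
#'
#' From-scratch implementation of the Sokal-Michener unweighted pair-group
#' method: the distance matrix is scanned for its minimum (the most similar
#' pair), the pair is merged at that height, and the merged cluster's
#' distance to every other cluster is the size-weighted mean
#' d(k, i+j) = (n_i d(k,i) + n_j d(k,j)) / (n_i + n_j) — equivalently the
#' mean of all original pairwise distances between members. Ties resolve
#' deterministically to the pair with the smallest node creation indices
#' (leaves in input order, internal nodes in merge order); the older node
#' becomes the left child.
#'
#' @param dist A `pm_dist` matrix (or any symmetric numeric matrix with zero
#'   diagonal), n >= 2.
#' @return A `pm_dendrogram`: list with `merge` (hclust-style n-1 x 2
#'   matrix; negative entries are leaves, positive earlier merges),
#'   `height` (merge heights, non-decreasing), `labels`, `size` (member
#'   count per merge) and `n`.
#' @seealso [leaf_order()], [as.hclust.pm_dendrogram()], [cut_dendrogram()]
#' @export
upgma <- function(dist) {
  d <- unclass(dist)
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L)
    stop("need a square distance matrix with n >= 2")
  if (max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: creation id (1..n leaves, n+m for merge m), size,
  # hclust merge code
  creation <- seq_len(n)
  size <- rep(1L, n)
  code <- -seq_len(n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    k <- length(creation)
    # minimum off-diagonal distance
    Dm <- D
    Dm[!upper.tri(Dm)] <- Inf
    best <- min(Dm)
    cand <- which(Dm <= best, arr.ind = TRUE)
    # tie-break: smallest (older creation id, then younger creation id)
    key_lo <- pmin(creation[cand[, 1L]], creation[cand[, 2L]])
    key_hi <- pmax(creation[cand[, 1L]], creation[cand[, 2L]])
    pick <- order(key_lo, key_hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    if (creation[i] > creation[j]) { tmp <- i; i <- j; j <- tmp }
    merge[m, ] <- c(code[i], code[j])
    height[m] <- D[i, j]
    msize[m] <- size[i] + size[j]
    # size-weighted update against all remaining clusters; equal distances
    # pass through unchanged so ultrametric inputs stay exact
    others <- setdiff(seq_len(k), c(i, j))
    di <- D[i, others]; dj <- D[j, others]
    newd <- ifelse(di == dj, di,
                   (size[i] * di + size[j] * dj) / (size[i] + size[j]))
    keep <- others
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    creation <- c(creation[keep], n + m)
    size <- c(size[keep], msize[m])
    code <- c(code[keep], m)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 size = msize, n = n),
            class = "pm_dendrogram")
}

#' @export
print.pm_dendrogram <- function(x, ...) {
  cat("<pm_dendrogram> ", x$n, " leaves, ", length(x$height),
      " merges, heights ", format(min(x$height), digits = 4), "..",
      format(max(x$height), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Leaf order of a dendrogram
#'
#' Depth-first traversal, left child first; deterministic given the tree.
#'
#' @param dend A `pm_dendrogram`.
#' @return Character vector of leaf labels in display order.
#' @export
leaf_order <- function(dend) {
  stopifnot(inherits(dend, "pm_dendrogram"))
  dend$labels[leaf_order_idx(dend)]
}

leaf_order_idx <- function(dend) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(dend$merge[node, 1L]), walk(dend$merge[node, 2L]))
  }
  walk(nrow(dend$merge))
}

#' Convert a `pm_dendrogram` to an `hclust` object
#'
#' Allows reuse of the standard tree utilities (`cutree`, `plot`,
#' `as.dendrogram`, `cophenetic`).
#'
#' @param x A `pm_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.pm_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order_idx(x), labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "centred_pearson"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' @param dend A `pm_dendrogram`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships (leaf labels).
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "pm_dendrogram"))
  stats::cutree(as.hclust(dend), k = k)
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance between two leaves is the height of their lowest
#' common ancestor; for an ultrametric input matrix UPGMA reproduces the
#' input exactly.
#'
#' @param dend A `pm_dendrogram`.
#' @return Symmetric numeric matrix with the dendrogram's leaf labels.
#' @export
cophenetic_matrix <- function(dend) {
  stopifnot(inherits(dend, "pm_dendrogram"))
  n <- dend$n
  out <- matrix(0, n, n, dimnames = list(dend$labels, dend$labels))
  members <- vector("list", nrow(dend$merge))
  for (m in seq_len(nrow(dend$merge))) {
    kids <- lapply(dend$merge[m, ], function(node)
      if (node < 0L) -node else members[[node]])
    out[kids[[1L]], kids[[2L]]] <- dend$height[m]
    out[kids[[2L]], kids[[1L]]] <- dend$height[m]
    members[[m]] <- c(kids[[1L]], kids[[2L]])
  }
  out
}
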