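# Single CART classification tree (Gini impurity), grown greedily.
# Kept deliberately small: two features, binary labels, deterministic
# tie-breaking (lower feature index, then lower threshold).

.gini <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

# Best split of one node: search midpoints of sorted unique values of
# every feature, maximizing the impurity decrease.
.bestSplit <- function(X, labels, minLeaf) {
  n <- length(labels)
  parent <- .gini(labels)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    v <- X[, f]
    u <- sort(unique(v))
    if (length(u) < 2) next
    cuts <- (head(u, -1) + tail(u, -1)) / 2
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      if (nl < minLeaf || n - nl < minLeaf) next
      dec <- parent - (nl * .gini(labels[left]) +
                       (n - nl) * .gini(labels[!left])) / n
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(feature = f, threshold = cut, decrease = dec)
      }
      # ties: the earlier (lower feature index, lower threshold)
      # candidate wins because later candidates need a strict gain
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

.growTree <- function(X, labels, depth, maxDepth, minLeaf) {
  counts <- table(factor(labels, levels = c("well", "poor")))
  majority <- names(counts)[which.max(counts)]
  leaf <- list(class = majority, n = length(labels),
               counts = as.list(counts))
  if (length(unique(labels)) == 1 || depth >= maxDepth ||
      length(labels) < 2 * minLeaf) {
    return(leaf)
  }
  sp <- .bestSplit(X, labels, minLeaf)
  if (is.null(sp)) return(leaf)
  left <- X[, sp$feature] <= sp$threshold
  list(
    feature = sp$feature, threshold = sp$threshold,
    left = .growTree(X[left, , drop = FALSE], labels[left],
                     depth + 1, maxDepth, minLeaf),
    right = .growTree(X[!left, , drop = FALSE], labels[!left],
                      depth + 1, maxDepth, minLeaf)
  )
}

#' Fit a single decision tree on the (AlogP, PSA) plane
#'
#' Grows a binary CART tree by greedy Gini-impurity splits. Split
#' candidates are the midpoints of sorted unique feature values; a node
#' becomes a leaf when it is pure, the depth limit is reached, or it is
#' too small to split into two leaves of at least `minLeaf` points.
#' Single-class input yields a depth-0 majority leaf.
#'
#' @param points two-column matrix/data.frame of (AlogP, PSA) pairs.
#' @param labels `"well"` / `"poor"` class labels, one per row.
#' @param maxDepth maximum tree depth (default 4).
#' @param minLeaf minimum points per leaf (default 5).
#' @return A [TreeModel-class].
#' @export
fitTree <- function(points, labels, maxDepth = 4L, minLeaf = 5L) {
  X <- as.matrix(points)
  if (length(labels) != nrow(X)) stop("one label per point required")
  if (!all(labels %in% c("well", "poor"))) {
    stop("labels must be 'well' or 'poor'")
  }
  if (nrow(X) < 2 * minLeaf && length(unique(labels)) > 1) {
    stop("need at least 2*minLeaf points to grow a nontrivial tree")
  }
  feats <- colnames(X)
  if (is.null(feats)) feats <- c("alogp", "psa")
  new("TreeModel",
    nodes = .growTree(X, labels, 0L, maxDepth, minLeaf),
    features = feats,
    maxDepth = as.numeric(maxDepth), minLeaf = as.numeric(minLeaf)
  )
}

#' @rdname fitTree
#' @param model a fitted [TreeModel-class].
#' @export
treeClassify <- function(model, points) {
  stopifnot(is(model, "TreeModel"))
  P <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  apply(P, 1, function(x) {
    node <- model@nodes
    while (is.null(node$class)) {
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    }
    node$class
  })
}

# Depth of a fitted tree (internal; used by tests and summaries).
.treeDepth <- function(node) {
  if (!is.null(node$class)) return(0L)
  1L + max(.treeDepth(node$left), .treeDepth(node$right))
}
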