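# Rational dataset splitting by sphere exclusion in autoscaled
# descriptor space.

# Autoscale a numeric matrix to zero mean / unit SD; constant columns
# are dropped from the metric with a warning.
.autoscale <- function(X) {
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(
      "constant column(s) dropped from the distance metric: ",
      paste(colnames(X)[!keep], collapse = ", ")
    )
  }
  Xs <- sweep(X[, keep, drop = FALSE], 2, ctr[keep], "-")
  Xs <- sweep(Xs, 2, sds[keep], "/")
  list(X = Xs, center = ctr[keep], scale = sds[keep],
       columns = colnames(X)[keep])
}

.descriptorMatrix <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(descriptorNames("model"), names(table))
    if (length(columns) == 0) {
      columns <- setdiff(
        names(table)[vapply(table, is.numeric, logical(1))],
        c("F", "target")
      )
    }
  }
  missing <- setdiff(columns, names(table))
  if (length(missing)) {
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(table[, columns, drop = FALSE])
  if (anyNA(X)) stop("descriptor table contains NA cells")
  storage.mode(X) <- "double"
  rownames(X) <- table$id
  X
}

#' Sphere-exclusion train/test split
#'
#' Splits a descriptor table into a structurally diverse training set
#' and a test set. Descriptor columns are autoscaled to zero mean and
#' unit SD; then, starting from the point closest to the data centroid,
#' the unassigned point farthest (in Euclidean distance) from the
#' current training set is repeatedly moved to training and every
#' unassigned point within `radius` of it is assigned to test. Ties
#' break on the lower row index. By construction every pair of training
#' points is more than `radius` apart and every test point lies within
#' `radius` of some training point.
#'
#' @param table data.frame with an `id` column and numeric descriptor
#'   columns (the modeling set of [descriptorNames()] when present).
#' @param radius exclusion radius, in autoscaled descriptor units (> 0).
#' @param seed kept for interface symmetry; the algorithm is
#'   deterministic and ignores it.
#' @param columns optional explicit descriptor column selection.
#' @return A [SplitResult-class] with empty `externalIds`.
#' @export
sphereExclusionSplit <- function(table, radius, seed = 0L, columns = NULL) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("radius must be a single positive number")
  }
  X <- .descriptorMatrix(table, columns)
  if (nrow(X) < 2) stop("need at least 2 rows to split")
  sc <- .autoscale(X)
  Xs <- sc$X
  n <- nrow(Xs)
  ids <- if (!is.null(table$id)) as.character(table$id) else as.character(seq_len(n))

  assigned <- rep(NA_character_, n)
  # distance of every point to the current training set (min over members)
  dtrain <- rep(Inf, n)
  centroid <- colMeans(Xs)
  d0 <- sqrt(colSums((t(Xs) - centroid)^2))
  pick <- which.min(d0) # deterministic: which.min takes the first minimum
  repeat {
    assigned[pick] <- "train"
    dpick <- sqrt(colSums((t(Xs) - Xs[pick, ])^2))
    near <- is.na(assigned) & dpick <= radius
    assigned[near] <- "test"
    dtrain <- pmin(dtrain, dpick)
    open <- which(is.na(assigned))
    if (length(open) == 0) break
    pick <- open[which.max(dtrain[open])]
  }
  new("SplitResult",
    trainIds = ids[assigned == "train"],
    testIds = ids[assigned == "test"],
    externalIds = character(),
    radius = radius,
    scaling = list(center = sc$center, scale = sc$scale, columns = sc$columns)
  )
}

#' Tune the exclusion radius for a target training fraction
#'
#' Bisects on the radius until the training-set size lands within
#' `tolerance` compounds of `round(targetTrainFraction * n)`. The
#' training size is non-increasing in the radius, which makes bisection
#' valid.
#'
#' @inheritParams sphereExclusionSplit
#' @param targetTrainFraction desired train share in (0, 1].
#' @param tolerance acceptable deviation from the target size (count).
#' @param maxSteps bisection step budget (default 60).
#' @return List with `radius`, `trainSize`, `converged`, and the
#'   [SplitResult-class] under `split`.
#' @export
tuneRadius <- function(table, targetTrainFraction, tolerance = 3L,
                       columns = NULL, maxSteps = 60L) {
  stopifnot(targetTrainFraction > 0, targetTrainFraction <= 1)
  X <- .descriptorMatrix(table, columns)
  n <- nrow(X)
  target <- round(targetTrainFraction * n)
  if (target < 1) stop("target training size below 1")
  sc <- .autoscale(X)
  diameter <- max(stats::dist(sc$X))
  lo <- 1e-6            # radius -> 0: everything train
  hi <- diameter + 1e-6 # radius >= diameter: single training point
  best <- NULL
  for (step in seq_len(maxSteps)) {
    mid <- (lo + hi) / 2
    sp <- sphereExclusionSplit(table, radius = mid, columns = columns)
    size <- length(trainIds(sp))
    if (is.null(best) || abs(size - target) < abs(best$trainSize - target)) {
      best <- list(radius = mid, trainSize = size, split = sp)
    }
    if (abs(size - target) <= tolerance) {
      best <- list(radius = mid, trainSize = size, split = sp)
      break
    }
    if (size > target) lo <- mid else hi <- mid
  }
  best$converged <- abs(best$trainSize - target) <= tolerance
  if (!best$converged) {
    warning(sprintf(
      "radius tuning did not reach the target size (wanted %d +/- %d, got %d)",
      target, tolerance, best$trainSize
    ))
  }
  best
}

#' Select an external prediction set spanning the response range
#'
#' Picks `k` compounds at quantile-spaced positions of the sorted
#' response values, always including the minimum and the maximum, so the
#' external set spans the full %F range. The selection is deterministic;
#' duplicated response values still yield `k` distinct compounds.
#'
#' @param table data.frame with an `id` column.
#' @param targets numeric response values (%F), one per row.
#' @param k external-set size (>= 2, < number of rows).
#' @return Character vector of `k` ids.
#' @export
selectExternalSet <- function(table, targets, k) {
  n <- nrow(table)
  if (k <= 1) stop("external set size k must be at least 2")
  if (k >= n) stop("external set size k must be smaller than the table")
  if (length(targets) != n) stop("one target value per row required")
  ord <- order(targets, seq_len(n)) # stable: ties broken by row index
  pos <- unique(round(seq(1, n, length.out = k)))
  # rounding can merge positions; pad with unused ranks until k reached
  if (length(pos) < k) {
    extra <- setdiff(seq_len(n), pos)
    pos <- sort(c(pos, extra[seq_len(k - length(pos))]))
  }
  as.character(table$id[ord[pos]])
}
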