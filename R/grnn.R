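# General regression neural network: Nadaraya-Watson kernel regression
# with a Gaussian kernel and one isotropic bandwidth sigma, the form
# introduced by Specht. "Training" stores the (autoscaled) cases;
# the only free parameter is sigma.

.scaleApply <- function(X, center, scale) {
  Xs <- sweep(X, 2, center, "-")
  sweep(Xs, 2, scale, "/")
}

# Squared Euclidean distances between rows of A (m x d) and B (n x d).
.cross2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Core prediction for pre-scaled query rows. Numerically stabilized:
# per query, the largest exponent is subtracted before exponentiation,
# so the maximum weight is exactly 1 and the denominator never
# underflows to zero.
.grnnKernelPredict <- function(Xs, y, Qs, sigma) {
  E <- -.cross2(Qs, Xs) / (2 * sigma^2)
  E <- E - apply(E, 1, max)
  W <- exp(E)
  den <- rowSums(W)
  stopifnot(all(den > 0)) # guaranteed: max exponent is 0
  as.vector(W %*% y) / den
}

#' Predict %F with a GRNN model
#'
#' The prediction is the Gaussian-kernel weighted mean of the stored
#' training targets, i.e. a convex combination of them: it always lies
#' between min and max of the training %F. As sigma tends to 0 the
#' model interpolates the nearest training case exactly; as sigma tends
#' to infinity every prediction tends to the training mean.
#'
#' @param model a [GRNNModel-class].
#' @param x numeric descriptor vector in the model's column order (raw,
#'   unscaled units).
#' @return Predicted %F (clamped to [0, 100] when the model clips).
#' @export
grnnPredict <- function(model, x) {
  stopifnot(is(model, "GRNNModel"))
  x <- as.numeric(x)
  if (length(x) != ncol(model@trainX)) {
    stop("query length ", length(x), " does not match the ",
         ncol(model@trainX), " model descriptors")
  }
  if (!all(is.finite(x))) stop("query vector must be finite")
  q <- .scaleApply(matrix(x, nrow = 1), model@center, model@scale)
  yhat <- .grnnKernelPredict(model@trainX, model@trainY, q, model@sigma)
  if (model@clip) yhat <- pmin(100, pmax(0, yhat))
  yhat
}

#' @rdname grnnPredict
#' @param table data.frame carrying the model's descriptor columns (and
#'   optionally `id` and an `F` column of observed values).
#' @return `grnnPredictBatch`: data.frame with `id`, `predicted`, and
#'   `actual` when observed values are present.
#' @export
grnnPredictBatch <- function(model, table) {
  stopifnot(is(model, "GRNNModel"))
  missing <- setdiff(model@columns, names(table))
  if (length(missing)) {
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(table[, model@columns, drop = FALSE])
  if (anyNA(X)) stop("descriptor table contains NA cells")
  Qs <- .scaleApply(X, model@center, model@scale)
  yhat <- .grnnKernelPredict(model@trainX, model@trainY, Qs, model@sigma)
  if (model@clip) yhat <- pmin(100, pmax(0, yhat))
  out <- data.frame(
    id = if (!is.null(table$id)) as.character(table$id) else
      as.character(seq_len(nrow(X))),
    predicted = yhat,
    stringsAsFactors = FALSE
  )
  if (!is.null(table$F)) out$actual <- table$F
  out
}

.rmse <- function(a, b) sqrt(mean((a - b)^2))

# Test-set RMSE of a candidate sigma (model refitted in place).
.sigmaObjective <- function(Xs, y, XsTest, yTest, sigma) {
  .rmse(yTest, .grnnKernelPredict(Xs, y, XsTest, sigma))
}

# Leave-one-out RMSE on the training set (fallback when no test set).
.sigmaLOO <- function(Xs, y, sigma) {
  n <- nrow(Xs)
  E <- -.cross2(Xs, Xs) / (2 * sigma^2)
  diag(E) <- -Inf # exclude self
  E <- E - apply(E, 1, max)
  W <- exp(E)
  yhat <- as.vector(W %*% y) / rowSums(W)
  .rmse(y, yhat)
}

#' Fit a GRNN: bandwidth selection monitored on the test set
#'
#' Autoscaling (zero mean / unit SD) is fitted on the training rows
#' only, so no information leaks from test or external data. The single
#' isotropic bandwidth sigma is chosen to minimize test-set RMSE by
#' golden-section search over log10(sigma) in [-3, 2], refined to 1e-3
#' relative; the search trace (sigma, train RMSE, test RMSE per
#' evaluation) is stored in the model. With an empty/NULL test table,
#' sigma is chosen by leave-one-out RMSE on the training set instead.
#'
#' @param train data.frame of training rows: descriptor columns plus the
#'   target column.
#' @param test data.frame of test rows sharing the same columns, or
#'   `NULL`.
#' @param columns descriptor columns (default: the modeling set of
#'   [descriptorNames()] present in `train`).
#' @param targetColumn name of the %F column (default `"F"`).
#' @param bracket log10(sigma) search interval (default `c(-3, 2)`).
#' @param clip clamp predictions to [0, 100] (default TRUE).
#' @return A [GRNNModel-class].
#' @export
fitGRNN <- function(train, test = NULL, columns = NULL, targetColumn = "F",
                    bracket = c(-3, 2), clip = TRUE) {
  if (is.null(columns)) {
    columns <- intersect(descriptorNames("model"), names(train))
    if (length(columns) == 0) {
      columns <- setdiff(
        names(train)[vapply(train, is.numeric, logical(1))], targetColumn
      )
    }
  }
  if (!targetColumn %in% names(train)) {
    stop("target column '", targetColumn, "' not found in the training table")
  }
  if (nrow(train) == 0) stop("training table is empty")
  X <- as.matrix(train[, columns, drop = FALSE])
  y <- train[[targetColumn]]
  if (anyNA(X) || anyNA(y)) stop("training data contain NA")
  sc <- .autoscale(X)
  Xs <- sc$X

  useTest <- !is.null(test) && nrow(test) > 0
  if (useTest) {
    missing <- setdiff(c(sc$columns, targetColumn), names(test))
    if (length(missing)) {
      stop("test table lacks column(s): ", paste(missing, collapse = ", "))
    }
    XsTest <- .scaleApply(
      as.matrix(test[, sc$columns, drop = FALSE]), sc$center, sc$scale
    )
    yTest <- test[[targetColumn]]
  }

  trace <- data.frame(sigma = numeric(), train_rmse = numeric(),
                      test_rmse = numeric())
  objective <- function(logSigma) {
    sigma <- 10^logSigma
    val <- if (useTest) {
      .sigmaObjective(Xs, y, XsTest, yTest, sigma)
    } else {
      .sigmaLOO(Xs, y, sigma)
    }
    trace[nrow(trace) + 1L, ] <<- c(
      sigma,
      .rmse(y, .grnnKernelPredict(Xs, y, Xs, sigma)),
      val
    )
    val
  }

  # golden-section search over log10(sigma); deterministic
  gr <- (sqrt(5) - 1) / 2
  a <- bracket[1]; b <- bracket[2]
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- objective(c1); fd <- objective(d1)
  while ((b - a) > 1e-3 * max(1, abs(a) + abs(b)) / 2) {
    if (fc < fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- objective(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- objective(d1)
    }
  }
  sigma <- 10^((a + b) / 2)
  objective(log10(sigma))

  new("GRNNModel",
    trainX = Xs, trainY = as.numeric(y), sigma = sigma,
    center = sc$center, scale = sc$scale, columns = sc$columns,
    clip = isTRUE(clip), trace = trace
  )
}

#' Construct a GRNN with a fixed bandwidth
#'
#' Builds a [GRNNModel-class] directly from raw training data and a
#' user-chosen sigma, bypassing bandwidth selection. Useful for
#' studying the kernel-regression limits (interpolation as sigma -> 0,
#' global mean as sigma -> Inf is approached by large sigma).
#'
#' @param X numeric matrix/data.frame of raw training descriptors.
#' @param y numeric training targets.
#' @param sigma kernel bandwidth in autoscaled units (> 0).
#' @param scale autoscale the training matrix (default TRUE); when
#'   FALSE the matrix is used as-is (center 0, scale 1).
#' @param clip clamp predictions to [0, 100] (default FALSE here).
#' @return A [GRNNModel-class].
#' @export
grnnModel <- function(X, y, sigma, scale = TRUE, clip = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (scale) {
    sc <- .autoscale(X)
  } else {
    sc <- list(
      X = X, center = stats::setNames(rep(0, ncol(X)), colnames(X)),
      scale = stats::setNames(rep(1, ncol(X)), colnames(X)),
      columns = colnames(X)
    )
  }
  new("GRNNModel",
    trainX = sc$X, trainY = as.numeric(y), sigma = sigma,
    center = sc$center, scale = sc$scale, columns = sc$columns,
    clip = isTRUE(clip),
    trace = data.frame(sigma = numeric(), train_rmse = numeric(),
                       test_rmse = numeric())
  )
}
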