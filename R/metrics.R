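#' Evaluation statistics for one data split
#'
#' Computes the standard regression report: coefficient of
#' determination R2 = 1 - SS_res/SS_tot, RMSE, MAE, and the sample SD
#' (n-1) of the actual values, plus the squared Pearson correlation for
#' reference (the two R2 conventions differ on held-out data; the
#' coefficient of determination is the headline value here).
#'
#' @param actual numeric observed values.
#' @param predicted numeric predictions of the same length.
#' @param name split label (`"train"`, `"test"`, `"external"`, ...).
#' @return One-row data.frame with columns `split_name`, `r2`,
#'   `pearson_r2`, `rmse`, `mae`, `sd`, `n`. With constant actuals the
#'   R2 values are `NA` with a warning.
#' @examples
#' evaluatePredictions(c(0, 10), c(3, 7), "toy")
#' @export
evaluatePredictions <- function(actual, predicted, name = "split") {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 1) stop("empty input")
  err <- actual - predicted
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  if (length(unique(actual)) < 2) {
    warning("constant actual values: R2 undefined, reported as NA")
    r2 <- NA_real_
    pr2 <- NA_real_
    sdv <- if (length(actual) > 1) 0 else NA_real_
  } else {
    sstot <- sum((actual - mean(actual))^2)
    r2 <- 1 - sum(err^2) / sstot
    pr2 <- suppressWarnings(stats::cor(actual, predicted)^2)
    sdv <- stats::sd(actual)
  }
  data.frame(
    split_name = name, r2 = r2, pearson_r2 = pr2,
    rmse = rmse, mae = mae, sd = sdv, n = length(actual),
    stringsAsFactors = FALSE
  )
}

#' Pairwise Pearson correlation matrix of the descriptors
#'
#' @param table data.frame or matrix; the modeling descriptor columns
#'   of [descriptorNames()] are used when present, otherwise all numeric
#'   columns.
#' @return Symmetric correlation matrix with unit diagonal. Constant
#'   columns give NA rows/columns with a warning.
#' @export
correlationMatrix <- function(table) {
  if (is.data.frame(table)) {
    cols <- intersect(descriptorNames("model"), names(table))
    if (length(cols) == 0) {
      cols <- names(table)[vapply(table, is.numeric, logical(1))]
      cols <- setdiff(cols, c("F", "target"))
    }
    X <- as.matrix(table[, cols, drop = FALSE])
  } else {
    X <- as.matrix(table)
  }
  if (nrow(X) < 3) stop("need at least 3 rows for a correlation matrix")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(
      "constant column(s) reported as NA: ",
      paste(colnames(X)[sds == 0], collapse = ", ")
    )
  }
  suppressWarnings(stats::cor(X))
}
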