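# Bivariate confidence-ellipse absorption classifier in the
# (AlogP, PSA) plane.

#' Fit a confidence ellipse to well-absorbed compounds
#'
#' Under bivariate normality, the squared Mahalanobis distance of a
#' point from the mean is chi-square distributed with 2 degrees of
#' freedom, so the ellipse enclosing a fraction `confidence` of the
#' population has squared-Mahalanobis radius qchisq(confidence, 2)
#' (equal to -2*log(1 - confidence)). The model stores the sample mean
#' and covariance (n-1 denominator) of the supplied points.
#'
#' @param points two-column matrix or data.frame of (AlogP, PSA) pairs
#'   for well-absorbed compounds; at least 3 non-collinear rows.
#' @param confidence coverage level in (0, 1); default 0.95.
#' @return An [EllipseModel-class].
#' @examples
#' set.seed(1)
#' pts <- cbind(rnorm(100, 2.5, 1.5), rnorm(100, 60, 25))
#' fitEllipse(pts)
#' @export
fitEllipse <- function(points, confidence = 0.95) {
  P <- as.matrix(points)
  if (ncol(P) != 2) stop("points must have two columns (AlogP, PSA)")
  if (nrow(P) < 3) stop("need at least 3 points to fit an ellipse")
  stopifnot(confidence > 0, confidence < 1)
  mu <- colMeans(P)
  S <- stats::cov(P)
  if (det(S) <= 1e-12 * prod(diag(S) + 1e-300)) {
    stop("singular covariance: points are (nearly) collinear")
  }
  new("EllipseModel",
    mean = unname(mu), covariance = unname(S),
    threshold = stats::qchisq(confidence, df = 2),
    confidence = confidence
  )
}

#' Classify points with a fitted ellipse
#'
#' A point is `"well"` (well-absorbed) when its squared Mahalanobis
#' distance from the model mean is at most the threshold; the boundary
#' is inclusive. `"poor"` otherwise.
#'
#' @param model an [EllipseModel-class].
#' @param points two-column matrix/data.frame, or a length-2 vector.
#' @return Character vector of `"well"` / `"poor"` labels.
#' @export
ellipseClassify <- function(model, points) {
  stopifnot(is(model, "EllipseModel"))
  P <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  d2 <- stats::mahalanobis(P, model@mean, model@covariance)
  ifelse(d2 <= model@threshold, "well", "poor")
}

#' Misclassification rate of an absorption classifier
#'
#' @param model an [EllipseModel-class] or [TreeModel-class].
#' @param points two-column matrix/data.frame of (AlogP, PSA) pairs.
#' @param labels true classes, `"well"` / `"poor"`.
#' @return Fraction of points whose prediction differs from the label.
#' @export
misclassificationRate <- function(model, points, labels) {
  P <- as.matrix(points)
  if (nrow(P) == 0) stop("empty input")
  if (length(labels) != nrow(P)) stop("one label per point required")
  if (!all(labels %in% c("well", "poor"))) {
    stop("labels must be 'well' or 'poor'")
  }
  pred <- if (is(model, "EllipseModel")) {
    ellipseClassify(model, P)
  } else if (is(model, "TreeModel")) {
    treeClassify(model, P)
  } else {
    stop("unsupported model class: ", class(model))
  }
  mean(pred != labels)
}
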