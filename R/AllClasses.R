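#' @import methods
NULL

#' Molecule: atoms, bonds and preparation state
#'
#' An S4 container for one small molecule. The `atoms` slot is a
#' data.frame with one row per atom and columns `element` (symbol),
#' `mass` (Da), `x`, `y`, `z` (Angstrom, `NA` until prepared), `charge`
#' (Gasteiger partial charge in electrons, `NA` until prepared), `is_h`
#' (logical) and `vdw` (Bondi van der Waals radius, Angstrom). The
#' `bonds` slot has columns `i`, `j` (1-based atom indices), `order`
#' (`"single"`, `"double"`, `"triple"`, `"aromatic"`) and `aromatic`
#' (logical). A molecule is *prepared* when it carries explicit
#' hydrogens, finite 3D coordinates and partial charges; all geometry
#' and charge descriptors require a prepared molecule.
#'
#' Crippen logP (`alogp`) and Ertl topological polar surface area
#' (`psa`) are computed at parse time from the molecular graph and
#' stored in their own slots.
#'
#' @slot id character molecule identifier.
#' @slot atoms data.frame of per-atom properties (see Description).
#' @slot bonds data.frame of bonds (see Description).
#' @slot prepared logical preparation flag.
#' @slot source character the original record text (SMILES string or
#'   SDF block) the molecule was read from; used to re-derive geometry.
#' @slot sourceFormat character `"smiles"` or `"sdf"`.
#' @slot alogp numeric Crippen logP.
#' @slot psa numeric topological polar surface area (Angstrom^2).
#' @exportClass Molecule
setClass("Molecule", representation(
  id = "character",
  atoms = "data.frame",
  bonds = "data.frame",
  prepared = "logical",
  source = "character",
  sourceFormat = "character",
  alogp = "numeric",
  psa = "numeric"
))

setValidity("Molecule", function(object) {
  msgs <- character()
  at <- object@atoms
  bd <- object@bonds
  need <- c("element", "mass", "x", "y", "z", "charge", "is_h", "vdw")
  if (!all(need %in% names(at))) {
    return(paste("atoms data.frame must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(at) > 0 && any(!is.na(at$mass) & at$mass <= 0)) {
    msgs <- c(msgs, "atomic masses must be positive")
  }
  if (nrow(at) > 0 && any(!is.na(at$vdw) & at$vdw <= 0)) {
    msgs <- c(msgs, "van der Waals radii must be positive")
  }
  if (nrow(bd) > 0) {
    if (any(bd$i == bd$j)) msgs <- c(msgs, "a bond may not join an atom to itself")
    if (any(bd$i < 1 | bd$i > nrow(at) | bd$j < 1 | bd$j > nrow(at))) {
      msgs <- c(msgs, "bond indices out of range")
    }
  }
  if (isTRUE(object@prepared)) {
    if (nrow(at) == 0) msgs <- c(msgs, "a prepared molecule must have atoms")
    if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
      msgs <- c(msgs, "prepared molecule has non-finite coordinates")
    }
    if (any(is.na(at$charge))) {
      msgs <- c(msgs, "prepared molecule has missing partial charges")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Sphere-exclusion split of a descriptor table
#'
#' Holds the disjoint train/test/external id partitions produced by
#' [sphereExclusionSplit()] together with the exclusion radius and the
#' autoscaling parameters (per-column mean/SD of the training metric
#' space) needed to place new points in the same space.
#'
#' @slot trainIds,testIds,externalIds character id vectors, pairwise
#'   disjoint, jointly covering the input table.
#' @slot radius numeric exclusion radius in autoscaled descriptor units.
#' @slot scaling list with `center`, `scale` and `columns` describing
#'   the autoscaling applied before distances were measured.
#' @exportClass SplitResult
setClass("SplitResult", representation(
  trainIds = "character",
  testIds = "character",
  externalIds = "character",
  radius = "numeric",
  scaling = "list"
))

setValidity("SplitResult", function(object) {
  ids <- c(object@trainIds, object@testIds, object@externalIds)
  if (anyDuplicated(ids)) return("train/test/external id sets overlap")
  if (length(object@radius) != 1 || object@radius <= 0) {
    return("radius must be a single positive number")
  }
  TRUE
})

#' Bivariate confidence-ellipse absorption model
#'
#' A 95% (by default) confidence ellipse fitted to the (AlogP, PSA)
#' coordinates of well-absorbed compounds. A query point is classified
#' well-absorbed when its squared Mahalanobis distance from the mean is
#' at most the chi-square(2 df) quantile at the stated confidence.
#'
#' @slot mean numeric length-2 centre (AlogP, PSA).
#' @slot covariance 2x2 sample covariance (n-1 denominator).
#' @slot threshold numeric squared-Mahalanobis cutoff.
#' @slot confidence numeric confidence level in (0, 1).
#' @exportClass EllipseModel
setClass("EllipseModel", representation(
  mean = "numeric",
  covariance = "matrix",
  threshold = "numeric",
  confidence = "numeric"
))

setValidity("EllipseModel", function(object) {
  if (length(object@mean) != 2) return("mean must have length 2")
  S <- object@covariance
  if (!all(dim(S) == c(2, 2))) return("covariance must be 2x2")
  if (max(abs(S - t(S))) > 1e-8) return("covariance must be symmetric")
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    return("covariance must be positive definite")
  }
  if (abs(object@threshold -
          stats::qchisq(object@confidence, df = 2)) > 1e-6) {
    return("threshold must equal the chi-square(2 df) quantile at `confidence`")
  }
  TRUE
})

#' Single CART decision tree over (AlogP, PSA)
#'
#' A binary classification tree grown by greedy Gini-impurity splits.
#' `nodes` is a recursive list: internal nodes carry `feature`,
#' `threshold`, `left`, `right`; leaves carry `class` (one of the
#' training labels) plus the training counts that reached them.
#'
#' @slot nodes list recursive node structure.
#' @slot features character feature names in training column order.
#' @slot maxDepth,minLeaf numeric hyperparameters used at fit time.
#' @exportClass TreeModel
setClass("TreeModel", representation(
  nodes = "list",
  features = "character",
  maxDepth = "numeric",
  minLeaf = "numeric"
))

#' General regression neural network (Gaussian kernel regression)
#'
#' Specht-style GRNN: the prediction at a query x is the Gaussian-kernel
#' weighted mean of the stored training targets, with a single isotropic
#' bandwidth sigma measured in autoscaled descriptor units. The training
#' matrix is stored autoscaled; `center`/`scale` reproduce the transform
#' for new data.
#'
#' @slot trainX numeric matrix, autoscaled training descriptors.
#' @slot trainY numeric training targets (%F, 0-100).
#' @slot sigma numeric kernel bandwidth (> 0).
#' @slot center,scale numeric per-column scaling parameters (training
#'   set only).
#' @slot columns character descriptor column names, in order.
#' @slot clip logical clamp predictions to [0, 100].
#' @slot trace data.frame bandwidth-selection trace with columns
#'   `sigma`, `train_rmse`, `test_rmse`.
#' @exportClass GRNNModel
setClass("GRNNModel", representation(
  trainX = "matrix",
  trainY = "numeric",
  sigma = "numeric",
  center = "numeric",
  scale = "numeric",
  columns = "character",
  clip = "logical",
  trace = "data.frame"
))

setValidity("GRNNModel", function(object) {
  if (length(object@sigma) != 1 || !is.finite(object@sigma) ||
      object@sigma <= 0) {
    return("sigma must be a single positive number")
  }
  if (nrow(object@trainX) != length(object@trainY)) {
    return("trainX and trainY disagree on the number of cases")
  }
  if (anyNA(object@trainX) || anyNA(object@trainY)) {
    return("training data must be free of NA")
  }
  TRUE
})

setMethod("show", "Molecule", function(object) {
  at <- object@atoms
  cat(sprintf(
    "Molecule '%s': %d atoms (%d heavy), %d bonds, %s\n",
    object@id, nrow(at), sum(!at$is_h), nrow(object@bonds),
    if (object@prepared) "prepared (3D + charges)" else "unprepared"
  ))
  if (is.finite(object@alogp)) {
    cat(sprintf("  AlogP %.3f, PSA %.2f A^2\n", object@alogp, object@psa))
  }
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf(
    "SplitResult: %d train / %d test / %d external (radius %.4g)\n",
    length(object@trainIds), length(object@testIds),
    length(object@externalIds), object@radius
  ))
})

setMethod("show", "EllipseModel", function(object) {
  cat(sprintf(
    "EllipseModel: %.0f%% confidence, centre (%.3f, %.3f), threshold %.4f\n",
    100 * object@confidence, object@mean[1], object@mean[2], object@threshold
  ))
})

setMethod("show", "TreeModel", function(object) {
  cat(sprintf(
    "TreeModel: features [%s], max depth %d, min leaf %d\n",
    paste(object@features, collapse = ", "),
    object@maxDepth, object@minLeaf
  ))
})

setMethod("show", "GRNNModel", function(object) {
  cat(sprintf(
    "GRNNModel: %d training cases x %d descriptors, sigma = %.5g\n",
    nrow(object@trainX), ncol(object@trainX), object@sigma
  ))
})
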