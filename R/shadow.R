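# YZ shadow projection after principal-axis alignment.

# Rotate centred coordinates onto the principal axes of the atomic
# coordinate covariance, axes ordered by decreasing variance (X first).
# Eigenvector sign fixed by making each vector's largest-magnitude
# component positive, so the rotation is unique.
.principalAlign <- function(P) {
  X <- sweep(P, 2, colMeans(P))
  if (nrow(X) == 1) return(X)
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors # columns ordered by decreasing eigenvalue
  for (k in 1:3) {
    imax <- which.max(abs(V[, k]))
    if (V[imax, k] < 0) V[, k] <- -V[, k]
  }
  X %*% V
}

#' YZ shadow area of a prepared molecule
#'
#' The molecule is centred and rotated to the principal axes of its
#' atomic-coordinate covariance (largest variance along X), then every
#' atom is projected onto the YZ plane as a disk of its Bondi van der
#' Waals radius. The shadow area of the disk union is measured by grid
#' rasterization over the disks' bounding rectangle; the normalized
#' shadow (`shdw6`) divides that area by the bounding-rectangle area,
#' giving a shape factor in (0, 1] (a single atom gives pi/4, the circle
#' inscribed in its bounding square).
#'
#' @param m a prepared [Molecule-class].
#' @param grid rasterization cell edge in Angstrom (default 0.1).
#' @return List with `area` (raw shadow, Angstrom^2), `normalized`
#'   (shdw6), and `extents` (bounding-rectangle edge lengths).
#' @export
shadowProjection <- function(m, grid = 0.1) {
  stopifnot(is(m, "Molecule"))
  if (!isPrepared(m)) stop("shadowProjection requires a prepared molecule")
  if (grid <= 0) stop("grid resolution must be positive")
  P <- .coordMatrix(m)
  r <- atoms(m)$vdw
  Y <- .principalAlign(P)[, c(2, 3), drop = FALSE]
  lo <- c(min(Y[, 1] - r), min(Y[, 2] - r))
  hi <- c(max(Y[, 1] + r), max(Y[, 2] + r))
  ext <- hi - lo
  if (any(ext <= 0)) {
    stop("degenerate geometry: YZ bounding rectangle has zero area")
  }
  ny <- max(1L, ceiling(ext[1] / grid))
  nz <- max(1L, ceiling(ext[2] / grid))
  cy <- lo[1] + (seq_len(ny) - 0.5) * grid
  cz <- lo[2] + (seq_len(nz) - 0.5) * grid
  covered <- matrix(FALSE, ny, nz)
  for (a in seq_len(nrow(Y))) {
    iy <- which(abs(cy - Y[a, 1]) <= r[a])
    iz <- which(abs(cz - Y[a, 2]) <= r[a])
    if (!length(iy) || !length(iz)) next
    d2 <- outer((cy[iy] - Y[a, 1])^2, (cz[iz] - Y[a, 2])^2, "+")
    covered[iy, iz] <- covered[iy, iz] | (d2 <= r[a]^2)
  }
  area <- sum(covered) * grid^2
  list(
    area = area,
    normalized = area / prod(ext),
    extents = ext
  )
}
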