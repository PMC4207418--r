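# Solvent-accessible surface area by Shrake-Rupley sphere sampling.

# Deterministic near-uniform unit-sphere points (golden-section spiral).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    x = cos(theta) * sin(phi),
    y = sin(theta) * sin(phi),
    z = cos(phi)
  )
}

.coordMatrix <- function(m) {
  at <- atoms(m)
  cbind(at$x, at$y, at$z)
}

.checkNoCoincident <- function(P, what) {
  if (nrow(P) < 2) return(invisible())
  d <- stats::dist(P)
  if (min(d) < 1e-6) {
    stop("coincident atoms encountered while computing ", what)
  }
  invisible()
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the Bondi van der Waals spheres of a
#' prepared molecule, sampling each enlarged sphere with a fixed
#' deterministic spiral point set. An atom's accessible area is the
#' fraction of its sample points lying outside every other enlarged
#' sphere, times the full sphere area 4*pi*(r + probe)^2.
#'
#' @param m a prepared [Molecule-class].
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param nPoints sphere sample points per atom (>= 100; default 960).
#' @return A list with `per_atom_area` (Angstrom^2, one entry per atom),
#'   `total_area`, `probe_radius` and `n_sphere_points`.
#' @examples
#' \donttest{
#' mol <- prepareMolecule(readMoleculesFromSmiles(c(ethanol = "CCO"))[[1]])
#' s <- computeSASA(mol)
#' s$total_area
#' }
#' @export
computeSASA <- function(m, probe = 1.4, nPoints = 960L) {
  stopifnot(is(m, "Molecule"))
  if (!isPrepared(m)) stop("computeSASA requires a prepared molecule")
  if (probe < 0) stop("probe radius must be >= 0")
  if (nPoints < 100) stop("nPoints must be >= 100")
  P <- .coordMatrix(m)
  .checkNoCoincident(P, "SASA")
  R <- atoms(m)$vdw + probe
  n <- nrow(P)
  S <- .spherePoints(as.integer(nPoints))
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- S * R[i]
    pts <- sweep(pts, 2, P[i, ], "+")
    # candidate occluders: spheres that can reach sphere i at all
    if (n > 1) {
      dd <- sqrt(colSums((t(P) - P[i, ])^2))
      nb <- which(dd < R[i] + R & seq_len(n) != i)
    } else {
      nb <- integer()
    }
    acc <- rep(TRUE, nrow(pts))
    for (j in nb) {
      d2 <- (pts[, 1] - P[j, 1])^2 + (pts[, 2] - P[j, 2])^2 +
        (pts[, 3] - P[j, 3])^2
      acc <- acc & d2 > R[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  list(
    per_atom_area = area,
    total_area = sum(area),
    probe_radius = probe,
    n_sphere_points = as.integer(nPoints)
  )
}
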