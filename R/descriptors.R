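#' Descriptor column names
#'
#' The modeling descriptor set holds the 11 variables fed to the %F
#' regression: single-bond count (`nsb`), aromatic-bond count (`nab`),
#' raw YZ shadow area (`yz_shadow`), cube root of the gravitational
#' index (`grav3`), mean acceptor surface area (`saaa`), oxygen and
#' nitrogen counts and their fractions of the total atom count
#' (`n_oxygen`, `n_nitrogen`, `rel_oxygen`, `rel_nitrogen`), maximum
#' hydrogen partial charge (`max_h_charge`) and the area-weighted
#' acceptor surface charge (`hasa2`). The full set adds the normalized
#' shadow (`shdw6`) and the two absorption-plane variables `alogp` and
#' `psa`.
#'
#' @param which `"model"` (11 columns) or `"all"` (14).
#' @return Character vector of column names.
#' @export
descriptorNames <- function(which = c("model", "all")) {
  which <- match.arg(which)
  model <- c(
    "nsb", "nab", "yz_shadow", "grav3", "saaa",
    "n_oxygen", "n_nitrogen", "rel_oxygen", "rel_nitrogen",
    "max_h_charge", "hasa2"
  )
  if (which == "model") model else c(model, "shdw6", "alogp", "psa")
}

.requirePrepared <- function(m, what) {
  if (!isPrepared(m)) {
    stop(what, " requires a prepared molecule (see prepareMolecule)")
  }
}

#' Bond-count descriptors
#'
#' `countSingleBonds` counts bonds of order single, including bonds to
#' explicit hydrogens (aromatic bonds are never counted, whatever their
#' localized order); `countAromaticBonds` counts bonds flagged aromatic
#' by the toolkit's aromaticity perception.
#'
#' @param m a prepared [Molecule-class].
#' @return Integer count.
#' @export
countSingleBonds <- function(m) {
  .requirePrepared(m, "countSingleBonds")
  b <- bonds(m)
  sum(b$order == "single" & !b$aromatic)
}

#' @rdname countSingleBonds
#' @export
countAromaticBonds <- function(m) {
  .requirePrepared(m, "countAromaticBonds")
  sum(bonds(m)$aromatic)
}

#' Element counts and fractions
#'
#' `countElement` counts atoms of the given element; `relativeCount`
#' divides by the total atom count *including* explicit hydrogens.
#'
#' @param m a prepared [Molecule-class].
#' @param element element symbol, e.g. `"O"` or `"N"`.
#' @return Count, or fraction in [0, 1].
#' @export
countElement <- function(m, element) {
  .requirePrepared(m, "countElement")
  sum(atoms(m)$element == element)
}

#' @rdname countElement
#' @export
relativeCount <- function(m, element) {
  .requirePrepared(m, "relativeCount")
  countElement(m, element) / nrow(atoms(m))
}

#' Maximum hydrogen partial charge
#'
#' The largest Gasteiger partial charge carried by any hydrogen atom
#' (electrons). A molecule without hydrogens yields 0 with a warning.
#'
#' @param m a prepared [Molecule-class] with charges assigned.
#' @return Charge in electrons.
#' @export
maxHydrogenCharge <- function(m) {
  .requirePrepared(m, "maxHydrogenCharge")
  at <- atoms(m)
  if (anyNA(at$charge)) stop("partial charges missing for '", m@id, "'")
  h <- at$charge[at$is_h]
  if (length(h) == 0) {
    warning("molecule '", m@id, "' has no hydrogen atoms; returning 0")
    return(0)
  }
  max(h)
}

#' Gravitational index and its cube root (GRAV-3)
#'
#' The gravitational index sums m_i * m_j / r_ij^2 over all unordered
#' atom pairs (hydrogens included), with masses in Da and distances in
#' Angstrom -- a mass-weighted compactness measure. `grav3` is its cube
#' root, the form used as a size/bulk descriptor.
#' `gravitationalIndexBonded` restricts the sum to bonded pairs; it is
#' exposed for completeness but not part of the modeling set.
#'
#' @param m a prepared [Molecule-class].
#' @return Numeric index (single atoms give 0).
#' @export
gravitationalIndex <- function(m) {
  .requirePrepared(m, "gravitationalIndex")
  P <- .coordMatrix(m)
  n <- nrow(P)
  if (n < 2) return(0)
  mass <- atoms(m)$mass
  d2 <- as.vector(stats::dist(P))^2
  if (min(d2) < 1e-12) stop("coincident atoms in '", m@id, "'")
  mm <- utils::combn(mass, 2, FUN = prod)
  sum(mm / d2)
}

#' @rdname gravitationalIndex
#' @export
grav3 <- function(m) gravitationalIndex(m)^(1 / 3)

#' @rdname gravitationalIndex
#' @export
gravitationalIndexBonded <- function(m) {
  .requirePrepared(m, "gravitationalIndexBonded")
  b <- bonds(m)
  if (nrow(b) == 0) return(0)
  at <- atoms(m)
  P <- .coordMatrix(m)
  d2 <- rowSums((P[b$i, , drop = FALSE] - P[b$j, , drop = FALSE])^2)
  if (min(d2) < 1e-12) stop("coincident atoms in '", m@id, "'")
  sum(at$mass[b$i] * at$mass[b$j] / d2)
}

# Hydrogen-bond acceptor atoms: every N and O, minus an optional
# exclusion list of atom indices (e.g. pyrrole-type nitrogens).
.acceptorIdx <- function(m, exclude = integer()) {
  idx <- which(atoms(m)$element %in% c("N", "O"))
  setdiff(idx, exclude)
}

#' Acceptor surface descriptors: SAAA and HASA-2
#'
#' `saaa` is the mean solvent-accessible surface area over hydrogen-bond
#' acceptor atoms (every N and O by default); a molecule without
#' acceptors yields 0 with a warning. `hasa2` is the area-weighted
#' acceptor surface charge: the sum over acceptor atoms of
#' |q_A| * sqrt(S_A), with q_A the partial charge (e) and S_A the
#' atom's accessible area (Angstrom^2). The absolute value makes the
#' quantity positive for the negatively charged acceptor atoms; the
#' square-root area weighting is one member of the CPSA descriptor
#' family and is isolated here as the package's fixed convention.
#'
#' @param m a prepared [Molecule-class].
#' @param surface a surface report from [computeSASA()] for `m`.
#' @param exclude integer atom indices to drop from the acceptor set.
#' @return Area in Angstrom^2 (`saaa`) or charge-area product in
#'   e * Angstrom (`hasa2`).
#' @export
saaa <- function(m, surface = computeSASA(m), exclude = integer()) {
  acc <- .acceptorIdx(m, exclude)
  if (length(acc) == 0) {
    warning("molecule '", m@id, "' has no acceptor atoms; SAAA = 0")
    return(0)
  }
  mean(surface$per_atom_area[acc])
}

#' @rdname saaa
#' @export
hasa2 <- function(m, surface = computeSASA(m), exclude = integer()) {
  acc <- .acceptorIdx(m, exclude)
  if (length(acc) == 0) return(0)
  q <- atoms(m)$charge[acc]
  if (anyNA(q)) stop("partial charges missing for '", m@id, "'")
  sum(abs(q) * sqrt(surface$per_atom_area[acc]))
}

#' Normalized YZ shadow (SHDW-6)
#'
#' Convenience wrapper around [shadowProjection()] returning only the
#' normalized shadow fraction.
#'
#' @inheritParams shadowProjection
#' @return Fraction in (0, 1].
#' @export
shdw6 <- function(m, grid = 0.1) shadowProjection(m, grid)$normalized

#' AlogP and topological polar surface area
#'
#' Both are computed from the molecular graph by published
#' atomic/fragment contribution schemes (Crippen logP and Ertl TPSA, via
#' the RDKit backend) and cached on the molecule at parse time.
#'
#' @param m a [Molecule-class].
#' @return Numeric value (logP is unitless; PSA in Angstrom^2).
#' @export
alogP <- function(m) {
  stopifnot(is(m, "Molecule"))
  if (!is.finite(m@alogp)) stop("AlogP unavailable for '", m@id, "'")
  m@alogp
}

#' @rdname alogP
#' @export
psa <- function(m) {
  stopifnot(is(m, "Molecule"))
  if (!is.finite(m@psa)) stop("PSA unavailable for '", m@id, "'")
  m@psa
}

#' Compute the full descriptor vector for one molecule
#'
#' Runs every descriptor operation and assembles a one-row data.frame
#' with the columns of `descriptorNames("all")` plus `id`. Deterministic
#' given the molecule and settings.
#'
#' @param m a prepared [Molecule-class].
#' @param probe SASA probe radius (Angstrom).
#' @param nPoints SASA sphere points per atom.
#' @param grid shadow rasterization cell edge (Angstrom).
#' @param excludeAcceptors atom indices excluded from the acceptor set.
#' @return One-row data.frame.
#' @export
computeDescriptors <- function(m, probe = 1.4, nPoints = 960L, grid = 0.1,
                               excludeAcceptors = integer()) {
  .requirePrepared(m, "computeDescriptors")
  out <- try({
    surface <- computeSASA(m, probe = probe, nPoints = nPoints)
    shadow <- shadowProjection(m, grid = grid)
    data.frame(
      id = m@id,
      nsb = countSingleBonds(m),
      nab = countAromaticBonds(m),
      yz_shadow = shadow$area,
      grav3 = grav3(m),
      saaa = saaa(m, surface, exclude = excludeAcceptors),
      n_oxygen = countElement(m, "O"),
      n_nitrogen = countElement(m, "N"),
      rel_oxygen = relativeCount(m, "O"),
      rel_nitrogen = relativeCount(m, "N"),
      max_h_charge = maxHydrogenCharge(m),
      hasa2 = hasa2(m, surface, exclude = excludeAcceptors),
      shdw6 = shadow$normalized,
      alogp = alogP(m),
      psa = psa(m),
      stringsAsFactors = FALSE
    )
  }, silent = TRUE)
  if (inherits(out, "try-error")) {
    stop("descriptor computation failed for molecule '", m@id, "': ",
         attr(out, "condition")$message)
  }
  out
}

#' @rdname computeDescriptors
#' @param mols list of prepared [Molecule-class] objects.
#' @export
computeDescriptorTable <- function(mols, probe = 1.4, nPoints = 960L,
                                   grid = 0.1, excludeAcceptors = integer()) {
  rows <- lapply(mols, computeDescriptors,
    probe = probe, nPoints = nPoints,
    grid = grid, excludeAcceptors = excludeAcceptors
  )
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
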