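# Shared fixtures, built once per test run. Molecule preparation goes
# through the chemistry backend, so it is cached here.

.fixtureCache <- new.env(parent = emptyenv())

preparedFixtures <- function() {
  if (is.null(.fixtureCache$mols)) {
    .fixtureCache$mols <- fixtureMolecules(prepare = TRUE, seed = 7L)
  }
  .fixtureCache$mols
}

fixtureDescriptorTable <- function() {
  if (is.null(.fixtureCache$desc)) {
    mols <- preparedFixtures()
    # drop the hydrogen-free / acceptor-free edge cases that warn
    .fixtureCache$desc <- suppressWarnings(computeDescriptorTable(mols))
  }
  .fixtureCache$desc
}

# Build a bare Molecule object from explicit coordinates; used by the
# geometry unit tests so they do not depend on the backend.
toyMolecule <- function(elements, coords, charges = NULL,
                        bonds = NULL, id = "toy", masses = NULL) {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  n <- length(elements)
  if (is.null(masses)) {
    masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)[elements]
  }
  at <- data.frame(
    element = elements, mass = unname(masses),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = if (is.null(charges)) rep(0, n) else charges,
    is_h = elements == "H",
    vdw = vdwRadius(elements),
    stringsAsFactors = FALSE
  )
  bd <- if (is.null(bonds)) {
    data.frame(i = integer(), j = integer(), order = character(),
               aromatic = logical(), stringsAsFactors = FALSE)
  } else {
    data.frame(i = bonds[, 1], j = bonds[, 2],
               order = rep("single", nrow(bonds)),
               aromatic = rep(FALSE, nrow(bonds)), stringsAsFactors = FALSE)
  }
  new("Molecule",
    id = id, atoms = at, bonds = bd, prepared = TRUE,
    source = "", sourceFormat = "smiles",
    alogp = NA_real_, psa = NA_real_
  )
}

aspirinMolBlock <- function() {
  paste(c(
    "aspirin",
    "     RDKit          2D",
    "",
    " 13 13  0  0  0  0  0  0  0  0999 V2000",
    "   -3.8123   -1.2868    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -2.6987   -0.2818    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -3.0122    1.1850    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.2716   -0.7438    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.1580    0.2612    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.4715    1.7281    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6420    2.7330    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0691    2.2711    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.3827    0.8043    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.2691   -0.2007    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5826   -1.6676    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.0097   -2.1295    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.4690   -2.6725    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  2  3  2  0",
    "  2  4  1  0",
    "  4  5  1  0",
    "  5  6  2  0",
    "  6  7  1  0",
    "  7  8  2  0",
    "  8  9  1  0",
    "  9 10  2  0",
    " 10 11  1  0",
    " 11 12  2  0",
    " 11 13  1  0",
    " 10  5  1  0",
    "M  END",
    "$$$$"
  ), collapse = "\n")
}
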