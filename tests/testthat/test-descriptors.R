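# Brute-force oracles kept deliberately naive and separate from the
# implementation paths they check.

bruteGravitationalIndex <- function(m) {
  at <- atoms(m)
  g <- 0
  for (i in seq_len(nrow(at) - 1)) {
    for (j in seq(i + 1, nrow(at))) {
      r2 <- (at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
        (at$z[i] - at$z[j])^2
      g <- g + at$mass[i] * at$mass[j] / r2
    }
  }
  g
}

test_that("bond and element counts match hand enumeration", {
  mols <- preparedFixtures()
  # (nsb, nab) per molecule, hydrogens explicit
  expect_equal(countSingleBonds(mols$methane), 4)
  expect_equal(countSingleBonds(mols$ethanol), 8)
  expect_equal(countSingleBonds(mols$benzene), 6) # the six C-H bonds
  expect_equal(countAromaticBonds(mols$ethane), 0)
  expect_equal(countAromaticBonds(mols$benzene), 6)
  expect_equal(countAromaticBonds(mols$naphthalene), 11)
  # aspirin C9H8O4
  expect_equal(countElement(mols$aspirin, "O"), 4)
  expect_equal(relativeCount(mols$aspirin, "O"), 4 / 21, tolerance = 1e-12)
  expect_equal(countElement(mols$benzene, "N"), 0)
  expect_equal(relativeCount(mols$benzene, "N"), 0)
  # caffeine C8H10N4O2
  expect_equal(countElement(mols$caffeine, "N"), 4)
  expect_equal(relativeCount(mols$caffeine, "N"), 4 / 24, tolerance = 1e-12)
})

test_that("counts are invariant under atom-order permutation", {
  # same molecule written with different atom orderings
  a <- prepareMolecule(readMoleculesFromSmiles(c(x = "OCC"))[[1]])
  b <- prepareMolecule(readMoleculesFromSmiles(c(x = "CCO"))[[1]])
  expect_equal(countSingleBonds(a), countSingleBonds(b))
  expect_equal(countElement(a, "O"), countElement(b, "O"))
  expect_equal(relativeCount(a, "O"), relativeCount(b, "O"))
})

test_that("maximum hydrogen charge picks the most acidic hydrogen", {
  m <- toyMolecule(
    c("O", "H", "H", "H"),
    c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1),
    charges = c(-0.4, 0.031, 0.052, 0.047)
  )
  expect_equal(maxHydrogenCharge(m), 0.052)
  # ethanol: the hydroxyl hydrogen carries the maximum
  eth <- preparedFixtures()$ethanol
  at <- atoms(eth)
  oIdx <- which(at$element == "O")
  bd <- bonds(eth)
  nb <- setdiff(c(bd$i[bd$j == oIdx], bd$j[bd$i == oIdx]), oIdx)
  ohH <- nb[at$is_h[nb]]
  expect_equal(maxHydrogenCharge(eth), at$charge[ohH])
  # no hydrogens at all -> 0 with a warning
  cf4 <- preparedFixtures()$tetrafluoromethane
  expect_warning(v <- maxHydrogenCharge(cf4), "no hydrogen")
  expect_equal(v, 0)
})

test_that("gravitational index: closed form, limits and brute force", {
  single <- toyMolecule("C", c(0, 0, 0))
  expect_equal(gravitationalIndex(single), 0)
  # two atoms of mass 12 at the C-C bond distance
  pair <- toyMolecule(c("C", "C"), c(0, 0, 0, 1.54, 0, 0),
                      masses = c(12, 12), bonds = cbind(1, 2))
  expect_equal(gravitationalIndex(pair), 144 / 1.54^2, tolerance = 1e-12)
  expect_equal(grav3(pair), (144 / 1.54^2)^(1 / 3), tolerance = 1e-12)
  # full molecules against the double-loop oracle
  for (m in preparedFixtures()[c("ethanol", "benzene", "aspirin", "caffeine")]) {
    expect_equal(gravitationalIndex(m), bruteGravitationalIndex(m),
                 tolerance = 1e-9)
  }
  # coincident atoms are an error
  bad <- toyMolecule(c("C", "C"), c(0, 0, 0, 0, 0, 0))
  expect_error(gravitationalIndex(bad), "coincident")
})

test_that("bonded-pairs gravitational variant only sums over bonds", {
  tri <- toyMolecule(
    c("C", "C", "C"), c(0, 0, 0, 1.5, 0, 0, 3, 0, 0),
    bonds = rbind(c(1, 2), c(2, 3))
  )
  m <- atoms(tri)$mass[1]
  expect_equal(gravitationalIndexBonded(tri), 2 * m^2 / 1.5^2,
               tolerance = 1e-12)
  expect_true(gravitationalIndex(tri) > gravitationalIndexBonded(tri))
})

test_that("SASA: analytic sphere, additivity and grid convergence", {
  o <- toyMolecule("O", c(0, 0, 0))
  s <- computeSASA(o, probe = 1.4)
  expect_equal(s$total_area, 4 * pi * (1.52 + 1.4)^2, tolerance = 0.01)
  # two far-separated atoms: areas add
  oo <- toyMolecule(c("O", "O"), c(0, 0, 0, 50, 0, 0))
  s2 <- computeSASA(oo, probe = 1.4)
  expect_equal(s2$total_area, 2 * 4 * pi * (1.52 + 1.4)^2, tolerance = 0.01)
  expect_equal(s2$total_area, sum(s2$per_atom_area))
  expect_true(all(s2$per_atom_area >= 0))
  # doubling the point count barely moves the answer
  eth <- preparedFixtures()$ethanol
  a1 <- computeSASA(eth, nPoints = 960L)$total_area
  a2 <- computeSASA(eth, nPoints = 1920L)$total_area
  expect_lt(abs(a1 - a2) / a1, 0.005)
})

test_that("SAAA averages acceptor areas; acceptor-free molecules warn", {
  o <- toyMolecule("O", c(0, 0, 0))
  s <- computeSASA(o, probe = 1.4)
  expect_equal(saaa(o, s), s$total_area) # one acceptor owns the sphere
  hex <- preparedFixtures()$hexane
  expect_warning(v <- saaa(hex, computeSASA(hex)), "no acceptor")
  expect_equal(v, 0)
  # two acceptors with known areas -> plain mean
  m <- toyMolecule(c("N", "O"), c(0, 0, 0, 50, 0, 0))
  fake <- list(per_atom_area = c(10, 20), total_area = 30,
               probe_radius = 1.4, n_sphere_points = 960L)
  expect_equal(saaa(m, fake), 15)
})

test_that("HASA-2 is the |q|*sqrt(S) sum over acceptors", {
  hex <- preparedFixtures()$hexane
  expect_equal(hasa2(hex, computeSASA(hex)), 0)
  one <- toyMolecule("O", c(0, 0, 0), charges = -0.40)
  fake1 <- list(per_atom_area = 107.13, total_area = 107.13,
                probe_radius = 1.4, n_sphere_points = 960L)
  expect_equal(hasa2(one, fake1), 0.40 * sqrt(107.13), tolerance = 1e-12)
  two <- toyMolecule(c("N", "O", "C"),
                     c(0, 0, 0, 10, 0, 0, 20, 0, 0),
                     charges = c(-0.3, -0.5, 0.1))
  fake2 <- list(per_atom_area = c(25, 16, 99), total_area = 140,
                probe_radius = 1.4, n_sphere_points = 960L)
  expect_equal(hasa2(two, fake2), 0.3 * 5 + 0.5 * 4, tolerance = 1e-12)
})

test_that("shadow: single atom gives pi/4; coincident atoms unchanged", {
  o <- toyMolecule("O", c(0, 0, 0))
  sh <- shadowProjection(o, grid = 0.05)
  expect_equal(sh$normalized, pi / 4, tolerance = 0.01)
  expect_equal(sh$area, pi * 1.52^2, tolerance = 0.02 * pi * 1.52^2)
})

test_that("shadow is invariant under translation and axis permutation", {
  m <- preparedFixtures()$aspirin
  base <- shadowProjection(m)
  shift <- m
  shift@atoms$x <- shift@atoms$x + 13.7
  shift@atoms$y <- shift@atoms$y - 4.2
  shift@atoms$z <- shift@atoms$z + 0.9
  moved <- shadowProjection(shift)
  expect_equal(moved$area, base$area, tolerance = 0.01)
  perm <- m
  perm@atoms[, c("x", "y", "z")] <- m@atoms[, c("z", "x", "y")]
  swapped <- shadowProjection(perm)
  expect_equal(swapped$area, base$area, tolerance = 0.01)
  expect_equal(swapped$normalized, base$normalized, tolerance = 0.01)
})

test_that("shadow area agrees with a Monte-Carlo disk-union oracle", {
  skip_if_not_installed("withr")
  for (nm in c("ethanol", "benzene", "caffeine")) {
    m <- preparedFixtures()[[nm]]
    sh <- shadowProjection(m, grid = 0.05)
    # oracle: rejection sampling over the same aligned disks
    at <- atoms(m)
    P <- cbind(at$x, at$y, at$z)
    Y <- BioavailQSPR:::.principalAlign(P)[, 2:3, drop = FALSE]
    r <- at$vdw
    lo <- c(min(Y[, 1] - r), min(Y[, 2] - r))
    hi <- c(max(Y[, 1] + r), max(Y[, 2] + r))
    mc <- withr::with_seed(42, {
      ns <- 2e5
      py <- runif(ns, lo[1], hi[1])
      pz <- runif(ns, lo[2], hi[2])
      inside <- rep(FALSE, ns)
      for (a in seq_len(nrow(Y))) {
        inside <- inside | ((py - Y[a, 1])^2 + (pz - Y[a, 2])^2 <= r[a]^2)
      }
      mean(inside) * prod(hi - lo)
    })
    expect_equal(sh$area, mc, tolerance = 0.02)
  }
})

test_that("AlogP and PSA follow the published contribution schemes", {
  mols <- preparedFixtures()
  expect_equal(psa(mols$benzene), 0)
  expect_equal(psa(mols$ethanol), 20.23, tolerance = 1e-9)
  # logP grows monotonically along the alkane series C2..C10
  alk <- readMoleculesFromSmiles(stats::setNames(
    vapply(2:10, function(k) paste(rep("C", k), collapse = ""), character(1)),
    paste0("C", 2:10)
  ))
  lp <- vapply(alk, alogP, numeric(1))
  expect_true(all(diff(lp) > 0))
  expect_true(all(lp[-1] > 0))
})

test_that("computeDescriptors is total, finite and deterministic", {
  tab <- fixtureDescriptorTable()
  expect_equal(nrow(tab), length(preparedFixtures()))
  num <- tab[, setdiff(names(tab), "id")]
  expect_true(all(vapply(num, function(x) all(is.finite(x)), logical(1))))
  expect_true(all(tab$shdw6 > 0 & tab$shdw6 <= 1))
  expect_true(all(tab$saaa >= 0 & tab$psa >= 0 & tab$grav3 >= 0))
  expect_true(all(tab$rel_oxygen <= 1 & tab$rel_nitrogen <= 1))
  again <- suppressWarnings(computeDescriptors(preparedFixtures()$benzene))
  expect_equal(again, tab[tab$id == "benzene", ], ignore_attr = TRUE)
})
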