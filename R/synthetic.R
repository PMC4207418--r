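# Synthetic study data: fixture molecules, descriptor tables emulating
# a drug-like compound collection, and labeled (AlogP, PSA) clouds.

# Run expr with a private RNG stream; the caller's RNG state is
# untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Built-in fixture molecules
#'
#' A small in-package collection of drug and drug-like SMILES spanning
#' every descriptor code path: toy molecules (methane, ethane, ethanol,
#' benzene, naphthalene), an alkane and a cycloalkane with no N/O
#' acceptors, a perfluorinated molecule with no hydrogens, heteroaromatic
#' rings, and a set of marketed drugs (aspirin, caffeine, ibuprofen,
#' paracetamol, atenolol, propranolol, diazepam, warfarin, ...).
#'
#' @param prepare also run [prepareMolecules()] (default FALSE).
#' @param seed embedding seed used when `prepare = TRUE`.
#' @return `fixtureSmiles()`: a named character vector of SMILES;
#'   `fixtureMolecules()`: a named list of [Molecule-class] objects.
#' @export
fixtureSmiles <- function() {
  c(
    methane = "C",
    ethane = "CC",
    ethanol = "CCO",
    benzene = "c1ccccc1",
    naphthalene = "c1ccc2ccccc2c1",
    hexane = "CCCCCC",
    cyclohexane = "C1CCCCC1",
    tetrafluoromethane = "FC(F)(F)F",
    pyridine = "c1ccncc1",
    aniline = "Nc1ccccc1",
    phenol = "Oc1ccccc1",
    toluene = "Cc1ccccc1",
    acetic_acid = "CC(=O)O",
    imidazole = "c1c[nH]cn1",
    nicotine = "CN1CCCC1c1cccnc1",
    glucose = "OCC1OC(O)C(O)C(O)C1O",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    diazepam = "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O"
  )
}

#' @rdname fixtureSmiles
#' @export
fixtureMolecules <- function(prepare = FALSE, seed = 7L) {
  mols <- readMoleculesFromSmiles(fixtureSmiles())
  if (prepare) mols <- prepareMolecules(mols, seed = seed)
  mols
}

#' Default per-descriptor simulation ranges
#'
#' The (min, max) range of each of the 11 modeling descriptors over a
#' drug-like compound collection of kinase/protease inhibitors and GPCR
#' antagonists; counts are integer-valued.
#'
#' @return Named list of length-2 numeric vectors.
#' @export
defaultDescriptorRanges <- function() {
  list(
    nsb = c(26, 90),
    nab = c(0, 12),
    yz_shadow = c(29.9, 110.46),
    grav3 = c(25.97, 42.16),
    saaa = c(28.38, 32.14),
    n_oxygen = c(0, 7),
    n_nitrogen = c(1, 8),
    rel_oxygen = c(0, 0.12),
    rel_nitrogen = c(0.02, 0.17),
    max_h_charge = c(0.03, 0.1),
    hasa2 = c(2.89, 32.2)
  )
}

# Standardize x drawn from U(a, b) using the theoretical uniform
# moments, so the %F generating function has fixed, data-independent
# coefficients.
.zUnif <- function(x, range) {
  (x - mean(range)) / (diff(range) / sqrt(12))
}

# Factor loadings tying each descriptor to the two latent compound
# factors (size and polarity) through a Gaussian copula. Real
# descriptor sets are strongly intercorrelated (size measures with each
# other, oxygen counts with oxygen fractions); the copula reproduces
# that while leaving every marginal exactly uniform on its range.
.SYNTH_LOADINGS <- list(
  size = c(nsb = 0.78, nab = 0.58, yz_shadow = 0.78, grav3 = 0.90),
  polarity = c(saaa = 0.52, n_nitrogen = 0.58, n_oxygen = 0.70,
               max_h_charge = 0.65, hasa2 = 0.85)
)

# Latent %F signal: smooth, partly non-additive function of GRAV-3,
# HASA-2, NSB and SAAA (standardized by their theoretical uniform
# moments). Coefficients are fixed implementation constants.
.synthLatent <- function(tab, ranges) {
  zg <- .zUnif(tab$grav3, ranges$grav3)
  zh <- .zUnif(tab$hasa2, ranges$hasa2)
  zn <- .zUnif(tab$nsb, ranges$nsb)
  zs <- .zUnif(tab$saaa, ranges$saaa)
  0.6 * zg - 0.5 * zh + 1.2 * zn * zh + 1.0 * sin(1.3 * zs)
}

#' Simulate a descriptor table with a %F response
#'
#' Draws `n` synthetic compounds. Each descriptor is uniform on its
#' range (counts on their integer ranges), but the columns are
#' correlated through a Gaussian copula with two latent factors -- a
#' size factor loading on the bond counts, shadow area and GRAV-3, and
#' a polarity factor loading on the N/O counts, acceptor surface and
#' charge descriptors -- mirroring the strong intercorrelations of real
#' descriptor tables. The element fractions are derived from the counts
#' and a plausible total atom count, so every row satisfies the
#' descriptor invariants.
#'
#' The %F response is a fixed saturating logistic in a smooth latent
#' function of GRAV-3, HASA-2, NSB and SAAA containing an interaction
#' and a non-monotone term (structure a nonlinear learner can recover
#' but linear least squares cannot), plus Gaussian noise, clamped to
#' [0, 100]. The logistic offset sits at the (1 - `highBias`) quantile
#' of the latent signal, so about `highBias` of the compounds are well
#' absorbed (%F > 50) -- a collection biased toward high %F values.
#'
#' @param n number of compounds (default 217).
#' @param seed RNG seed; tables are exactly reproducible.
#' @param highBias target fraction of compounds with %F > 50.
#' @param noiseSd Gaussian noise SD in %F units (default 5).
#' @param ranges per-descriptor ranges, as [defaultDescriptorRanges()].
#' @return data.frame with `id`, the 11 modeling descriptor columns and
#'   the response column `F`.
#' @examples
#' tab <- simulateDescriptorTable(n = 20, seed = 1)
#' summary(tab$F)
#' @export
simulateDescriptorTable <- function(n = 217L, seed = 7L, highBias = 0.7,
                                    noiseSd = 5, ranges = defaultDescriptorRanges()) {
  stopifnot(n >= 2, highBias > 0, highBias < 1, noiseSd >= 0)
  stopifnot(all(vapply(ranges, function(r) r[1] < r[2], logical(1))))
  .withSeed(seed, {
    f_size <- stats::rnorm(n)
    f_pol <- stats::rnorm(n)
    lam <- c(.SYNTH_LOADINGS$size, .SYNTH_LOADINGS$polarity)
    factorOf <- function(nm) {
      if (nm %in% names(.SYNTH_LOADINGS$size)) f_size else f_pol
    }
    # copula: correlated latent normal -> uniform(0,1) -> target range
    u <- function(nm) {
      l <- lam[[nm]]
      stats::pnorm(l * factorOf(nm) + sqrt(1 - l^2) * stats::rnorm(n))
    }
    qu <- function(p, r) r[1] + p * (r[2] - r[1])
    qi <- function(p, lo, hi) lo + pmin(floor(p * (hi - lo + 1)), hi - lo)

    nsb <- qi(u("nsb"), ranges$nsb[1], ranges$nsb[2])
    nab <- qi(u("nab"), ranges$nab[1], ranges$nab[2])
    n_nitrogen <- qi(u("n_nitrogen"), ranges$n_nitrogen[1], ranges$n_nitrogen[2])
    # total atom count window keeping both element fractions in range
    t_hi <- pmin(160, floor(n_nitrogen / ranges$rel_nitrogen[1]))
    o_max <- pmin(ranges$n_oxygen[2], floor(ranges$rel_oxygen[2] * t_hi))
    n_oxygen <- pmin(
      qi(u("n_oxygen"), ranges$n_oxygen[1], ranges$n_oxygen[2]), o_max
    )
    t_lo <- pmax(
      30,
      ceiling(n_nitrogen / ranges$rel_nitrogen[2]),
      ceiling(ifelse(n_oxygen > 0, n_oxygen / ranges$rel_oxygen[2], 0))
    )
    t_lo <- pmin(t_lo, t_hi)
    n_atoms <- t_lo + floor(stats::runif(n) * (t_hi - t_lo + 1))

    tab <- data.frame(
      id = sprintf("synth_%03d", seq_len(n)),
      nsb = nsb, nab = nab,
      yz_shadow = qu(u("yz_shadow"), ranges$yz_shadow),
      grav3 = qu(u("grav3"), ranges$grav3),
      saaa = qu(u("saaa"), ranges$saaa),
      n_oxygen = n_oxygen, n_nitrogen = n_nitrogen,
      rel_oxygen = n_oxygen / n_atoms,
      rel_nitrogen = n_nitrogen / n_atoms,
      max_h_charge = qu(u("max_h_charge"), ranges$max_h_charge),
      hasa2 = qu(u("hasa2"), ranges$hasa2),
      stringsAsFactors = FALSE
    )

    s <- .synthLatent(tab, ranges)
    offset <- stats::quantile(s, 1 - highBias, names = FALSE)
    f0 <- 100 * stats::plogis(0.45 * (s - offset))
    tab$F <- pmin(100, pmax(0, f0 + stats::rnorm(n, 0, noiseSd)))
    tab
  })
}

# The noise-free generating signal for a simulated table; used by
# calibration checks.
.syntheticSignal <- function(tab, highBias = 0.7,
                             ranges = defaultDescriptorRanges()) {
  s <- .synthLatent(tab, ranges)
  offset <- stats::quantile(s, 1 - highBias, names = FALSE)
  100 * stats::plogis(0.45 * (s - offset))
}

# Draw n rows from a bivariate normal with given means, SDs and
# correlation (Cholesky construction; deterministic given the RNG).
.rmvn2 <- function(n, mean, sd, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  x <- mean[1] + sd[1] * z1
  y <- mean[2] + sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  cbind(x, y)
}

#' Simulate labeled (AlogP, PSA) absorption clouds
#'
#' Well-absorbed compounds are drawn from a bivariate normal centred at
#' AlogP 2.5, PSA 60 A^2 (SDs 1.5 and 25, correlation -0.3): moderately
#' lipophilic, low polar surface area. Poor compounds come from a
#' two-component normal mixture centred at high PSA (overall PSA mean
#' 140 A^2, the poor-permeation regime); the clouds overlap, as real
#' well/poor classes do in this plane.
#'
#' @param nWell,nPoor class sizes (either may be 0).
#' @param seed RNG seed.
#' @param wellMean,wellSd,wellRho well-class parameters.
#' @param poorMeans,poorSds,poorWeights mixture parameters for the poor
#'   class (2 components).
#' @return data.frame with columns `alogp`, `psa`, `class`.
#' @export
simulateAbsorptionClouds <- function(nWell, nPoor, seed = 7L,
                                     wellMean = c(2.5, 60),
                                     wellSd = c(1.5, 25),
                                     wellRho = -0.3,
                                     poorMeans = list(c(1.2, 150), c(4.2, 125)),
                                     poorSds = list(c(1.8, 30), c(1.6, 28)),
                                     poorWeights = c(0.6, 0.4)) {
  stopifnot(nWell >= 0, nPoor >= 0, nWell + nPoor > 0)
  .withSeed(seed, {
    out <- NULL
    if (nWell > 0) {
      W <- .rmvn2(nWell, wellMean, wellSd, wellRho)
      out <- data.frame(alogp = W[, 1], psa = W[, 2], class = "well",
                        stringsAsFactors = FALSE)
    }
    if (nPoor > 0) {
      comp <- sample(seq_along(poorWeights), nPoor,
                     replace = TRUE, prob = poorWeights)
      P <- matrix(NA_real_, nPoor, 2)
      for (k in seq_along(poorWeights)) {
        idx <- which(comp == k)
        if (length(idx)) {
          P[idx, ] <- .rmvn2(length(idx), poorMeans[[k]], poorSds[[k]], 0)
        }
      }
      out <- rbind(out, data.frame(
        alogp = P[, 1], psa = P[, 2], class = "poor",
        stringsAsFactors = FALSE
      ))
    }
    out
  })
}
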