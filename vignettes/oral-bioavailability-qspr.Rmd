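---
title: "Modeling percent oral bioavailability from molecular descriptors"
author: "BioavailQSPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling percent oral bioavailability from molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BioavailQSPR)
```

## The modeling problem

Percent oral bioavailability (%F) is the fraction of an orally
administered dose that reaches systemic circulation, on a 0--100 scale.
Measuring it requires in vivo pharmacokinetics, so structure-based
estimates are attractive early in drug discovery. The quantitative
structure--property relationship (QSPR) approach implemented here has
three stages: represent each molecule by a fixed vector of computed
descriptors, split the compound collection rationally into training,
test and external-validation sets, and map descriptors to %F with a
nonlinear regressor -- a general regression neural network (GRNN),
i.e. Gaussian-kernel regression. Two simpler classifiers in the
(AlogP, PSA) plane -- a bivariate confidence ellipse and a single
decision tree -- serve as absorption baselines; their typically high
misclassification on diverse collections is the motivation for the
richer descriptor set.

## Molecule preparation

All geometry and charge descriptors need explicit hydrogens, one 3D
conformer and partial charges. `prepareMolecule()` delegates to an
RDKit helper: seeded ETKDG distance-geometry embedding followed by
MMFF94 minimization, then Gasteiger--Marsili charges. The embedding is
deterministic in `(molecule, seed)`, so every downstream descriptor is
exactly reproducible; SDF input that already carries 3D coordinates
keeps them. Two conventions are worth stating:

* **Charges.** Semiempirical AM1 charges are the classical choice for
  electronic descriptors, but embedding a quantum-chemistry engine is
  out of scope. The package uses the Gasteiger empirical scheme by
  default and accepts an external per-atom charge table
  (`charges = "file.csv"`) when better charges are available. Gasteiger
  hydrogen charges run systematically higher than AM1 (a hydroxyl
  hydrogen is near +0.21 e rather than +0.1 e), so absolute values of
  `max_h_charge` and `hasa2` are scheme-dependent; within one scheme
  they rank molecules consistently.
* **Conformers.** One minimized conformer per molecule stands in for a
  conformational-ensemble analysis. Descriptors such as the shadow
  area vary by a few percent across low-energy conformers; that
  variability is not modeled.

Protonation states are taken as drawn; tautomer and stereochemistry
enumeration are out of scope.

## The descriptor set

Eleven descriptors form the modeling vector (see
`descriptorNames()`), spanning topology, electronics and geometry:

* `nsb`, `nab` -- counts of single and aromatic bonds. Single bonds
  include bonds to explicit hydrogens (drug-sized molecules then land
  in the 26--90 range typical of such collections); aromatic bonds
  follow the toolkit's default aromaticity perception and are never
  double-counted as single.
* `n_oxygen`, `n_nitrogen`, `rel_oxygen`, `rel_nitrogen` -- element
  counts and their fractions of the *total* atom count including
  hydrogens (the denominator choice that keeps the fractions in the
  conventional 0--0.17 window).
* `max_h_charge` -- the largest partial charge on any hydrogen, a
  hydrogen-bond-donor strength proxy. Hydrogen-free molecules return 0
  with a warning.
* `grav3` -- cube root of the gravitational index
  $G = \sum_{i<j} m_i m_j / r_{ij}^2$ over **all** atom pairs
  (hydrogens included), a mass-weighted compactness measure. A
  bonded-pairs variant is exposed (`gravitationalIndexBonded()`) but
  not used by the pipeline.
* `saaa` -- mean solvent-accessible surface area over hydrogen-bond
  acceptor atoms. Acceptors are defined as every N and O atom; the
  rule is deliberately simple and deterministic, with an optional
  exclusion list (e.g. for pyrrole-type nitrogens) off by default.
* `hasa2` -- area-weighted acceptor surface charge
  $\sum_A |q_A| \sqrt{S_A}$ (e.Å), a charged-partial-surface-area
  (CPSA) descriptor. The CPSA literature contains several
  "area-weighted surface charge" variants; this package fixes the
  $|q|\sqrt{S}$ form, which yields positive values on the conventional
  2.9--32 scale, and isolates it in one function so the convention is
  auditable.
* `yz_shadow` -- area of the molecular projection onto the YZ plane
  after principal-axis alignment, with atoms drawn as van der Waals
  disks. The raw area (tens of Å², the scale on which reference
  collections tabulate "YZ shadow") is the modeling column; the
  normalized variant `shdw6` = area / bounding-rectangle area, a shape
  factor in (0, 1], is computed alongside because a "normalized
  projection" is how the descriptor is defined in the shadow-descriptor
  family. Descriptor tables therefore carry 14 numeric columns: the 11
  modeling descriptors plus `shdw6` and the absorption-plane pair
  `alogp`/`psa`.

`alogp` (Crippen atomic-contribution logP) and `psa` (Ertl topological
polar surface area) come from published contribution schemes via the
RDKit backend; they feed the absorption-plane models, not the GRNN.

### Numerical choices

* **SASA** uses Shrake--Rupley sampling with probe radius 1.4 Å
  (water) and 960 deterministic golden-spiral points per atom, over
  Bondi van der Waals radii shipped as a fixed table. Doubling the
  point count moves totals by well under 0.5%; an isolated atom
  reproduces $4\pi(r+p)^2$ to better than 1%.
* **Shadow** rasterization uses a 0.1 Å grid over the disks' bounding
  rectangle. Principal axes are ordered by decreasing coordinate
  variance, and each eigenvector's sign is fixed by making its
  largest-magnitude component positive, removing the sign ambiguity of
  eigendecompositions; the projection is then invariant to rigid
  motion of the input coordinates.
* Coincident atoms (distance < 1e-6 Å) abort the geometry descriptors
  rather than returning infinities.

## Rational splitting by sphere exclusion

`sphereExclusionSplit()` autoscales the descriptor columns to zero
mean and unit SD (constant columns are dropped from the metric with a
warning) and then grows the training set greedily: the first pick is
the point closest to the data centroid; thereafter the unassigned
point farthest from the current training set joins it, and all
unassigned points within the exclusion radius of the new member are
assigned to the test set, until nothing is left. Ties break on the
lower row index, making the procedure fully deterministic. The variant
matters little for the key property the splitter must deliver --
training points mutually farther apart than the radius, test points
each within the radius of a training point -- and both properties are
asserted on every run by the test suite. `tuneRadius()` bisects the
radius (at most 60 steps) until the training share hits a target such
as 159/209.

The external prediction set is chosen **before** sphere exclusion, at
quantile-spaced positions of the sorted %F values including both
extremes, so it spans the observed bioavailability range; the order of
these two operations is a design choice (the alternative -- carving the
external set out of the post-split pool -- could not guarantee range
coverage).

## Absorption models in the (AlogP, PSA) plane

For the ellipse model, well-absorbed training compounds (%F at or
above the configurable 50% cutoff) are summarized by their sample mean
and covariance; under bivariate normality the squared Mahalanobis
distance is $\chi^2_2$, so the 95% ellipse uses the threshold
$q_{\chi^2_2}(0.95) = -2\ln 0.05 \approx 5.991$. Classification is
boundary-inclusive, an arbitrary but fixed convention. Because
Mahalanobis distance is affine-invariant, the classifier is unchanged
under any consistent affine re-expression of the plane.

The single decision tree is CART with Gini impurity: greedy binary
splits over midpoints of sorted unique feature values, ties broken
toward the lower feature index and threshold, leaves when pure, at
depth 4, or below 5 points per child. These hyperparameters are
deliberately modest -- the model is a baseline, not the product.

The 50% well/poor cutoff is itself a parameter
(`wellThreshold`): absorption-classification conventions in the
literature range from 50% to 90%, and nothing in the method depends on
the choice.

## The GRNN

The GRNN is memory-based kernel regression: with autoscaled training
descriptors $\tilde{x}_i$ and targets $y_i$,

$$\hat{y}(x) = \frac{\sum_i y_i \exp(-\|\tilde{x} -
\tilde{x}_i\|^2 / 2\sigma^2)}{\sum_i \exp(-\|\tilde{x} -
\tilde{x}_i\|^2 / 2\sigma^2)}.$$

Predictions are convex combinations of training targets, so they can
never leave the observed %F range; as $\sigma \to 0$ the model
interpolates its training points and as $\sigma \to \infty$ it returns
the training mean -- both limits are verified to 1e-6 in the tests.
Exponents are stabilized by subtracting the per-query maximum before
exponentiation, so the weight denominator cannot underflow.

A note on architecture: descriptions of GRNN software sometimes quote
a fixed input--hidden--output layer count, but the canonical GRNN has
one pattern unit *per training case* and no trainable hidden layer; a
"3 hidden neurons" reading is not representable in this model class,
and the package implements the canonical form. The single isotropic
$\sigma$ is the only free parameter (per-feature bandwidths exist
behind `grnnModel()`'s scaling switch but are not the default).

$\sigma$ is selected by golden-section search on $\log_{10}\sigma \in
[-3, 2]$, minimizing test-set RMSE (the test set's role is exactly to
monitor overfitting of the bandwidth), refined to 1e-3 relative and
recorded in a selection trace. Scaling parameters come from the
training set alone, and the external set is untouched until final
validation -- the test suite checksums it across the run. With no test
set, leave-one-out RMSE on the training set is the documented
fallback.

## Evaluation conventions

`evaluatePredictions()` reports $R^2 = 1 - SS_{res}/SS_{tot}$ (the
coefficient of determination), RMSE and MAE in %F units, and the
sample SD of the *actual* values. Two conventions need stating: on
held-out data the coefficient of determination and the squared Pearson
correlation differ, so both are emitted with the former as the
headline; and the "standard deviation" column describes the spread of
the observed values in each split (a 0--100 response with a high-end
bias plausibly shows SDs in the 20--40 range), not of the residuals.

## What the synthetic data emulate

The reference compound collection behind this methodology -- some two
hundred kinase/protease inhibitors and GPCR antagonists with measured
%F -- is not publicly deposited, so the package ships a generator used
by the tests and any desk-scale experiment:

* `simulateDescriptorTable()` draws each descriptor uniformly on the
  range such collections report (single bonds 26--90, aromatic bonds
  0--12, YZ shadow 29.9--110.46 Å², GRAV-3 25.97--42.16, SAAA
  28.38--32.14 Å², O atoms 0--7, N atoms 1--8, O fraction 0--0.12, N
  fraction 0.02--0.17, max H charge 0.03--0.1 e, HASA-2 2.89--32.2),
  with element fractions derived from the counts and a plausible total
  atom count so all invariants hold row-wise. Columns are coupled
  through a Gaussian copula with two latent factors -- molecular size
  (bond counts, shadow, GRAV-3) and polarity (N/O counts, charge and
  acceptor-surface terms) -- because real descriptor tables are
  strongly intercorrelated while each marginal stays exactly uniform.
* The %F response is a saturating logistic in a fixed smooth function
  of GRAV-3, HASA-2, NSB and SAAA that contains an interaction and a
  non-monotone term, plus Gaussian noise (SD 5 %F units by default),
  clamped to [0, 100]. The coefficients are implementation constants
  chosen once so that the response has genuinely nonlinear structure:
  a GRNN trained on 800 compounds recovers the signal to within twice
  the noise SD on held-out data, while linear least squares on the
  same columns is at least 1.3 times worse -- reproducing the
  situation in which linear QSPR fails and a kernel method is
  warranted. The logistic offset sits at the (1 - `highBias`) quantile
  of the latent signal, so 70% of compounds exceed 50% absorption by
  default, emulating a collection biased toward well-absorbed
  compounds.
* `simulateAbsorptionClouds()` draws the well-absorbed class from a
  bivariate normal at (AlogP 2.5, PSA 60 Å²; SDs 1.5 and 25;
  correlation -0.3) and the poorly absorbed class from a two-component
  mixture centred at high PSA (mean 140 Å²), with deliberate overlap:
  in this plane real classes are not separable, which is exactly why
  the ellipse and tree baselines misclassify heavily.

What passing tests on these data do **not** show: that the descriptor
ranges co-occur as they would in real chemistry (a synthetic row need
not correspond to any realizable molecule), that Gasteiger-based
descriptor values match AM1-based ones in absolute terms, or that
predictive accuracy on the synthetic response transfers to measured
%F. The synthetic results validate the machinery -- splitting,
bandwidth selection, leakage protection, statistics -- not the
pharmacology.

## Problem sizes and runtimes

The test suite and examples use the sizes the methodology is built
around: 217-compound tables split 159/50/8-style, a 5,000-point cloud
for ellipse coverage, 800 training compounds for the
signal-recovery check, and 24 fixture molecules covering every
descriptor code path (acceptor-free alkanes, a hydrogen-free
perfluorocarbon, fused aromatics, common drugs). The whole suite runs
in well under a minute on one core.

## Known limitations

* Gasteiger charges shift the electronic descriptors' absolute scale
  relative to semiempirical charges; use the external-charge hook for
  scheme-faithful values.
* One conformer per molecule; conformer-sensitive descriptors carry
  that uncertainty.
* The acceptor rule (all N and O) ignores chemistry that a
  pharmacophore model would catch (amide nitrogens, pyrrole NH).
* The sphere-exclusion variant implemented is one of several in the
  literature; all deliver the dissimilarity property, but exact set
  memberships differ between variants.
* Absorption-plane classifiers are fitted only when the descriptor
  table carries `alogp`/`psa` columns (computed tables do; purely
  synthetic tables do not).
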