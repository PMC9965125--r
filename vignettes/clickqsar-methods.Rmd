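---
title: "Methods: descriptors, models and conjugate enumeration in clickqsar"
author: "clickqsar maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, models and conjugate enumeration in clickqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickqsar)
```

# Scope and rationale

`clickqsar` re-implements, as an open and testable pipeline, the kind of
QSAR analysis used to rationalise the anti-inflammatory and analgesic
activity of NSAID-triazole conjugates: ibuprofen and indomethacin are
esterified with a propargyl handle, clicked against a panel of substituted
phenyl azides, and the resulting 14-member 1,4-disubstituted
1,2,3-triazole library is screened in vivo. Three-descriptor multilinear
models built from charged-partial-surface-area (CPSA) descriptors and
semi-empirical frontier-orbital descriptors then explain the observed
potencies.

The package covers five layers: compound construction and validation,
surface/charge descriptors, a molecular-orbital engine with its reactivity
and energy descriptors, best-multilinear-regression model building with
internal cross-validation, and the bioassay arithmetic (relative potency,
edema inhibition, COX selectivity index, structure-activity contrasts).

# Compound construction

The two reaction templates are pure graph edits on molecules with explicit
hydrogens:

* **Propargylation** converts the single carboxylic acid of an NSAID into
  its prop-2-yn-1-yl ester (net formula change +C3H2, the HBr-equivalent
  leaving group accounted at the formula level).
* **Click cycloaddition** fuses a terminal alkyne and an aryl azide into
  the 1,4-disubstituted triazole. Every atom of both reactants is
  conserved; only the Cu(I)-selective 1,4-regioisomer is generated, which
  matches all of the library's characterised products.

Both templates are validated against the high-resolution MS formulas and
monoisotopic masses recorded for every library member (e.g. the ibuprofen
propargyl ester C16H20O2, 244.1463 Da; the 2-chlorophenyl conjugates
C22H24ClN3O2, 397.1557 Da and C28H22Cl2N4O4, 548.1018 Da). Masses are
neutral-formula sums of most-abundant-isotope masses reported to four
decimals, matching the "calculated" convention of TOF-MS tables (the
electron mass, ~0.0005 Da, is ignored).

The packaged 18-compound set (parents 1 and 6, esters 3 and 7, conjugates
5a-g and 8a-g) was transcribed from the systematic product names into
SMILES. The transcription guard is the formula check in
`load_fixture_set()`: the formula recomputed from each parsed structure
must match the recorded HRMS formula.

# 3D embedding

Surface areas and orbital integrals need one 3D conformer per molecule.
`embed_3d()` is a seeded distance-geometry construction: classical
multidimensional scaling of ideal-bond-length graph distances provides the
initial coordinates, which are refined against bond-length targets
(single-bond covalent radii sums, contracted by 0.88/0.79 for double and
triple bonds), 1-3 distance targets from hybridisation-ideal angles, sp2
planarity restraints and soft nonbonded lower bounds, using 500 iterations
of annealed gradient descent with a 0.25-Angstrom trust region. The result
is bit-identical for identical (structure, seed).

This embedder was written in-package because no deterministic seeded
alternative was available through the R toolchain, and descriptor
reproducibility (identical CSV output for identical configuration) is a
design requirement of the pipeline. The geometries are single conformers
with arbitrary but valid torsions; conformational averaging is out of
scope. Consequently, conformation-sensitive descriptor values carry an
embedding-choice component, which is one of several reasons the package's
absolute descriptor magnitudes are not comparable to values from other
engines (see *Reference statistics* below).

# Partial charges and surface areas

The CPSA definitions are charge-scheme agnostic, so the scheme is a
recorded parameter rather than a fixed assumption. The default is the
Gasteiger-Marsili iterative partial equalisation of orbital
electronegativity (PEOE): eight damped iterations of charge transfer
across bonds, with the published (a, b, c) electronegativity polynomials
per element and hybridisation. Charge is only ever transferred across
bonds, so the atomic charges sum to the molecular net charge by
construction.

Per-atom solvent-accessible surface areas use sphere-point sampling over
(Bondi van der Waals radius + probe) spheres with occlusion by
neighbouring spheres. The quadrature grid is a deterministic
golden-section spiral; defaults are a 1.4-Angstrom water probe and 960
points per atom (closed-form single-sphere area reproduced to well under
1%). Because the grid has a fixed global orientation, areas are exactly
translation-invariant but rotation-invariant only to quadrature accuracy
(about 0.1-0.5% at the default grid).

The CPSA block implements PPSA1 (area over atoms with strictly positive
partial charge), PNSA1 (its complement, so PPSA1 + PNSA1 = TMSA exactly;
zero-charge atoms are counted with the negative partition), PPSA3
(charge-weighted positive area), WNSA-1 = PNSA1 x TMSA / 1000, FPSA3 =
PPSA3 / TMSA, RNCG (largest negative charge over total negative charge)
and the hydrogen-bond-donor surface area (areas of H atoms bonded to N or
O). One printed formula for the relative-negative-charge descriptor
carries the positive-charge set in its subscript while its own caption
defines it from negative charges; the standard negative-charge reading is
implemented.

# Electronic structure and semi-empirical descriptors

A minimal extended Hueckel engine supplies every orbital-derived quantity.
The valence STO basis (H 1s; C, N, O, F 2s/2p; S, Cl 3s/3p) uses standard
single-zeta exponents and valence-state ionisation potentials; overlaps
are exact two-centre STO integrals evaluated in prolate-spheroidal
coordinates with the classical A/B auxiliary functions, and off-diagonal
Hamiltonian elements follow Wolfsberg-Helmholz, `H_ij = K S_ij (H_ii +
H_jj)/2` with K = 1.75. The generalised eigenproblem is solved by Loewdin
symmetric orthogonalisation; closed-shell occupation fills the lowest
orbitals two electrons each (open shells are rejected). Energies are in
eV.

From one such calculation the package reads off:

* the **nucleophilic index** of an atom, sum of squared HOMO coefficients
  on the atom over (1 - e_HOMO);
* the **electrophilic index**, squared LUMO coefficients over
  (e_LUMO + 10), the +10 eV shift applied with energies in eV;
* the **one-electron index**, the HOMO x LUMO coefficient double sum over
  the frontier gap;
* the **resonance energy** of a bonded pair, sum of density-matrix
  elements times resonance integrals between the two atoms;
* the **atomic state energy**, a zero-differential-overlap two-centre
  form: the atom's electron population interacting with every other
  atom's population (repulsion) and core charge (attraction) through a
  Mataga-Nishimoto Coulomb kernel `gamma_AB = 14.397 / (R_AB + a_AB)` eV
  with `a_AB` set by Pariser-Parr-style one-centre repulsion parameters.
  One-centre self-interaction terms are excluded; exact four-index
  integrals are out of scope.

Model descriptors aggregate these per element (for example the average
nucleophilic index over N atoms, the maximum electrophilic index over C
atoms, the maximum resonance energy over H-C bonds). A molecule with no
matching atom or bond scores the neutral value 0 with a warning, matching
how such descriptors appear as zeros in published tables.

# Regression machinery

`fit_ols()` is ordinary least squares with the standard statistics
(R2, F, s2, per-coefficient t values); rank-deficient designs are rejected
naming the collinear columns. `loo_cv()` computes the PRESS-based
leave-one-out q2 through the hat-matrix shortcut (verified against the
naive n-refit loop to 1e-10). `lmo_cv()` is leave-many-out: random
partitions into folds (default 3, i.e. leave-one-third-out, a common
convention when none is stated), pooled PRESS per repeat, averaged over
200 seeded repeats; `n_groups = n` reduces exactly to leave-one-out.

`bmlr_select()` is the best-multilinear-regression step: exhaustive search
over all k-descriptor subsets when their count is at most 1e5, otherwise
forward stepwise selection after removing one of each descriptor pair
correlated above |r| = 0.95. Ties on R2 break by higher leave-one-out q2,
then lexicographic column order. The original selection procedure behind
the published models is not documented; this hybrid is declared as the
package's procedure and is validated by planted-signal recovery
simulations.

Response handling: the anti-inflammatory and central-analgesic models fit
the potency directly; the peripheral-analgesic model fits the reciprocal
of the potency (`transform = "reciprocal"`), and predictions are inverted
back. Percent responses are fitted on the fraction scale by default
(`response_scale = "fraction"`), consistent with the magnitude of the
published residual variance (s2 = 0.001); the scale is a logged
configuration option. Intercepts are always estimated.

# Reference statistics and what is (not) asserted

The published models report R2 = 0.979, q2(LOO) = 0.951, q2(LMO) = 0.963,
F = 123.9, s2 = 0.001 for the anti-inflammatory fit and R2 = 0.967,
q2(LOO) = 0.941, q2(LMO) = 0.949 for the central-analgesic fit, with
printed coefficients and t values for named descriptors. These were
produced by a proprietary descriptor engine whose charge model,
semi-empirical level and exact training-set membership are unstated, and
the per-compound descriptor tables live in supplementary material that is
not packaged. The statistics are therefore recorded as reference metadata
(`reported_qsar_models()`), and `refit_reported_model()` stands ready to
refit the named three-descriptor models from a user-supplied
supplementary table. What the package asserts without that table are the
printed sign/ordering relations: under each recorded coefficient (through
the reciprocal transform where applicable) the compound with the higher
descriptor value must have the correspondingly ordered prediction, which
holds for every printed example pair.

One caveat found while encoding those examples: the peripheral-model
prose states that a higher average N nucleophilic index predicts a *less*
potent analog, but the printed example numbers (0.00721 to 86.0 vs
0.00365 to 42.5) run the other way on the raw potency scale. The numbers
are self-consistent once the model's stated reciprocal response is taken
into account, so the package follows the numbers.

# Synthetic data

`generate_linear_dataset()` emulates the statistical structure the
modelling stages assume: descriptors from a multivariate normal with
exchangeable correlation (default rho = 0.3, a mild realistic
inter-descriptor correlation), a sparse linear response with known
coefficients, Gaussian noise, and an optional reciprocal response
transform. It supports the recovery and calibration suites: planted
three-descriptor signals among ten columns at 5% noise are recovered in
effectively all seeded replicates, and fitted coefficients cover the
truth within two standard errors at the nominal rate. What the generator
does *not* emulate is real assay structure - repeated animals, time
courses, heteroscedastic percent endpoints - so passing tests demonstrate
the correctness of the machinery, not the field performance of any
particular fitted model.

`generate_azide_panel()` produces the substituted phenyl azides of the
conjugation chemistry; the default panel is the library's seven members
(2-Cl, 4-Cl, 4-F, 4-CH3, 2-OCH3, 4-OCH3, 4-NO2).

# Bioassay arithmetic

The bioassay layer stores only values printed in the study's running text
(unprinted table cells are absent, never imputed) and implements percent
edema inhibition, relative potency (a scale-invariant ratio versus the
designated reference drug), the COX selectivity index
SI = IC50(COX-1)/IC50(COX-2), and ordered structure-activity pair
contrasts with direction verdicts. One published ortho/para claim (5e
versus 5f on the anti-inflammatory endpoint) cannot be evaluated because
the 5f value is never printed; the contrast machinery raises an explicit
missing-value error for it, and the same ortho/para direction is verified
on the central-analgesic endpoint where both values are printed.

# Numerical choices and problem sizes

* Charges: 8 PEOE iterations, damping 0.5 (values converge to ~1e-3 by
  iteration 6; 8 matches the published practice).
* Surfaces: 960-point spiral, probe 1.4 A, Bondi radii. Doubling the grid
  moves total areas by < 0.5% on the packaged compounds.
* Electronic: K = 1.75, energies eV; overlap matrices are well
  conditioned for all packaged compounds (smallest eigenvalue guarded at
  1e-8).
* Embedding: 500 refinement iterations, annealed step from 0.03, momentum
  0.7; acceptance thresholds are 0.15 A maximum bond-length error and
  0.9 A minimum nonbonded separation, with up to 5 seeded restarts.
* Test-suite problem sizes: oracle equivalence runs on 50-atom random
  profiles and <= 20-orbital random systems; selection recovery uses
  n = 50, p = 10 over 100 seeds and coefficient calibration n = 50 over
  500 seeds - sizes chosen so the full suite exercises every claim in
  well under an hour on one core.

# Known limitations

* Descriptor magnitudes are engine-specific. Gasteiger charges and
  extended Hueckel orbitals will not reproduce descriptor values computed
  with other charge models or semi-empirical levels, and no such equality
  is claimed or tested; cross-engine comparisons should be made at the
  level of orderings or refitted models.
* Single-conformer geometry; no tautomer/stereoisomer enumeration or
  protonation-state prediction. All packaged compounds are neutral; any
  future charged analog should revisit the protonation assumption
  explicitly.
* The elemental parameter tables cover H, C, N, O, F, S, Cl (plus Br/I
  for masses and radii); other elements error out rather than silently
  extrapolating.
* Open-shell systems are rejected by design.
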