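---
title: "Direct-approximation polarizable electrostatics: models, fits and estimators"
author: "dpolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct-approximation polarizable electrostatics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpolkit)
```

## The model

Every atom carries a fixed partial charge $q_j$ (e) and an isotropic
point polarizability $\alpha_j$ (bohr$^3$). Under the **direct
polarization approximation** the induced dipole on atom $j$ is

$$\boldsymbol{\mu}_j = \alpha_j \mathbf{E}_j, \qquad
\mathbf{E}_j = \mathbf{E}_\mathrm{ext} +
\sum_{k \ne j} f_{jk}\, q_k\, \frac{\mathbf{r}_{jk}}{|\mathbf{r}_{jk}|^3},$$

i.e. the polarizing field contains the permanent charges and any uniform
external field, but *not* the other induced dipoles. This removes both
the self-consistent iteration of fully mutual models and their
short-range divergence (the polarization catastrophe), so no Thole-style
damping is used anywhere: the Coulomb and dipole kernels are bare.

Intramolecular charge–polarizability interactions are attenuated by the
bonded-path factor $f_{jk}$: 0 for 1–2 and 1–3 pairs, 0.5 for 1–4 pairs,
1 otherwise. The shortest bonded path defines the pair class; in rings,
where a pair can be both 1–3 and 1–4, the minimum path wins (the
convention of Applequist-style models; ring behaviour is not prescribed
by the protocol we emulate, so this choice is ours and is exercised by
the randomized-graph tests). Atoms in different connected components get
$f = 1$; an atom with no bonds at all is flagged with a warning since a
bonded path cannot classify it. The scaling applies **only to fields at
atom sites**; the ESP observed at grid points sums all charges and
dipoles unscaled, since the factor is defined for charge–polarizability
interactions, not for observer points.

The model ESP at a grid point $i$ is

$$V_i = \sum_j \frac{q_j}{|\mathbf{r}_{ij}|} +
\sum_j \frac{\boldsymbol{\mu}_j \cdot \mathbf{r}_{ij}}{|\mathbf{r}_{ij}|^3},$$

with $\mathbf{r}_{ij}$ from atom $j$ to point $i$. Because
$\boldsymbol{\mu}$ is linear in $q$ through the scaled permanent fields,
$V$ is a *linear* function of the charge vector — the single fact that
makes every fit below a linear least-squares problem
(`respDesignMatrix()` assembles the combined operator explicitly, and a
test verifies linearity against it).

Internal units are atomic units throughout (bohr, e, hartree/e);
Angstrom and Debye appear only at I/O boundaries
(1 Å = 1.8897261254578281 bohr, 1 au dipole = 2.541746473 D).

## ESP sampling grids

`generateMskGrid()` builds Merz–Singh–Kollman style shells: shell $k$
($k = 1,\dots,10$ by default) places a quasi-uniform lattice of 17
points/Å$^2$ on a sphere of radius $1.4\,r_\mathrm{vdW} + (k-1) \times
0.126$ Å around each atom and removes points inside any other atom's
same-shell sphere. The 0.126 Å figure is read as the radial increment
between successive shells; the innermost scale factor is not part of the
stated protocol, so the standard MSK value 1.4 (on Bondi radii) is the
default and both are configurable in `mskGridSpec()`.

Sphere sampling uses a golden-spiral (Fibonacci) lattice — deterministic
and quasi-uniform at any density — generated in a molecule-fixed
principal-axes frame whose axis signs are fixed against the
farthest-from-centroid atoms. This makes the grid rotate rigidly with
the molecule (exact equivariance for molecules with non-degenerate
principal moments; for symmetric tops such as methane the grid is still
deterministic, merely not strictly equivariant, which no computation
here depends on). Near-duplicate points are removed by coordinate
hashing at 10⁻⁶ Å rather than all-pairs distance checks, which keeps
grid construction linear in the point count.

## Fitting typed polarizabilities

Polarizabilities attach to *types*: either one value per element
(C, H, O, N in the trained scope) or one per SMARTS pattern applied in
order with last-match-wins semantics, the hierarchy convention of
SMIRNOFF-style force-field formats (generic patterns first, specific
overrides later).

Training data are, per conformer, six ESP *difference* records:
perturbed-minus-baseline under uniform fields of 0.01 au along
$\pm x, \pm y, \pm z$ (a strength comparable to the field of a sodium
ion ~4 Å away; six directions average over anisotropy). In the
difference, the permanent-charge contribution cancels and a uniform
field induces $\boldsymbol{\mu}_{jkl} = \alpha_{t(j)}
\mathbf{E}_{\mathrm{ext},l}$ exactly, so the objective

$$\chi^2(\alpha) = \sum_{k,l,i} \Big( V_{\mathrm{diff},ikl} -
\sum_j \alpha_{t(j)}\, \mathbf{E}_{\mathrm{ext},l} \cdot
\frac{\mathbf{r}_{ijk}}{|\mathbf{r}_{ijk}|^3} \Big)^2$$

is an exact quadratic in the typed $\alpha$. `fitPolarizabilities()`
accumulates the per-record Gram matrices (so memory does not grow with
the number of records) and solves it two ways: a closed-form
least-squares solution with non-negativity enforced by active-set
clamping, and Nelder–Mead (the optimizer of record for this model)
restarted until stationary. The two optima must agree to 10⁻⁶ relative —
a standing test, not just a convention — and a type matched by no atom in
the training set raises an unidentifiable-parameter error naming the
type. A positive by-product of the quadratic structure: duplicating
conformers rescales the objective without moving its minimum, which is
also tested.

## RESP-dPol charges

`fitRespDpol()` fits charges to a baseline (zero-field) ESP record by
minimizing

$$\chi^2(q) = \sum_i \big(V_{\mathrm{ref},i} - V_i(q)\big)^2 +
\lambda \Big(\sum_j q_j - q_\mathrm{tot}\Big) +
\sum_j a_j \big(\sqrt{q_j^2 + b^2} - b\big),$$

where $V_i(q)$ includes the induced-dipole term and $\lambda$ is a
Lagrange multiplier pinning the charge sum to the molecule's formal
charge. The hyperbolic restraint is handled by iterated diagonal
reweighting: at each pass the penalty is replaced by its quadratic
majorizer at the current charges (effective diagonal term
$a_j/\sqrt{q_j^2+b^2}$), and the KKT system is solved exactly. Because
each pass minimizes a majorizer, the objective is monotone
non-increasing — asserted by the tests over the recorded trace.
Convergence is declared at max $|\Delta q| < 10^{-8}$ e, capped at 200
iterations (the restraint is named by the protocol, the solver is not;
this scheme is our choice). A singular design — e.g. degenerate toy
grids — surfaces as a rank-deficiency error rather than silent garbage.

Stage 1 fits all atoms with the weak restraint ($a = 0.005$,
$b = 0.1$ au). Stage 2 freezes every atom except sp3 carbons bearing at
least two topologically equivalent hydrogens, plus those hydrogens,
enforces exact within-class charge equality (one shared variable per
class) and refits under the strong restraint ($a = 0.01$ au). The
protocol says only that "polar regions" stay fixed; enumerating the
refit set as methyl/methylene groups, and restraining only non-hydrogen
atoms, follows classic RESP practice — both choices are explicit
arguments (`restraintSpec()`), not hard-wired. Topological equivalence
comes from `symmetryClasses()`, an iterative canonical-rank
(Morgan/Weisfeiler–Lehman) refinement over elements, degrees, formal
charges and bond orders; permutation-invariance of the partition is a
standing property test.

Multi-conformer fitting treats conformers as independent molecules
(per-conformer fits), mirroring the reference protocol; charged species
use their formal $q_\mathrm{tot}$ in the constraint, and their dipoles
are reported about the center of nuclear charge, since the dipole of an
ion is origin-dependent.

## BCC-dPol training and AM1-BCC-dPol assignment

Bond charge corrections express charges as
$q_j = q_j^\mathrm{pre} + \sum_\beta T_{j\beta} B_\beta$: population
precharges (from a fast semi-empirical method; always an *input* here)
plus an antisymmetric per-bond-type transfer. `bondTypeMatrix()` assigns
each bond to the first table entry whose bond order and two
atom-environment patterns match ($+1$ on the first-pattern end, $-1$ on
the other), so every column of $T$ sums to zero and *any* $B$ conserves
every molecule's total charge exactly. A bond matching a symmetric type
in both orientations contributes zero — such types carry no signal and
are reported as unsupported rather than invented. Aromatic bonds are a
distinct order class (order 4), since published BCC type tables
distinguish them; table contents are configuration (JSON), not code.

`fitBccs()` minimizes the summed squared ESP deviation over a training
set, which is again linear in $B$ through the combined
Coulomb-plus-induction operator; rank-deficient directions are resolved
by the minimum-norm (pseudoinverse) solution. Whether the induced
dipoles should respond to the corrected charges or to the precharges
during training is not specified by the protocol; both are linear, we
default to the self-consistent choice (`inducedFrom = "corrected"`) and
expose the switch. `assignAm1BccDpol()` then applies fitted corrections
deterministically and refuses to run if a matched type has no value.

## Liquid-state estimators

From per-frame total dipoles $\boldsymbol{\mu}$ (e·bohr) and volumes
(bohr$^3$):

- mass density $\rho = M / \langle V \rangle$ in g/mL;
- static dielectric constant (Gaussian units)
  $D = \varepsilon_\infty + 4\pi\,(\langle \mu^2 \rangle -
  |\langle \boldsymbol{\mu} \rangle|^2) / (3 \langle V \rangle k_B T)$,
  reported together with $1/D$ because electrostatic screening scales
  with the reciprocal;
- $\varepsilon_\infty = 1 + 4\pi \sum_j \alpha_j / \langle V \rangle$:
  under direct polarization the induced dipoles do not interact, so the
  electronic susceptibility is strictly additive.

The printed forms of the fluctuation formula and of
$\varepsilon_\infty$ appear as display equations (images) in the source
we emulate, so both are reconstructed from the standard references and
from the direct-approximation argument respectively; as a guard, the
analytic $\varepsilon_\infty$ is cross-checked — in a mandatory test —
against the finite-difference polarization response
$1 + 4\pi\,\partial P/\partial E$ of the implemented model on a frozen
50-molecule box, where it agrees to machine precision (the response is
exactly linear). The ensemble average $\langle V \rangle$ is used in
the denominators (per-frame volume is an open reading; the difference
vanishes for NVT series and is second-order small in NPT volume
fluctuations). The full vector second moment is used with no block
averaging by default; $D \ge \varepsilon_\infty \ge 1$ holds by
construction and is property-tested.

The Lorentz–Lorenz relation
$\alpha_M = \frac{3}{4\pi\rho}\frac{n^2-1}{n^2+2}$ converts a liquid's
refractive index into a molecular polarizability to compare with
$\alpha_M = \sum_j \alpha_j$ (additive under direct polarization); its
algebraic inverse is provided for round-trip checks.

## The synthetic ground-truth emulator

`makeToySet()` builds eight idealized CHON molecules — two alkanes, an
alcohol, an amine, an amide, a carboxylate anion, an ammonium cation and
an aromatic — from hard-coded tetrahedral/trigonal templates, in 2–4
conformers each. Conformers beyond the first are seeded smooth
distortions of the template, accepted only if every conformer pair
differs by at least 0.5 Å coordinate RMSD (the distinctness threshold of
the emulated training protocol). `makeGroundTruth()` draws true charges
per *topological symmetry class* (equivalent atoms get equal true
charges, as in any physically sensible charge model — and necessarily,
for stage-2 equivalencing to be consistent with the truth), shifted to
sum exactly to the formal charge, and pairs them with element-typed true
polarizabilities (9.4, 2.7, 5.4, 7.4 bohr$^3$ for C, H, O, N — the
magnitude typical of Applequist-style element parameters).

`synthEspRecords()` then emulates the reference protocol with the
package's own forward model: a baseline ESP on the standard grid plus
six 0.01 au field-perturbed ESPs reported as differences. Optional noise
is i.i.d. Gaussian on ESP values, added after differencing — the
simplest stand-in for reference-data and grid error. What these records
deliberately do **not** emulate: anisotropy of the true electronic
response, charge penetration at the inner shells, basis-set or
correlation error. Recovery tests on them are therefore *exact-model*
tests — they verify the estimators, the linear algebra and the
protocols, not the physics gap between a point-charge-plus-dipole model
and real quantum-mechanical ESPs. The noise-robustness checks
(σ ∈ {10⁻⁵, 10⁻⁴, 10⁻³} hartree/e, error growing monotonically and
roughly linearly) probe conditioning, not realism.

`synthDipoleSeries()` generates the independent-rotor liquid: N dipoles
of fixed magnitude, freshly and uniformly reoriented each frame, whose
dielectric constant has the closed form
$D = 1 + 4\pi N \mu_0^2/(3 V k_B T)$ — the analytic target for the
fluctuation estimator. `synthFrozenBox()` packs rigid bent three-atom
polar molecules into a cube for the $\varepsilon_\infty$
finite-difference cross-check.

## Numerical choices and problem sizes

- Coincident atom/point geometry raises singularity errors (thresholds
  10⁻²⁰ bohr² atom–atom, 10⁻¹⁶ bohr² point–atom) instead of returning
  infinities.
- Non-negativity of $\alpha$ is a hard bound: active-set clamping in the
  linear solver, a scaled quadratic penalty in Nelder–Mead.
- The restraint reweighting starts from $q = 0$ (weights $a/b$), which
  makes the first iterate the ridge-like solution and every later pass a
  monotone improvement.
- Seeds: every stochastic helper takes an explicit integer seed and is
  bit-reproducible for a fixed value; derived seeds stay far below
  2³¹. Solver results must be seed-independent anyway (the two-solver
  agreement property).
- Default problem sizes were chosen so the whole synthetic study runs in
  well under a minute per fit on a single core: 8 molecules / 23
  conformers on the full 10-layer, 17 points/Å$^2$ grids (≈3×10⁴ points
  per conformer) for the acceptance-level runs, coarser 2-layer grids
  for fast unit tests, 10⁵ frames for the dielectric estimator.

## Known limitations

- The SMARTS matcher implements a documented subset (bracket primitives
  `#n`, element, `X`/`D`, `H`, charge, `a`/`A`, `*`; bonds `- = # : ~`;
  branches; single-digit ring closures; conjunction only). Disjunction,
  recursive SMARTS and stereo raise errors. Hydrogens must be explicit
  atoms. The subset is cross-checked against an independent
  cheminformatics implementation in the test suite.
- Aromaticity is what the input says it is: an atom is aromatic when it
  participates in a bond of the aromatic order class; no perception is
  performed.
- Element-based typing covers any element with a configured radius and
  polarizability, but the shipped defaults target the CHON scope.
- The liquid module consumes time series; it does not run dynamics, and
  the dielectric estimator assumes the series is equilibrated and
  decorrelated (no automatic error analysis beyond the delta-method
  standard error it reports).
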