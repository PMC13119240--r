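---
title: "Refining molecular models against X-ray total scattering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining molecular models against X-ray total scattering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsrlite)
```

## The problem

A high-energy X-ray total scattering experiment on a molecular liquid or
glass yields one curve, the total structure factor $S(Q)$, which mixes
every atom-pair correlation in the sample.  Empirical potential structure
refinement (EPSR) inverts this under-determined problem by simulation:
a box of semi-rigid molecules is evolved by Metropolis Monte Carlo under a
physically sensible *reference* potential (Lennard-Jones plus Coulomb with
literature partial charges), and a data-derived *empirical* correction
potential is iterated until the model's X-ray weighted $S(Q)$ matches the
measurement.  The refined ensemble is then interrogated for the
quantities of pharmaceutical interest: NH···O hydrogen-bond statistics,
running coordination numbers $n_{ab}(r)$, conformer populations, and — in
drug–polymer dispersions — whether the drug's amino donor prefers drug or
polymer carbonyl acceptors.

`epsrlite` implements this pipeline for dihydropyridine drugs
(nifedipine, felodipine), their aryl-flipped and enantiomeric conformers,
and polyvinylpyrrolidone (PVP) oligomers, together with crystal-structure
comparators and a synthetic-data generator that stands in for beamline
data in every test.

## Molecular models

Templates are idealized three-dimensional structures built from standard
bond lengths (aromatic C–C 1.39 Å, C–Cl 1.73 Å, C=O 1.22 Å, N–H 1.01 Å,
C–H 1.09 Å) with planar rings and radial substituents.  They are *starting
conformations*, not quantum-chemical minima: the Monte Carlo engine owns
the conformational exploration.  Each template declares its rotatable
groups — for nifedipine the two methyl esters, the two ring methyls and
the nitro group (five rotations); for felodipine the two esters and the
two ring methyls, since it has no nitro group.  Rotations are exact
rigid-body operations about the declared axis bond; a greedy torsion
relaxation at build time removes steric clashes among the freshly placed
substituents (deterministic, so templates are reproducible objects).

Felodipine's chirality is encoded by which ring position carries the
ethyl (versus methyl) ester, matching the methyl/ethyl-interchange
convention for the R and S enantiomers; the two enantiomer templates are
mirror images.  The "flipped" nifedipine conformer moves the nitro group
to the opposite ortho position of the aryl ring, the rotamer whose
population the conformer scan estimates.  The rigid dichlorophenyl
geometry puts the intramolecular Cl···Cl distance at
$2(1.39+1.73)\sin 30^\circ = 3.12$ Å, which is the origin of the sharp
~3.1 Å feature in the felodipine differential PDF.

PVP oligomers are built syndiotactically (pyrrolidone rings alternate
above and below the backbone zig-zag plane); each monomer's carbonyl
oxygen carries the carbonyl acceptor type and forms the "polymer"
acceptor class in mixture analyses.

### Reference potential

Partial charges and like-type Lennard-Jones parameters follow the
tabulated dihydropyridine/ester/nitro/dichlorophenyl set; unlisted atoms
keep per-element default LJ parameters (aromatic-carbon-like 3.55 Å/0.29
kJ mol⁻¹ for C, 2.42 Å/0.10 for H, element defaults for N, O, Cl) and
zero charge.  The assignment of "pyridine" carbons is ambiguous in a
dihydropyridine; we map the two ring carbons flanking the N–H to that
type and leave the remaining ring carbons at defaults, documented here as
the chosen interpretation.  Unordered pairs combine by Lorentz–Berthelot
rules.  Because the tabulated charges do not sum to zero on a whole
molecule, a uniform neutralizing correction is spread over the atoms with
zero tabulated charge — cutoff Coulomb sums need neutral molecules for
box-size-independent energies.  The refinement engine uses a 12 Å
spherical cutoff (capped at half the box) with a shifted Coulomb term;
`lj_coulomb_energy()` defaults to the bare untruncated sum so that its
closed-form pair values hold exactly.  Intramolecular nonbonded
exclusions are the usual 1-2/1-3, with 1-4 and beyond at full strength.

## Scattering formalism

Partial pair distribution functions are histogram estimators with
minimum-image distances and exact shell volumes, normalized per ordered
pair ($\rho c_b N_a$; same-type pairs counted once).  The X-ray total is
the Faber–Ziman combination
$$S_X(Q) = 1 + \sum_{a\le b}(2-\delta_{ab})\,c_a c_b
  \frac{f_a(Q) f_b(Q)}{\langle f\rangle^2}\,[S_{ab}(Q)-1],$$
with Cromer–Mann form factors for H, C, N, O, Cl and hydrogen kept at its
true (weak) weight.  For isolated clusters the self-scattering
normalization $\langle f^2 \rangle$ replaces $\langle f\rangle^2$
(`background = FALSE`), which makes the histogram-transform route agree
with a direct Debye sum to better than $10^{-3}$ — one of the package's
standing oracle checks.

Finite boxes truncate $g(r)$ at half the edge; the transform therefore
applies a cosine taper over the outer 20 % of the $r$ range by default,
suppressing low-$Q$ termination ripples.  The taper is an estimator
choice applied identically to pseudo-experiments and models, so recovery
tests compare like with like; set `taper = 0` for the exact truncated
transform.

$D(r) = (2/\pi)\int Q\,[S(Q)-1]\sin(Qr)\,dQ = 4\pi\rho r\,[g(r)-1]$ is
computed by trapezoidal quadrature over the measured range, optionally
Lorch-windowed.  First-sharp-diffraction-peak (FSDP) metrics use
three-point parabolic interpolation around the first local maximum in the
0.6–2.0 Å⁻¹ window (configurable), ignoring candidate maxima whose
prominence is below 20 % of the window's dynamic range so that
measurement noise cannot masquerade as the FSDP; when two genuine maxima
survive, the lower-$Q$ one is taken, since the FSDP is by definition the
first.

## The refinement loop

One empirical-potential iteration is: several Monte Carlo sweeps (one
attempted move per molecule per sweep, cycling translation / rigid
rotation / group rotation), a model $S_X(Q)$ from a few snapshots, and a
potential update.  The update is a direct Fourier-feedback scheme
$$\Delta u(r) = k_BT \cdot f \cdot \frac{1}{2\pi^2\rho r}
  \int Q\,[S_\mathrm{model}-S_\mathrm{target}]\sin(Qr)\,dQ,$$
apportioned to pair channels in proportion to their Q-averaged X-ray
weights (normalized so the aggregate feedback is exactly $f$),
Gaussian-smoothed (σ = 0.3 Å), tapered to zero at the table edge, added
to $u_{ep}$ and clipped to ±15 kJ/mol.  This is deliberately simpler
than the Poisson-function expansion used by the original EPSR software
but has the same fixed point: when model and target agree, the update is
identically zero.  Defaults — feedback 0.3, smoothing 0.3 Å, cap
15 kJ/mol — were chosen for stable convergence on the synthetic recovery
problems and are all exposed through `empirical_potential_state()`.

Hard minimum distances (the 2.9 Å NH···O constraint from the crystal
structures, plus a 1.0 Å global intermolecular floor) are enforced by
outright rejection.  The rule is "never worsen": a move that creates or
deepens a violation is rejected, so a valid state can never acquire one,
while a starting configuration with residual insertion contacts repairs
itself monotonically.  Move sizes (0.2 Å translation, 10° rotation, 15°
group rotation) are auto-tuned towards 30–50 % acceptance every 1000
proposals.  All randomness comes from R's RNG: a seed makes the entire
trajectory bit-reproducible, which the tests assert literally.

Temperatures are always configuration inputs (300 K glass, 430/470 K
liquid in typical use), never constants baked into the code.

### Density refinement

`compress_box()` mirrors the protocol of starting from a random
low-density arrangement and shrinking the box until the model FSDP height
matches the target, because that peak is very sensitive to density.
Molecule centroids are rescaled (internal geometry untouched), the box
re-equilibrates between steps, and once two informative points exist the
next density comes from a secant step on the (density, height) relation,
clamped to the exploratory step ratio.  Near the target the height is
re-measured with a larger snapshot average — measurement noise, not step
size, limits the attainable density resolution — and an apparent match is
confirmed at high precision before the routine reports convergence.
Non-convergence and density-bound hits are reported, never silent.

### Conformer populations

`scan_conformer_fraction()` estimates the population of a second
conformer from the R-factor ($R = \frac{1}{N_Q}\sum[S_\mathrm{model} -
S_\mathrm{target}]^2$; the mean-square convention — magnitudes of a few
$10^{-3}$ for good fits) as a function of the assumed fraction.  Its
default (`"in_place"`) estimator was designed around two measured facts
about desk-scale boxes.  First, the structural realization of a small
box projects onto the conformer-difference signature at the ±0.1–0.2
level in fraction units, so independently refined mixture boxes per
fraction (`mode = "rebuild"`) mostly compare box realizations, not
conformer content.  Second, empirical-potential refinement *absorbs* the
composition signal: the correction potential can reproduce the
conformer signature through intermolecular structure, flattening R(f).
The in-place scan therefore collects one (optionally
replicate-pooled) equilibrated ensemble of the first conformer under the
reference potential only, and scores each fraction f by replacing a
fraction f of the intramolecular scattering with that of the flipped
conformer — realized exactly, per snapshot, by the torsion-preserving
180° rotation of the aryl ring about its attachment bond
(`flip_substituent()`).  R(f) is then an exact quadratic in f whose
vertex (`best_interp`) is the least-squares fraction estimate; the grid
argmin (`best`) and the fitted normalization scale (a known sensitive
indicator of conformer content) are reported alongside.  Even so, the
estimate inherits the realization structure of the boxes on *both* sides
of the comparison: the measured information limit is roughly ±0.1 in
fraction per realization pair at 20 molecules, improving with the square
root of pooled replicates and of box size.  The acceptance suite runs
this inversion at its stated tolerance and documents the outcome rather
than widening the band; a pseudo-experiment averaged over several
independently prepared boxes (the synthetic analogue of a
macroscopically self-averaging sample) is the matching study condition.

## The synthetic-data generator

`generate_reference_fluid()` produces equilibrated molecular (or
single-site Lennard-Jones) fluids by plain Metropolis NVT under the
reference potential, with equilibration detected from the slope of the
windowed running mean of the energy; `make_pseudo_experiment()` turns an
ensemble into an instrument-like pattern: X-ray weighted $S(Q)$ on the
0.6–25.0 Å⁻¹ range (0.02 Å⁻¹ steps) with additive Gaussian noise of
σ = 0.005 — visually comparable to high-energy synchrotron data quality.
Every dataset carries its ground truth (density, partials, conformer
fractions, any planted perturbation potential), and recovery tests score
against that truth, never against published measurements.

What the generator emulates: the equilibrium structure of a semi-rigid
molecular fluid under the reference potential, instrument Q-range and
noise, and known perturbations for inverse-problem tests.  What it does
not emulate: Compton and detector corrections (inputs are assumed
normalized), quantum conformer energetics, and real relaxation dynamics.
Passing recovery tests therefore demonstrates that the *inverse
machinery* works at the stated problem sizes; it does not validate the
reference potential against real drugs.

### Problem sizes and study conditions

Tests run at desk scale by design: 100–150-particle Lennard-Jones fluids
for the planted-perturbation and density recoveries, 16–20-molecule
drug boxes for the refinement and conformer scans (the production-scale
demonstrations use 64 molecules, matching the usual box size for these
systems), ensembles of 50–150 configurations instead of the ≥50 000 a
publication-quality run would accumulate.  The conformer-scan target is
generated at 470 K and an atom density of 0.09 Å⁻³, a hot-liquid density
a few percent below the 0.105–0.110 Å⁻³ reported for the 300 K glass.
Recovery tolerances (density 2 %, fraction ±0.05, $\max|\Delta g| <
0.1$ on 0.3 Å-smoothed curves) are set by the sampling statistics
achievable at these sizes; the g(r) comparison smooths because the raw
0.1 Å histogram bins carry ~0.05 counting noise at ensemble size 150.

## Crystal comparators

A minimal core-CIF reader (cell, both symmetry-operator dialects,
atom-site loop, occupancy-resolved disorder) feeds symmetry expansion to
Cartesian supercells, molecule regrouping by covalent radii × 1.2,
intermolecular donor–acceptor contact lists with N–H···O angles, mass
densities $ZM/(N_AV)$, and exact step-curve coordination numbers.
Contact searches verify their supercell is large enough by re-running in
a larger one.  Published database structures are accepted as user-supplied
CIF files — there is no automated retrieval — so the shipped tests
exercise this path with synthetic toy crystals that plant a known contact
distance and angle.  When hydrogens are absent the donor H is placed by
riding geometry and the output flags it, since the N–H···O angle depends
on that placement.

## Hydrogen-bond conventions

The geometric criteria are not settled in the literature; the defaults
are d(N···O) ≤ 3.5 Å and ∠N–H···O ≥ 120°, both exposed in
`hbond_criteria()` and echoed in every census output.  Acceptor classes
are resolved structurally: drug ester carbonyls, drug nitro oxygens, and
PVP carbonyls.  Coordination thresholds (e.g. the distance where
$n_{NO}(r)$ reaches 0.4) are reported by linear interpolation between
grid points and are sensitive to the acceptor-class convention, which is
why every analysis output states its classes.

## Known limitations

* The empirical-potential update is a diagonal approximation in pair
  space; strongly correlated multi-component systems may converge slowly.
* No Ewald summation: charged long-range order beyond the cutoff is out
  of scope (molecules are neutralized, so the error is a short-ranged
  multipole term).
* Backbone dihedrals of the PVP oligomer are fixed; only the pyrrolidone
  rings rotate.
* The CIF reader targets well-formed core CIF; esoteric dialects (multi-
  block files, text fields) are not supported.
* Desk-scale ensembles leave visible counting noise in partials; scale
  `ensemble_size` up for production work.
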