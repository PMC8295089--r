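---
title: "Energy-Entropy Multiscale Cell Correlation: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-Entropy Multiscale Cell Correlation: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemcc)
```

## The method

`eemcc` computes absolute free energies of simulation boxes directly from
molecular-dynamics output, and from them the octanol–water partition
coefficient of a solute. The free energy of each box is `G = H - TS`. The
enthalpy `H` is simply the time-averaged total (potential + kinetic) energy
of the simulation; the pressure–volume term is neglected, as it nearly
cancels in a transfer at ambient pressure. The entropy `S` is where the
method lives: it is decomposed multiscale over every molecule in the system,

```
S = sum over (molecule kind a, level b, motion c, minima-type d) of S_ab^cd
```

with levels *molecule* (M) and *united atom* (UA, a heavy atom rigidly
carrying its bonded hydrogens), motions *translation* and *rotation*, and
minima-types *vibrational* (motion within an energy well) and
*topographical* (the multiplicity and probabilities of wells).

logP follows from the transfer free energy of solute X from water to
octanol, assembled from four independent boxes — solute in water X(aq),
solute in octanol X(oct), pure water, pure octanol:

```
dG_transfer = (G_X(oct) + G_wat) - (G_oct + G_X(aq))
logP        = -dG_transfer / (ln(10) kB T)
```

Only first-solvation-shell solvent molecules are counted in the solution
boxes: the entropy of more distant solvent changes little on transfer and is
poorly converged. The pure-liquid boxes count the *same number* of solvent
molecules as the solute's first shell (stoichiometric matching), but their
per-molecule statistics are pooled over every molecule of the liquid for
better convergence.

## Vibrational entropy

Each unit (molecule, or united atom) vibrates in the mean field of its
cell. The vibrational entropy of a set of units is obtained from the
covariance matrix of their generalized forces:

* translation: the mass-weighted force covariance, elements
  `<F_a F_b> / sqrt(m_a m_b)`;
* rotation: the moment-of-inertia-weighted torque covariance, elements
  `<tau_a tau_b> / sqrt(I_a I_b)`, with torques expressed in the unit's body
  frame.

Eigenvalues `lambda_i` convert to quasi-harmonic frequencies
`nu_i = (1/2 pi) sqrt(lambda_i / kB T)` and each mode contributes the
quantum-harmonic-oscillator entropy

```
S_vib = kB * sum_i [ x_i / (exp(x_i) - 1) - ln(1 - exp(-x_i)) ],   x_i = h nu_i / kB T
```

Two conventions matter and are applied exactly:

* **Mean-field halving.** Molecule-level forces and torques and UA-level
  torques are halved before accumulation — half of each interaction belongs
  to the neighbouring cell. UA-level *forces* are not halved, because
  inter-UA correlations are carried explicitly in the molecule reference
  frame.
* **Six-mode removal.** The six lowest-frequency modes of the UA
  translational spectrum duplicate the molecule-level translation and
  rotation and are removed. The package enforces structurally that this
  removal can only be applied to UA translational spectra.

Body frames: a molecule's frame sits at its centre of mass with axes along
the principal axes of inertia, ordered by ascending moment. A united atom's
origin is its heavy atom, with axes derived from its covalent bonds to other
heavy atoms (bisector rule for two neighbours, bond direction plus a
deterministic perpendicular for one). A UA's rotational degrees of freedom
follow its hydrogen count — 3 if it carries two or more hydrogens, 2 for
one (rotation about the heavy–H axis carries no inertia, so the two torque
axes are perpendiculars to that bond), 0 for none.

Numerical conventions the estimator depends on, chosen here because the
underlying theory does not fix them:

* Eigenvector signs are fixed (largest-magnitude component positive,
  right-handed third axis), and each frame's axes are additionally
  sign-matched to the previous frame's. Without this, near-degenerate
  inertia moments flip axes between frames and inject spurious covariance.
* Covariances are *central* (mean-subtracted): a nonzero mean force at
  equilibrium is a sampling artifact, not signal.
* Eigenvalues in `[-1e-8, 0) * trace/N` are clipped to zero; anything below
  `1e-12 * trace/N` is treated as an exact zero mode and contributes zero
  entropy rather than the divergent classical value. Such modes only arise
  from degenerate inputs or exact constraints.
* One covariance matrix is accumulated per *species* (solute, shell water,
  shell octanol), pooling all molecules of the species and all frames.
  Per-molecule matrices over a whole liquid would be enormous and
  unconverged.

## Solvation shells: RAD

First shells are defined on molecular centres of mass by the Relative
Angular Distance criterion, which is parameter-free: candidates are taken in
order of increasing minimum-image distance `r_ij`, and candidate `j` joins
the shell unless some already-accepted closer neighbour `k` blocks it,

```
blocked  <=>  1/r_ij^2 < (1/r_ik^2) cos(theta_jik)
```

where `theta_jik` is the angle subtended at the central molecule. Ties in
distance are broken by molecule index so results are deterministic. A
distance pre-cut (default 12 A) restricts the candidate pool purely for
speed; the suite verifies on fixtures that it never alters a shell. The
coordination number distribution `p(Nc)` is accumulated per frame — for the
single tagged solute, or pooled over every molecule of a species in a pure
liquid.

## Topographical entropy

* **Positional** (molecule translation): `S_pos = kB ln(V0 / V_solvent)`,
  where `V_solvent` is the pure-solvent box volume per molecule. `V0` is
  taken as the solution box volume; it cancels in every reported transfer
  difference, which depends only on the two molecular volumes. For a 34 A
  cubic box with 1300 waters versus 150 octanols this difference is
  -18 J K^-1 mol^-1 regardless of everything else.
* **Orientational** (molecule rotation):
  `S_or = kB sum_Nc p(Nc) ln(max(1, sqrt(Nc^3 pi) / sigma))`, with `sigma`
  the molecular symmetry number (2 for water, 1 for octanol and typical
  solutes). For water an extra factor 1/4 multiplies the orientation count
  inside the logarithm, before the clamp, for hydrogen-bond directionality.
  The clamp guarantees at least one orientation.
* **Conformational** (UA translation): flexible heavy-atom dihedrals are
  discretised into conformers at the maxima of their angle distributions. A
  periodic 72-bin (5-degree) histogram is smoothed with a 3-bin circular
  moving average; maxima below 1% occupancy are ignored and boundaries fall
  at the minima between adjacent maxima. These two smoothing choices make
  "maxima of the distribution" deterministic on finite samples. The entropy
  is `S_conf = kB sum_i lambda_i ln(1/lambda_i)` over the eigenvalues of the
  conformer correlation matrix: diagonal entries are marginal conformer
  probabilities, off-diagonal entries between conformers of different
  dihedrals are symmetrized joint probabilities, entries between conformers
  of the same dihedral are zero, and the eigenvalues are clipped at zero and
  renormalized to unit sum. For a single dihedral this is exactly the
  Shannon entropy of its conformer populations; a perfectly correlated pair
  of dihedrals contributes `kB ln 2`, not twice that. Dihedrals with fewer
  than 50 observations are marked rigid and contribute nothing. UA
  *rotational* topographical entropy is excluded structurally (rigidity and
  symmetry make it negligible), and water carries no UA or conformational
  terms at all — it is treated only at the molecule level.

## Assembly

For an aqueous solution, the total is the seven solute terms plus `Nc` times
the three per-water terms:

```
S_X(aq)  = S_X,M^transvib + S_X,M^rovib + S_X^pos + S_X^or
         + S_X,UA^transvib + S_X,UA^rovib + S_X^conf
         + Nc,X * (S_wat,M^transvib + S_wat,M^rovib + S_wat^or)
```

For octanol solutions the bracket gains the solvent's UA and conformational
terms (six solvent terms instead of three). Pure liquids keep only the
bracket, with the same `Nc,X` as the matching solution box. The multiplier
is the *mean* coordination number over frames — a real number — chosen for
consistency with the orientational term, which already uses the full
`p(Nc)`. `mcc_system_result()` enforces these term inventories and
`transfer()` applies the four-box combination; missing slots are named
errors, never silently zero.

Replicate simulations are combined by averaging energies and entropies over
repeats and then forming `dG` and logP; per-simulation entropies are
computed independently (covariances are not pooled across repeats).
Uncertainty is the standard error of the mean over repeats, `s / sqrt(n)`.
Both MAE and RMSE are always reported when comparing to experiment.

## Units

Internal units are Angstrom, amu, kcal mol^-1, Kelvin, with
`kB = 0.0019872041 kcal mol^-1 K^-1` and Planck's constant expressed per
mole in the same system. Because `amu x Avogadro = 1 g` exactly, the single
factor `4.184e26` converts covariance eigenvalue ratios
(kcal mol^-1 A^-2 amu^-1) to s^-2. Entropies are reported in J K^-1 mol^-1
with a kcal mol^-1 K^-1 attribute view.

## The synthetic generator: what it validates, and what it does not

Every estimator stage has a generator with an exactly known answer:

* `synth_harmonic_liquid()` — point masses tethered to lattice sites,
  positions drawn from the *exact* Boltzmann distribution (no integrator,
  hence no timestep bias), forces exactly `-k x`, energies the sampled
  potential plus a chi-squared kinetic term. The oracle carries
  `nu = (1/2 pi) sqrt(k/m)` and the closed-form QHO entropy. Because the
  tether is an external potential rather than an interaction shared between
  neighbouring cells, the matching estimator
  (`harmonic_entropy_estimate()`) applies no mean-field halving; the
  halving conventions are exercised separately on molecular fixtures.
* `synth_dihedral_chain()` — multi-state angle series with known well
  populations, independent or copy-correlated, with exact Shannon/joint
  entropies.
* `toy_shell_geometry()` — fixed configurations whose RAD shells are
  derived by direct evaluation of the blocking inequality, independently of
  the production implementation.
* `synth_composite_solution()` — four harmonic boxes sharing solvent
  parameters so that all solvent terms cancel in the transfer; a prescribed
  `dH` enters as an energy offset and a prescribed `dS` is realised by
  root-finding the solute spring constant in the octanol-like box against
  the QHO entropy. The oracle `dG` and logP are exact.

What passing these tests shows: the covariance-to-frequency-to-entropy
chain, the conformer machinery, the shell criterion and the four-box
arithmetic are each correct against analytic truth, and the whole pipeline
recovers a known logP. What they do not show: anything about force-field
quality, about the convergence of real water/octanol simulations, or about
anharmonicity — the generator's wells are exactly harmonic and its dihedral
states are uncorrelated in time. Fixtures validate estimators, not
force fields.

## Problem sizes and defaults

The suite runs at desk scale by choice: harmonic recovery uses 2e4–5e4
Boltzmann samples (relative error of a variance estimate scales as
`sqrt(2/n)`, so 5e4 frames put the frequency error near 0.3%), conformer
recovery uses 4e3–6e3 frames, the composite four-box test uses 1e5 frames
and 12 solvent molecules per box, and the molecular-liquid pipeline tests
use 10–25 frame boxes of 5–8 molecules, which exercise every code path
while keeping the RAD-per-molecule cost trivial. The composite's default
solvent count is small because solvent contributions cancel identically in
the transfer; their only role is to contribute realistic cancelling noise.

## Known limitations

* Only orthorhombic (in practice cubic) boxes; no velocities, restarts or
  trajectory concatenation; no GROMACS/CHARMM dialects. Topology input is
  the YAML fixture dialect or a minimal AMBER prmtop subset; trajectories
  use the package's documented text dialect, which requires forces on every
  frame — their absence is a hard error, not a warning.
* Shells are molecular-COM-based throughout, including octanol's long
  chain.
* The UA bond-derived axis construction and the conformer correlation
  matrix normalization follow the frozen conventions stated above; other
  choices exist in the literature, and the normative behaviours any variant
  must reproduce (single-dihedral Shannon limit, no double counting of
  correlated dihedrals) are pinned by the test suite.
* Whole-box energies are used for `H`; shell-restricted energies would
  reduce noise but require per-group energy decomposition that standard MD
  logs do not provide.
* Mixed solvation (water dissolved in the octanol phase), tautomer and
  protonation-state enumeration are out of scope.

## A small worked example

```{r example}
## exact two-state conformational entropy
dc <- synth_dihedral_chain(4000, centers = list(c(-60, 180)),
                           probs = list(c(0.5, 0.5)), seed = 1)
cf <- assign_conformers(dc$angles[, 1])
as.numeric(conformational_entropy(list(cf)))   # ~ kB ln 2 = 5.76 J/K/mol

## four-box harmonic bundle with a prescribed transfer
cs <- synth_composite_solution(2e4, dh = -1.3643, ds = 0, seed = 2)
rec <- composite_logp(cs)
c(oracle = cs$oracle$logP, recovered = rec$logP)
```
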