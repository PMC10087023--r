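---
title: "Multiscale cell correlation free-energy analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale cell correlation free-energy analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemcc)
```

## The problem

The absolute stability of a hydrated biomolecule is quantified by its Gibbs
free energy, $G = H - TS$. From an equilibrium molecular-dynamics (MD)
simulation the enthalpy $H$ is directly available as the ensemble average of
the system Hamiltonian, but the entropy $S$ requires an explicit model of
the configurational distribution. `eemcc` implements an energy–entropy
approach in which entropy comes from *multiscale cell correlation* (MCC):
the system is discretized into units at three length scales — united atoms
(UA: a heavy atom plus its bonded hydrogens), monomers (protein residues,
water molecules, ions) and polymers (whole molecules) — and at each level
the entropy splits into a *vibrational* part (motion within an energy well,
treated as quantum harmonic oscillators) and a *topographical* part
(the distribution over distinct wells: dihedral conformers for residues,
hydrogen-bond orientations for water).

The package consumes MD output (topology with masses/charges and bonds,
coordinate and force trajectories, per-atom potential and kinetic energies)
and produces per-water, per-residue and per-molecule tables of $S$, $H$ and
$G$, plus grouping and correlation reports.

## Vibrational entropy from force and torque covariances

For a set of $N$ units at one level, the package accumulates the covariance
of mass-weighted net forces, $\langle F_i F_j \rangle / \sqrt{m_i m_j}$, and
inertia-weighted torques, $\langle \tau_i \tau_j \rangle / \sqrt{I_i I_j}$,
over frames, with each unit's 3-vector expressed in a level-specific
coordinate frame (below). Eigenvalues $\lambda_i$ of these matrices are
converted to harmonic frequencies

$$\nu_i = \frac{1}{2\pi}\sqrt{\frac{\lambda_i}{k_B T}},$$

and each kept mode contributes the quantum-harmonic-oscillator entropy

$$S_{vib} = k_B \sum_i \left[\frac{h\nu_i/k_B T}{e^{h\nu_i/k_B T}-1}
 - \ln\!\left(1-e^{-h\nu_i/k_B T}\right)\right].$$

The stiffer the effective well (larger force variance at fixed
temperature), the higher the frequency and the lower the entropy. A
harmonic trap with spring constant $k$ and mass $m$ gives
$\langle F^2\rangle = k\,k_B T$ per axis and hence recovers
$\nu = \sqrt{k/m}/2\pi$ exactly; the test suite drives the whole chain with
Boltzmann-sampled traps and checks the analytic entropy to within 2% at
$10^5$ samples.

Mode bookkeeping follows three rules:

* **Rigid-body removal.** At sub-polymer levels the six smallest force
  eigenvalues are removed: they correspond to translation and rotation of
  the whole collection, which are counted once at the level above. (An
  alternative would be projecting out rigid-body vectors before
  diagonalization; we implement smallest-six removal as the simpler,
  spectrum-level operation. With fewer than six eigenvalues available —
  a one-unit collection — all are removed.)
* **Torque mode counts.** A unit contributes 3, 2 or 0 rotational
  components for nonlinear, linear and point geometry. At the UA level the
  class comes from the topology alone (two or more hydrogens / exactly one
  / none), so a CH group is linear and a carbonyl oxygen is a point; at
  higher levels it comes from the collinearity of the unit's atoms. The
  3/2/0 rule is applied uniformly at all levels.
* **Clamping.** Negative eigenvalues (statistical noise in a
  finite-sample covariance) are clamped to zero and excluded, with a
  count reported; $\nu = 0$ modes contribute zero entropy, since the QHO
  expression diverges logarithmically as $\nu \to 0$ and such modes are
  either noise or already counted elsewhere.

### Coordinate frames

* *Polymer*: mass-weighted principal axes at the center of mass.
* *Residue translations*: the polymer principal axes. *Residue rotations*:
  a backbone frame with origin at the mean of N, CA, C; x along N→C,
  y normal to the N–CA–C plane, z completing the right-handed set.
  Collinear backbones fall back to principal axes with a warning.
* *UA translations*: the residue backbone frame. *UA rotations*: origin at
  the heavy atom, x along the mean covalent bond vector to the hydrogens,
  with the perpendicular axes fixed by the first hydrogen and, for linear
  UAs, by the first bonded heavy neighbor.
* *Water*: each molecule is a single unit in its own principal-axes frame
  with 3 translational and 3 rotational modes and no rigid-body removal
  (it *is* the top level for that molecule).

All sign and axis conventions are resolved against the structure itself
(never the laboratory frame), which makes every entropy term invariant
under a rigid rotation of the whole system — a property the suite asserts
to $10^{-8}$ — while remaining deterministic across reruns.

Moments of inertia are computed per frame about the unit origin in the
local frame and used to weight that frame's torques; we do not time-average
the inertia first, as the per-frame weighting matches the covariance
construction most directly.

## Conformational (topographical) entropy

For every rotatable heavy-atom bond, a dihedral is enumerated from the bond
graph (lowest-index heavy neighbors flank the central bond; the dihedral
belongs to the residue of the central bond, so backbone phi/psi/omega
quadruples that reach into a bonded neighbor are included; improper-like
quadruples are not generated). Angles are histogrammed on a circular grid
with 30-degree bins; peaks are bins strictly above both circular neighbors,
with equal-count plateaus merged to the lower bin index; every frame is
assigned to the nearest peak in circular distance. The entropy of a residue
is the Shannon entropy over its joint conformer states,

$$S_{topo} = -k_B \sum_i p_i \ln p_i,$$

computed over tuples across all of the residue's dihedrals, so
inter-dihedral correlation within a residue is captured (a uniform 3-state
dihedral gives $k_B\ln 3 = 9.134$ J K⁻¹ mol⁻¹). States observed once
contribute their $-k_B p \ln p$ as computed; no sparse-state bias
correction is applied. Inter-residue conformer correlations and
residue-level topographical entropy are out of scope (assumed small for
stable globular proteins).

## Water orientational entropy

Water's topographical entropy reflects how many distinct hydrogen-bonding
orientations its coordination shell supports. Three ingredients:

1. **RAD shells.** The coordination shell of a UA is parameter-free: a
   neighbor $j$ (sorted by distance) is in the shell of $i$ unless some
   closer $k$ blocks it, i.e. unless
   $1/r_{ij}^2 \le (1/r_{ik}^2)\cos\theta_{jik}$. All closer neighbors are
   tested as blockers (not only already-accepted ones; the two variants are
   compared on fixtures and agree on equilibrated water, with the
   all-closer reading kept as the default since it is the stricter test).
   An 8 Å pre-filter truncates the candidate list purely for speed; it is
   far outside any first shell in condensed phase.
2. **Topological hydrogen bonds.** Each donor hydrogen binds at most one
   acceptor: the negatively charged atom, within the donor UA's shell,
   minimizing $q_D q_A / r^2$. Equal scores break to the lowest atom index
   for determinism.
3. **Donate/accept statistics.** Waters are classed by their
   nearest-solute label (bulk, or nearest-residue identity); shell members
   are typed as water-in-first-shell, water-outside, protein UA, or ion.
   Counts are accumulated over all frames of a class and then converted to
   probabilities ($p_{Dn} = N_{Dn}/\sum_n N_{Dn}$, likewise $p_{An}$), since
   the working equations are written on mean quantities. Then
   $$p_{HBn} = \frac{p_{Dn}}{p_{Dn}+p_{An}}\cdot\frac{p_{An}}{p_{Dn}+p_{An}},
   \qquad
   p_{HB}^{av} = \sum_n p_{HBn}\frac{N_n}{N_c}, \qquad
   N_{eff} = \frac{\sum_n p_{HBn} N_n}{0.25},$$
   where 0.25 is the ideal value for two hydrogen bonds each with equal
   donate/accept probability, and
   $$S_{or} = k_B \sum_c p_c \ln\!\left(\frac{N_{eff}\,\pi^{3/2}\,
   p_{HB}^{av}}{\sigma}\right), \qquad \sigma = 2.$$

Two genuinely open readings were resolved as follows:

* **Placement of the factors in $S_{or}$.** We read the argument as
  $N_{eff}\,\pi^{3/2}\,p_{HB}^{av}/\sigma$. Self-consistency pins this
  down: with one neighbor type and equal donate/accept propensities the
  expression reduces to $k_B\ln(N_c\,\pi^{3/2}/8)$, which evaluates to
  10.7 J K⁻¹ mol⁻¹ at the RAD bulk-water coordination number
  $N_c = 5.2$ — the accepted bulk orientational entropy. Alternative
  placements do not reproduce this value.
* **Class taxonomy.** Shell classes $c$ are nearest-solute labels and the
  four neighbor types above; this is a documented interpretation of the
  grouping practice rather than a unique prescription.

Arguments of the logarithm at or below 1 are clamped to zero contribution
(a state with one available orientation has no orientational entropy) and
counted. For per-class vibrational pooling, each water is assigned the
class it occupies most often across the analyzed frames, so covariances of
sparsely populated classes still converge; per-frame reassignment would
fragment the statistics.

## Enthalpy and free energy

LAMMPS-style per-atom potential energies already divide every interaction
term equally among its participating atoms, so any grouping of atoms sums
exactly to the system Hamiltonian average:
$H_j = \sum_{i \in j}(\langle K_i\rangle + \langle U_i\rangle)$. The test
suite asserts exact conservation under arbitrary regroupings. The $PV$
term is of order joules per mole per molecule at ambient pressure and is
neglected by default (a flag adds it back for sensitivity checks). Kinetic
energies are used as dumped; no constraint-correction is applied when the
engine uses SHAKE. Free energy is assembled as $G = H - TS$ with entropies
converted from J K⁻¹ mol⁻¹ internally.

## What the synthetic generators emulate

All fixtures are seeded, bit-reproducible, carry their ground truth as
metadata, and are written through the package's own dump/TSV writers and
re-read with `load_frames()`, so every test also exercises the I/O path.

* `sample_harmonic()` draws Boltzmann configurations of independent 1-D
  wells: positions Gaussian with variance $k_B T/k$, forces exactly
  $-kx$, per-atom energies exact. It validates the covariance → spectrum →
  QHO chain against closed forms. It does not emulate anharmonicity or
  inter-unit coupling.
* `make_water_box_frames()` places TIP3P-charged rigid waters on a jittered
  cubic lattice at liquid density (0.0334 waters/Å³) with fresh random
  orientations each frame, so donate/accept statistics are symmetric by
  construction. It exercises RAD shells (mean coordination number lands in
  the physical 4–7 band), topological H-bonds and the orientational
  machinery. Its forces and energies are placeholders: it does *not*
  emulate real water dynamics, so passing tests validate the estimator
  algebra, not TIP3P thermodynamics.
* `make_toy_dipeptide()` builds an idealized ACE–ALA–NME geometry
  (22 atoms, 10 UAs) and plants a conformer plan on the backbone phi
  dihedral (wrapped-normal wells, default sd 10°); the analytic
  $-k_B\sum p\ln p$ is attached. `make_solvated_dipeptide()` centers the
  peptide in a water lattice for end-to-end runs.

Consequently, green tests demonstrate correctness of the estimators and
bookkeeping on systems with known answers; reproducing literature values
for real proteins additionally requires converged MD sampling (tens of
nanoseconds with forces and per-atom energies dumped), which is outside
the test suite's scope.

## Numerical choices and degenerate inputs

* Minimum-image convention for all inter-unit distances; molecules are
  made whole (bond-graph walk) before frames, torques and inertia are
  computed.
* Internal units: Å, kJ mol⁻¹, K, amu; LAMMPS `real` input is converted by
  4.184. Entropies are reported in J K⁻¹ mol⁻¹, energies in kJ mol⁻¹.
* Ties: equal H-bond scores → lowest atom index; equal proximity
  distances → lowest residue id; plateau histogram peaks → lowest bin.
* Degenerate geometry: collinear backbones fall back to principal axes
  with a warning; coincident UA centers are an error; empty dihedral
  series are an error; a shell class with $N_c = 0$ is skipped with a log
  entry.
* Rank-deficient covariances (fewer frames than matrix dimension) warn;
  their spurious small eigenvalues are largely absorbed by rigid-body
  removal and clamping, but converged results need frames well in excess
  of $3N$ per level.

## Problem sizes used by the tests

The suite runs at desk scale by design: harmonic-trap recovery uses
$10^5$ samples (relative error ≈ 0.2%, asserted at 2%); conformer-plan
recovery uses $10^4$ frames (multinomial sampling error ≈ 0.4%, asserted
at 1%); RAD oracles enumerate up to 10 particles exactly; water boxes of
27–216 molecules over a few frames exercise shells, H-bonds and grouping;
the solvated dipeptide (~100 waters, 2–3 frames) drives the full pipeline
end to end. These sizes were chosen to make sampling error a small
fraction of each asserted tolerance while keeping the whole suite fast.

## Known limitations

* Protein orientational entropy is not computed (out of scope).
* Water beyond the first protein shell is treated as bulk.
* Ion mixing entropy is not included.
* The harmonic approximation underlies all vibrational terms; strongly
  anharmonic soft modes are approximated by their force-variance
  equivalent well.
* Baseline (capped amino acid) thermodynamics are an input file — the
  shipped `baselines_synthetic.tsv` is a synthetic example for
  demonstration, not reference data.
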