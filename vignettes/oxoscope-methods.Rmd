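---
title: "Methods: thermochemistry, kinetics and electrostatics post-processing for iron(IV)-oxo selectivity"
author: "oxoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermochemistry, kinetics and electrostatics post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxoscope)
```

## What the package models

Nonheme iron enzymes such as the taurine dioxygenase abstract a hydrogen
atom from a specific C–H bond of their substrate through a high-valent
iron(IV)-oxo (ferryl) oxidant, and the question of *which* C–H bond — the
pro-R C1–H rather than the intrinsically weaker C2–H — is a question about
free-energy differences of a few kcal/mol between four competing
abstraction transition states (labelled C1R, C1S, C2S, C2R by carbon and
prochirality). Electronic-structure codes produce the raw ingredients
(energies, Hessians, dipoles, spin densities); everything downstream of
that — composite energy assembly, statistical thermodynamics, rate theory,
isotope effects, branching ratios, bond-strength perturbation by fields,
and protein-level electrostatics — is deterministic arithmetic that this
package implements as a tested, reusable layer. Electronic-structure
computation itself (DFT, TS searches, QM/MM coupling, solvation models) is
out of scope: records enter the pipeline already computed, or synthetic.

## The record model and units

A `qc_record()` holds one species: label, charge, multiplicity, electronic
energies in hartree (`E_high` at the single-point level, optionally
`E_low`), optional solvation and dispersion corrections in hartree,
harmonic wavenumbers in cm⁻¹ with imaginary modes encoded as *negative*
values, an optional Cartesian Hessian in hartree/bohr², dipole in debye,
per-atom spin densities, and the geometry in ångström. Exactly one of
frequencies or Hessian+geometry is needed for thermochemistry. All unit
conversions go through the single `oxo_constants` table
(1 hartree = 627.5095 kcal/mol, 1 cm⁻¹ = 2.8591·10⁻³ kcal/mol,
hc/k_B = 1.43877 cm·K, k_B/h = 2.08366·10¹⁰ s⁻¹K⁻¹,
1 e·Å = 4.80321 D, 14.3996 V/Å per e at 1 Å).

Records serialize to a human-readable YAML text format with an explicit
format/units header, chosen so fixtures can be audited by eye; floats are
written to 17 significant digits so read–write round-trips are exact to
better than 1 part in 10¹². Default atomic masses are isotope-pure (most
abundant isotope), overridable atom by atom — isotope substitution is a
first-class operation, not a table edit. PDB parsing is delegated to
`bio3d` with first-model/altloc-A conventions applied on top.

## RRHO thermochemistry

`rrho()` implements standard rigid-rotor harmonic-oscillator statistical
mechanics at a standard state of 1 atm and (by default) 298.15 K:

* ZPE = ½ Σ hcνᵢ over real modes; imaginary modes are excluded and
  counted (`n_imag`), with a warning — not an error — beyond one, since
  scan artefacts with two small imaginary modes are common in practice.
* The thermal enthalpy correction `H_corr` collects vibrational thermal
  energy, 3/2 RT translation + RT (PV), and rotation (RT for linear
  species); `G_corr = H_corr − T·S` by construction.
* Translational entropy is Sackur–Tetrode and rotation uses the classical
  rigid-rotor partition function with symmetry number fixed at 1
  (enzyme-model species have no symmetry; this matches QC-package
  defaults). Both need a geometry; without one the result is
  vibration-only, which cancels exactly in differences between species
  sharing a frame — the mode in which the synthetic landscapes operate.
* Frequencies enter *unscaled* by default; scaling factors (e.g. the 0.95
  recommended for B3LYP fundamentals) are applied only on request, and
  only to real modes — a scaling factor calibrates observable
  fundamentals, not the curvature at a saddle point.
* Low-frequency modes enter the entropy as harmonic oscillators, with no
  quasi-RRHO damping: that reproduces the upstream protocol whose numbers
  the pipeline book-keeps. Linearity is detected by a smallest principal
  moment of inertia below 10⁻⁴ amu·Å².

Validation: the implementation reproduces Sackur–Tetrode entropy for a
39.948 amu atom (36.98 cal mol⁻¹K⁻¹) and the σ=1 entropy of CO at 298.15 K
to better than 0.01 cal mol⁻¹K⁻¹, and the vibrational entropy reaches the
closed-form high-temperature limit R(1 + ln(k_BT/hcν)) within 1 % for
hcν/k_BT < 0.05.

## Hessians, normal modes and isotope shifts

`isotope_frequencies()` mass-weights the Cartesian Hessian, projects out
the translational and (2 or 3) rotational directions with an orthonormal
mass-weighted basis, diagonalizes, and converts eigenvalues to
wavenumbers, negative for imaginary modes. Isotope substitution replaces
per-atom masses before mass-weighting. For a diatomic this collapses to
the reduced-mass law ν′ = ν√(μ/μ′): an Fe–O oscillator tuned to 860 cm⁻¹
with masses 56/16 drops by 38.0 cm⁻¹ on ¹⁸O substitution, and 0.95 scaling
of the fundamental gives 817 cm⁻¹. The integer masses here follow the
closed-form oracle convention; with isotope-pure masses
(55.9349/15.9949/17.9992) the shift is 38.1 cm⁻¹ — both conventions are
supported and the difference is far below any experimental resolution of
the difference spectrum.

## Composite energies and landscapes

`assemble()` builds kcal/mol totals under explicit schemes —
`E+ZPE`, `E+ZPE+solv`, `E+ZPE+solv+disp`, and `G` (which adds thermal and
−TS, and folds in solvation/dispersion when the record carries them). A
scheme that names a component the record lacks errors by component name
rather than assuming zero; this is deliberate: silent zero-defaults are
how sign errors in solvation bookkeeping survive review.

A `landscape()` is a validated set of `stationary_point()`s (roles Re,
TS1_HA, IM1, TS2_reb, P; pathways C1R/C1S/C2S/C2R) sharing one reference
reactant — by default the lowest-energy (ground-spin) Re. TS roles must
carry exactly one imaginary mode when frequencies are present; points
flagged `estimated` (rebound barriers from constraint scans rather than
located saddle points) are exempt and excluded from rate-determining-step
calls. Both C1 transition states may share one radical intermediate, so
the TS2-needs-IM1 validation works per carbon position. `relative_table()`
reports ΔE+ZPE and ΔG columns against the reference, which is gauge
invariant under any common shift of the electronic energies.

## Kinetics, KIEs and branching

Transition-state theory with unit transmission coefficient connects rates
and barriers, k = (k_BT/h)·exp(−ΔG‡/RT); the experimental abstraction rate
of 13 s⁻¹ at 278.15 K converts to ΔG‡ = 14.83 kcal/mol. Kinetic isotope
effects use the Eyring form KIE = exp((ΔG‡_D − ΔG‡_H)/RT) and the
Wigner-corrected form KIE·Q_t,H/Q_t,D with
Q_t = 1 + (hcν/k_BT)²/24 evaluated at the magnitude of the TS imaginary
wavenumber (Q_t(i1495 cm⁻¹, 298.15 K) = 3.17). Tunnelling enters only
through this factor; ν_D below ν_H is expected for H-transfer, and the
reverse triggers a warning but still evaluates.

`branching()` applies Curtin–Hammett logic: fractions ∝ exp(−ΔG‡ᵢ/RT)
from a common, rapidly equilibrating reactant with irreversible first
step. `selectivity_from_barriers()` sums fractions per carbon and calls
the preference *dominant* above 0.9, *preferred* above 0.5, otherwise
*unselective* (with a 10⁻⁶ epsilon so an exact 50/50 split is
unselective). Barriers default to free energies when every TS1 carries
them, otherwise the landscape's electronic scheme, and the choice is
recorded in the result.

## BDFE and field response

Bond dissociation free energies are the homolysis sums
BDFE = G(R•) + G(H•) − G(RH) with an internal identity re-check, and mixed
assembly schemes across the three components are an error. Field response
is first-order by default: BDFE(F) = BDFE(0) − (Δμ·u)F with Δμ the
fragments-minus-parent dipole difference in debye and 1 D·(V/Å) = 4.8032
kcal/mol; a quadratic −½Δα F² term is available when a polarizability
difference is supplied. First order suffices for the qualitative
axis-dependence being modelled (a field along the substrate skeleton
barely moves the C1/C2 difference; a field along the pro-R C1–H bond flips
the weakest bond at a crossing field computable in closed form). Molecular
axes pass through the centre of mass with a right-handed convention; the
sign of +u is a documented flag, since upstream codes differ. Field
magnitudes beyond 1 V/Å are rejected as unphysical for condensed-phase
reasoning. The solvated bond-strength ordering (all four C–H bonds within
2.0 kcal/mol, C1–H weakest) is encoded as an inequality fixture, not as
hard-coded values, because only the gas-phase numbers are printed text.

## Protein electrostatics

`residue_census()` counts unique (chain, residue number) ATOM residues of
the first model; Asp+Glu are the negative tally, Arg+Lys the positive,
His neutral unless explicitly flagged doubly protonated — the protonation
toggle that separates the selectivity-correct from the
selectivity-reversed cluster models. `charge_model()` places ±1 e at
side-chain representative atoms (CG/CD/CZ/NZ; ND1–NE2 midpoint for
protonated His), falling back to the residue centroid when absent.
Dipoles are Σqᵢ(rᵢ−origin) in debye — translation-invariant only for
net-neutral sets, so the origin is always explicit and the origin-shift
identity μ(O₁)−μ(O₂) = q_net(O₂−O₁) is tested, not assumed. The Coulomb
field is an unscreened vacuum point-charge sum (optional uniform
dielectric divisor), with a 0.5 Å singularity guard; composing the site
field with the Stark model gives the end-to-end
environment → bond-weakening estimate whose sign flips when all charges
are negated.

## Synthetic generators and what they do (not) show

All fixtures are generated, seeded, and carry their ground truth:

* `gen_harmonic_system()` builds H = M^(1/2) B diag(λ) Bᵀ M^(1/2) with B a
  seeded random orthonormal basis of the internal subspace, so the
  recomputed spectrum equals the prescription to 10⁻⁶ cm⁻¹ while
  translations/rotations are exactly null. The seed moves the mixing
  matrix and geometry, never the spectrum.
* `gen_landscape()` emits full stationary-point ensembles whose assembled
  energies reproduce prescribed ΔE+ZPE *and* ΔG profiles to 10⁻⁹
  kcal/mol. The split of each total into E_high/ZPE/E_solv/E_disp is
  randomized under the seed (a deliberate stress on sign and unit
  handling), and the ΔG−ΔE gap per species is steered analytically
  through twelve low-frequency modes via the closed-form inverse of the
  per-mode vibrational free-energy tail RT·ln(1−e^(−hcν/k_BT)). The
  reference record's steering modes sit at 80 cm⁻¹, giving ≈ ±8 kcal/mol
  of headroom on the gap.
* `gen_toy_pdb()` writes fixed-width PDB files on a 5 Å cubic lattice
  (no accidental contacts) with CA plus the charge-bearing side-chain
  atoms per residue. It is a *synthetic* structure: composition is ground
  truth, conformation is not, and census results on it validate counting
  logic only — not agreement with any deposited crystal structure, which
  would require the real coordinate file.

Presets encode the study conditions the workflow analyses: the medium
cluster model's full profile (barriers 9.3/10.9/11.8/12.2 kcal/mol on the
E+ZPE scale with free energies 15.4/14.2/13.1/14.5, shared intermediates
at −8.8/−8.1, scan-estimated C1R/C2R rebound barriers, spin ladder
0/10.4/10.9/19.2 for multiplicities 5/3/7/1), the large cluster model
(14.5/15.8 vs 21.2/23.1; i1495/i1534 cm⁻¹), the QM/MM barrier sets, and
the summary barrier table. Where the source profile states only free
energies, the electronic scale is placed 2 kcal/mol below by a one-time
convention; where it states only ">i1000 cm⁻¹" for imaginary modes or
"large exothermicity" for products, representative values (1250–1350 cm⁻¹;
−46 to −50 kcal/mol) were fixed once. These choices affect no selectivity
verdict: verdicts depend only on barrier differences within a model.

Passing tests therefore demonstrate that the *arithmetic layer* is exact
and self-consistent on inputs with known truth. They do not validate the
electronic-structure inputs themselves, conformational sampling, or any
real-protein electrostatics beyond counting — those live upstream of this
package.

## Numerical choices

* Problem sizes: recovery sweeps use 50 seeded prescriptions (9–18
  records each) and harmonic fixtures of 2–6 atoms; each sweep runs in
  seconds and larger sizes add no new code paths.
* Degenerate inputs: single atoms get translational thermochemistry only;
  zero-mode records have ZPE 0; empty substitution maps are identities;
  empty structures and missing components error by name.
* Tie-breaks: rate-determining-step ties (within 10⁻⁹ kcal/mol) resolve
  to the earlier mechanistic step and are flagged; the weakest-bond map
  reports midpoints of grid intervals as transition fields.
* Tolerances: 10⁻⁹ kcal/mol for generator round-trips, 10⁻⁶ cm⁻¹ for
  spectra, 10⁻¹² relative for file round-trips, 0.01 kcal/mol for the
  frequency-list-vs-Hessian thermochemistry agreement (the projection
  changes low modes at that level on random fixtures).

## Known limitations

No anharmonicity, hindered rotors, quasi-RRHO entropy damping (offered
nowhere because the upstream protocol does not use it), variational TST or
Eckart tunnelling; no Poisson–Boltzmann screening or pKa logic in the
electrostatics; PDB writing and mmCIF are out of scope. The toy-PDB
census substitutes for the deposited structure's census whenever the
coordinate file is unavailable; on the real file the same function applies
unchanged, and any count discrepancy there should be reported, not
adjusted away.
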